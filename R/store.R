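#' Build an annotated MS1 point store with a spatial index
#'
#' Bulk-loads a point cloud into a balanced partition tree whose split
#' dimension alternates by level — m/z at even depths, RT at odd depths —
#' so that windowed queries are fast whether the requested region is
#' narrow in m/z, in RT, or both. Alongside the tree, an intensity
#' registry (all point ids ordered by non-increasing intensity, ties by
#' ascending id) supports jumping to the next unannotated maximum.
#'
#' The returned store is a mutable single-writer object: annotation edits
#' (see [create_trace()], [assign_rectangle()], [set_envelope()],
#' [mark_noise()]) are applied synchronously, so every subsequent query
#' reflects them — a curation engine must never serve stale membership.
#'
#' The tree is built by recursive median split on the depth-parity
#' dimension (ties broken by ascending point id), which is deterministic
#' for a fixed input set and yields leaves of at most `leaf_capacity`
#' points. Query answers are independent of input order.
#'
#' @param points A data frame of peak points (see [as_peak_points()]);
#'   may carry pre-existing annotations, which are registered.
#' @param leaf_capacity Maximum points per tree leaf, >= 1. Default 512.
#' @return An object of class `mz_store`.
#' @examples
#' pts <- peak_points(mz = runif(100, 400, 500), rt = runif(100, 0, 300),
#'                    intensity = rexp(100))
#' store <- build_index(pts, leaf_capacity = 16)
#' count_in_window(store, global_bounds(store))
#' @export
build_index <- function(points, leaf_capacity = 512L) {
  if (!is_count(leaf_capacity, min = 1L))
    mz_stop("validation", "leaf_capacity must be a positive integer")
  pts <- as_peak_points(points)
  store <- new.env(parent = emptyenv())
  store$points <- pts
  store$leaf_capacity <- as.integer(leaf_capacity)
  store$tree <- if (nrow(pts) > 0L)
    build_node(pts$mz, pts$rt, pts$point_id, depth = 0L,
               cap = store$leaf_capacity)
  else NULL
  store$intensity_order <- pts$point_id[order(-pts$intensity, pts$point_id)]
  # register annotation namespaces found in the input
  tids <- sort(unique(pts$trace_id[pts$trace_id > 0L]))
  t2e <- integer(length(tids))
  for (i in seq_along(tids)) {
    envs <- unique(pts$envelope_id[pts$trace_id == tids[i]])
    if (length(envs) > 1L)
      mz_stop("validation",
              "trace %d carries more than one envelope_id", tids[i])
    t2e[i] <- envs
  }
  store$traces <- data.table::data.table(trace_id = tids, envelope_id = t2e)
  eids <- sort(unique(t2e[t2e > 0L]))
  store$envelopes <- data.table::data.table(
    envelope_id = eids, charge = rep(NA_integer_, length(eids)))
  class(store) <- "mz_store"
  store
}

# recursive median-split node builder; splits m/z at even depth, RT at odd
build_node <- function(mz, rt, ids, depth, cap) {
  node <- list(
    bounds = mz_window(min(mz), max(mz), min(rt), max(rt)),
    depth = depth,
    split_dimension = if (depth %% 2L == 0L) "mz" else "rt"
  )
  n <- length(ids)
  if (n <= cap) {
    node$point_ids <- ids
    return(node)
  }
  v <- if (depth %% 2L == 0L) mz else rt
  ord <- order(v, ids)
  half <- as.integer(ceiling(n / 2))
  l <- ord[seq_len(half)]
  r <- ord[seq.int(half + 1L, n)]
  node$children <- list(
    build_node(mz[l], rt[l], ids[l], depth + 1L, cap),
    build_node(mz[r], rt[r], ids[r], depth + 1L, cap)
  )
  node
}

# ids of points in leaves overlapping the window (superset of the answer)
collect_candidate_ids <- function(node, w) {
  if (is.null(node) || !windows_overlap(node$bounds, w)) return(integer(0))
  if (!is.null(node$point_ids)) return(node$point_ids)
  c(collect_candidate_ids(node$children[[1L]], w),
    collect_candidate_ids(node$children[[2L]], w))
}

# exact in-window subset via the tree, in ascending point_id order
tree_window_points <- function(store, w) {
  ids <- collect_candidate_ids(store$tree, w)
  if (!length(ids)) return(store$points[0L])
  cand <- store$points[list(sort(ids))]
  cand[window_mask(cand, w)]
}

#' Query a window for points, optionally under a point budget
#'
#' Returns the stored points inside the closed window. When `limit` is
#' `NULL` (or at least the in-window count) the full set is returned;
#' otherwise a deterministic representative subset of exactly `limit`
#' points is chosen by [weighted_stride()], which always preserves the
#' window's intensity maximum. Returned rows carry the current
#' `trace_id`/`envelope_id` annotation values.
#'
#' @param store An `mz_store`.
#' @param window An [mz_window()] (or length-4 numeric
#'   `c(mz_min, mz_max, rt_min, rt_max)`).
#' @param limit `NULL` for no budget, or a non-negative integer cap on the
#'   number of points returned.
#' @return A `data.table` of peak points ordered by ascending `mz`, ties
#'   by ascending `rt`, then `point_id`.
#' @export
query_window <- function(store, window, limit = NULL) {
  stopifnot(inherits(store, "mz_store"))
  w <- as_mz_window(window)
  if (!is.null(limit) && !is_count(limit))
    mz_stop("validation", "limit must be NULL or a non-negative integer")
  inside <- tree_window_points(store, w)
  if (!is.null(limit) && limit < nrow(inside))
    inside <- weighted_stride(inside, limit)
  data.table::setorderv(inside, c("mz", "rt", "point_id"))
  inside[]
}

#' Count stored points inside a window
#'
#' Exact count of points in the closed window; used by clients to enforce
#' the mark-as-noise visibility guard.
#'
#' @inheritParams query_window
#' @return Integer count.
#' @export
count_in_window <- function(store, window) {
  stopifnot(inherits(store, "mz_store"))
  nrow(tree_window_points(store, as_mz_window(window)))
}

#' Select a representative subset of points under a budget (weighted striding)
#'
#' Deterministic level-of-detail subsampling for rendering large point
#' clouds: the input is ordered along the traversal axis (ascending m/z,
#' ties by RT then point id) and partitioned into `limit` contiguous
#' strides of (near-)equal point count; each stride contributes its
#' maximum-intensity point (ties by ascending point id). The global
#' intensity maximum is always retained, and the selection is spread
#' across the full m/z extent of the input, so peak shape and data
#' coverage survive aggressive budgets.
#'
#' @param points A data frame of peak points.
#' @param limit Non-negative integer budget.
#' @return A `data.table` of `min(limit, nrow(points))` points in
#'   traversal order.
#' @examples
#' pts <- peak_points(mz = 1:10 + 100, rt = 0, intensity = c(1:5, 5:1))
#' weighted_stride(pts, 2)  # the two stride maxima
#' @export
weighted_stride <- function(points, limit) {
  if (!is_count(limit))
    mz_stop("validation", "limit must be a non-negative integer")
  pts <- as_peak_points(points)
  n <- nrow(pts)
  data.table::setorderv(pts, c("mz", "rt", "point_id"))
  if (limit == 0L) return(pts[0L])
  if (n <= limit) return(pts[])
  stride <- as.integer(floor((seq_len(n) - 1L) * limit / n)) + 1L
  pick <- pts[, .I[order(-intensity, point_id)[1L]], by = stride]$V1
  pts[sort(pick)]
}

#' Minimal window enclosing every stored point
#'
#' @param store An `mz_store`.
#' @return An [mz_window()] whose closed bounds touch the extreme points.
#' @export
global_bounds <- function(store) {
  stopifnot(inherits(store, "mz_store"))
  if (nrow(store$points) == 0L)
    mz_stop("no_data", "store holds no points")
  store$tree$bounds
}

#' Jump target: the highest-intensity point not yet part of an annotation
#'
#' Scans the intensity registry (non-increasing intensity, ties by
#' ascending point id) for the first point with `trace_id == 0`. Points in
#' traces and points marked as noise are both skipped. Supports the
#' annotate-highest-first workflow: call, annotate the returned point,
#' call again.
#'
#' @param store An `mz_store`.
#' @return A one-row `data.table`, or `NULL` when every point is annotated
#'   or noise.
#' @export
next_unannotated_max <- function(store) {
  stopifnot(inherits(store, "mz_store"))
  if (nrow(store$points) == 0L) return(NULL)
  tid <- store$points[list(store$intensity_order), trace_id]
  hit <- which(tid == 0L)
  if (!length(hit)) return(NULL)
  store$points[list(store$intensity_order[hit[1L]])]
}

#' @export
print.mz_store <- function(x, ...) {
  cat(sprintf(
    "<mz_store> %d points, %d trace(s), %d envelope(s), leaf capacity %d\n",
    nrow(x$points), nrow(x$traces), nrow(x$envelopes), x$leaf_capacity))
  if (nrow(x$points) > 0L) {
    b <- x$tree$bounds
    cat(sprintf("  m/z [%g, %g] Th, RT [%g, %g] s\n",
                b$mz_min, b$mz_max, b$rt_min, b$rt_max))
  }
  n_noise <- sum(x$points$trace_id == -1L)
  n_tr <- sum(x$points$trace_id > 0L)
  cat(sprintf("  annotated: %d in traces, %d noise, %d unannotated\n",
              n_tr, n_noise, nrow(x$points) - n_tr - n_noise))
  invisible(x)
}
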