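#' @name annotation
#' @title Trace and envelope annotation editing
#'
#' @description
#' Curation builds a two-level grouping over raw MS1 points: points are
#' gathered into isotopic traces (extracted ion chromatograms — the
#' near-constant-m/z signal of one isotope across retention time), and
#' traces are grouped into isotopic envelopes (the isotope pattern of one
#' molecule at one charge state, spaced ~1/z apart in m/z). A point may
#' alternatively be marked as noise. The engine maintains a strict
#' partition law: each point is unannotated, noise, or in exactly one
#' trace; each trace is in at most one envelope; every point of a trace
#' carries its trace's envelope id.
NULL

smallest_unused <- function(used) {
  cand <- 1L
  used <- sort(unique(used))
  for (u in used) {
    if (u > cand) break
    if (u == cand) cand <- cand + 1L
  }
  cand
}

trace_known <- function(store, trace_id)
  trace_id %in% store$traces$trace_id
envelope_known <- function(store, envelope_id)
  envelope_id %in% store$envelopes$envelope_id
trace_envelope <- function(store, trace_id)
  store$traces$envelope_id[match(trace_id, store$traces$trace_id)]

#' Create a new (empty) isotopic trace
#'
#' Allocates the smallest unused positive trace id; ids freed by
#' [delete_trace()] are reused. The new trace starts with no member
#' points; populate it with [assign_rectangle()].
#'
#' @param store An `mz_store`.
#' @return The allocated integer trace id.
#' @export
create_trace <- function(store) {
  stopifnot(inherits(store, "mz_store"))
  id <- smallest_unused(store$traces$trace_id)
  store$traces <- data.table::rbindlist(list(
    store$traces,
    data.table::data.table(trace_id = id, envelope_id = 0L)))
  data.table::setorderv(store$traces, "trace_id")
  id
}

#' Delete a trace, releasing its points and its id
#'
#' Member points revert to unannotated (`trace_id = 0`, `envelope_id = 0`)
#' and the id becomes available for reallocation.
#'
#' @param store An `mz_store`.
#' @param trace_id Id of an existing trace.
#' @return Invisibly, the number of points released.
#' @export
delete_trace <- function(store, trace_id) {
  stopifnot(inherits(store, "mz_store"))
  if (!trace_known(store, trace_id))
    mz_stop("missing_trace", "no trace with id %d", trace_id)
  sel <- store$points$trace_id == trace_id
  store$points[sel, c("trace_id", "envelope_id") := list(0L, 0L)]
  keep <- which(store$traces$trace_id != trace_id)
  store$traces <- store$traces[keep]
  invisible(sum(sel))
}

#' Assign or release points with a selection rectangle
#'
#' The rectangle edit mirrors interactive trace curation: in `"add"` mode
#' every in-rectangle point that is unannotated joins `trace_id` (points
#' owned by a different trace are never stolen and noise points are never
#' reclaimed); newly added points also receive the trace's current
#' envelope id. In `"remove"` mode every in-rectangle member of
#' `trace_id` reverts to unannotated (`trace_id` and `envelope_id` 0).
#' Both modes are idempotent.
#'
#' @param store An `mz_store`.
#' @param rect An [mz_window()] selection rectangle (closed bounds).
#' @param trace_id Id of an existing trace.
#' @param mode `"add"` or `"remove"`.
#' @return The number of points whose annotation changed.
#' @export
assign_rectangle <- function(store, rect, trace_id, mode = c("add", "remove")) {
  stopifnot(inherits(store, "mz_store"))
  mode <- match.arg(mode)
  w <- as_mz_window(rect)
  if (!trace_known(store, trace_id))
    mz_stop("missing_trace", "no trace with id %d", trace_id)
  trace_id <- as.integer(trace_id)
  inside <- window_mask(store$points, w)
  if (mode == "add") {
    sel <- inside & store$points$trace_id == 0L
    tid_val <- trace_id
    eid_val <- trace_envelope(store, trace_id)
    store$points[sel, c("trace_id", "envelope_id") := list(tid_val, eid_val)]
  } else {
    sel <- inside & store$points$trace_id == trace_id
    store$points[sel, c("trace_id", "envelope_id") := list(0L, 0L)]
  }
  sum(sel)
}

#' Derived summary of each trace
#'
#' @param store An `mz_store`.
#' @return A `data.table` with one row per registered trace: member point
#'   count, intensity-weighted mean m/z (`centroid_mz`, `NA` for an empty
#'   trace), RT extent, and envelope membership. Recomputed from current
#'   point annotations on every call.
#' @export
trace_summary <- function(store) {
  stopifnot(inherits(store, "mz_store"))
  mem <- store$points[trace_id > 0L,
    list(n_points = .N,
         centroid_mz = sum(mz * intensity) / sum(intensity),
         rt_min = min(rt), rt_max = max(rt)),
    by = "trace_id"]
  out <- merge(store$traces, mem, by = "trace_id", all.x = TRUE)
  out$n_points[is.na(out$n_points)] <- 0L
  data.table::setorderv(out, "trace_id")
  out[]
}

probe_dist2 <- function(pts, probe) {
  ((pts$mz - probe$mz) / probe$mz_span)^2 +
    ((pts$rt - probe$rt) / probe$rt_span)^2
}

#' Describe a click location in view-normalized coordinates
#'
#' A probe carries the clicked (m/z, RT) coordinate together with the
#' current view spans, which normalize the two axes so that "closest"
#' matches on-screen proximity: the distance between a probe and a point
#' is `sqrt(((dmz)/mz_span)^2 + ((drt)/rt_span)^2)`.
#'
#' @param mz,rt Probe coordinates (Thomson, seconds).
#' @param mz_span,rt_span Current view width/height, > 0.
#' @return An object of class `mz_probe`.
#' @export
probe <- function(mz, rt, mz_span, rt_span) {
  if (!is_num1(mz) || !is_num1(rt) || !is_num1(mz_span) || !is_num1(rt_span))
    mz_stop("validation", "probe fields must be single numbers")
  if (mz_span <= 0 || rt_span <= 0)
    mz_stop("validation", "probe spans must be > 0")
  structure(list(mz = mz, rt = rt, mz_span = mz_span, rt_span = rt_span),
            class = "mz_probe")
}

#' Find the trace closest to a probe, within a threshold
#'
#' Computes, for every trace member point, the span-normalized Euclidean
#' distance to the probe and returns the trace owning the nearest one.
#' Ties are broken by ascending trace id. The default threshold 0.02 is
#' about 2\% of the view diagonal.
#'
#' @param store An `mz_store`.
#' @param probe An [probe()] with view spans.
#' @param threshold Maximum normalized distance, > 0.
#' @return The integer trace id, or `NA_integer_` when no trace point is
#'   within the threshold.
#' @export
nearest_trace <- function(store, probe, threshold = 0.02) {
  stopifnot(inherits(store, "mz_store"), inherits(probe, "mz_probe"))
  if (!is_num1(threshold) || threshold <= 0)
    mz_stop("validation", "threshold must be > 0")
  pts <- store$points[trace_id > 0L]
  if (nrow(pts) == 0L) return(NA_integer_)
  d2 <- probe_dist2(pts, probe)
  best <- data.table::data.table(trace_id = pts$trace_id, d2 = d2)[
    , list(d = sqrt(min(d2))), by = "trace_id"]
  data.table::setorderv(best, c("d", "trace_id"))
  if (best$d[1L] > threshold) return(NA_integer_)
  best$trace_id[1L]
}

#' A dragged line between two probes
#'
#' @param start,end [probe()] objects sharing the same view spans.
#' @return An object of class `mz_segment`.
#' @export
probe_segment <- function(start, end) {
  stopifnot(inherits(start, "mz_probe"), inherits(end, "mz_probe"))
  if (start$mz_span != end$mz_span || start$rt_span != end$rt_span)
    mz_stop("validation", "segment endpoints must share view spans")
  structure(list(start = start, end = end), class = "mz_segment")
}

# distance from normalized points (px, py) to normalized segment a->b
segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px))
       else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Traces swept by a dragged segment
#'
#' Returns every trace having at least one member point whose
#' span-normalized distance to the segment is within the threshold — the
#' one-gesture way to collect all traces of an envelope. A zero-length
#' segment degenerates to [nearest_trace()] semantics (a set of 0 or 1
#' ids).
#'
#' @param store An `mz_store`.
#' @param seg A [probe_segment()].
#' @param threshold Maximum normalized distance, > 0.
#' @return Integer vector of trace ids in ascending order (possibly
#'   empty).
#' @export
traces_on_segment <- function(store, seg, threshold = 0.02) {
  stopifnot(inherits(store, "mz_store"), inherits(seg, "mz_segment"))
  if (!is_num1(threshold) || threshold <= 0)
    mz_stop("validation", "threshold must be > 0")
  pts <- store$points[trace_id > 0L]
  if (nrow(pts) == 0L) return(integer(0))
  sp <- seg$start
  d <- segment_dist(pts$mz / sp$mz_span, pts$rt / sp$rt_span,
                    seg$start$mz / sp$mz_span, seg$start$rt / sp$rt_span,
                    seg$end$mz / sp$mz_span, seg$end$rt / sp$rt_span)
  sort(unique(pts$trace_id[d <= threshold]))
}

#' Create a new (empty) isotopic envelope
#'
#' Same allocation contract as [create_trace()], in the envelope id
#' namespace: smallest unused positive integer, deleted ids reusable.
#'
#' @param store An `mz_store`.
#' @param charge Optional known charge state (integer >= 1) recorded as
#'   envelope metadata; `NA` when unknown.
#' @return The allocated integer envelope id.
#' @export
create_envelope <- function(store, charge = NA_integer_) {
  stopifnot(inherits(store, "mz_store"))
  if (!is.na(charge) && !is_count(charge, min = 1L))
    mz_stop("invalid_charge", "charge must be a positive integer or NA")
  id <- smallest_unused(store$envelopes$envelope_id)
  store$envelopes <- data.table::rbindlist(list(
    store$envelopes,
    data.table::data.table(envelope_id = id, charge = as.integer(charge))))
  data.table::setorderv(store$envelopes, "envelope_id")
  id
}

#' Delete an envelope, detaching its traces
#'
#' Member traces survive but become envelope-free; their points'
#' `envelope_id` resets to 0. The id becomes available for reallocation.
#'
#' @param store An `mz_store`.
#' @param envelope_id Id of an existing envelope.
#' @return Invisibly, the number of traces detached.
#' @export
delete_envelope <- function(store, envelope_id) {
  stopifnot(inherits(store, "mz_store"))
  if (!envelope_known(store, envelope_id))
    mz_stop("missing_id", "no envelope with id %d", envelope_id)
  member <- store$traces$trace_id[store$traces$envelope_id == envelope_id]
  if (length(member)) set_envelope(store, member, envelope_id, mode = "remove")
  keep <- which(store$envelopes$envelope_id != envelope_id)
  store$envelopes <- store$envelopes[keep]
  invisible(length(member))
}

#' Add traces to, or remove traces from, an isotopic envelope
#'
#' In `"add"` mode each listed trace is moved into the envelope; a trace
#' already in another envelope is silently re-parented (removed from the
#' old one first), matching fluid interactive editing. The envelope id is
#' stamped on every member point of the moved traces. In `"remove"` mode
#' listed traces that are members of this envelope are detached and their
#' points' `envelope_id` reset to 0.
#'
#' @param store An `mz_store`.
#' @param trace_ids Integer vector of existing trace ids.
#' @param envelope_id Id of an existing envelope.
#' @param mode `"add"` or `"remove"`.
#' @return The number of traces whose envelope membership changed.
#' @export
set_envelope <- function(store, trace_ids, envelope_id,
                         mode = c("add", "remove")) {
  stopifnot(inherits(store, "mz_store"))
  mode <- match.arg(mode)
  if (!envelope_known(store, envelope_id))
    mz_stop("missing_id", "no envelope with id %d", envelope_id)
  trace_ids <- as.integer(trace_ids)
  unknown <- trace_ids[!trace_ids %in% store$traces$trace_id]
  if (length(unknown))
    mz_stop("missing_id", "no trace with id %d", unknown[1L])
  eid_val <- as.integer(envelope_id)
  changed <- 0L
  for (tid in unique(trace_ids)) {
    cur <- trace_envelope(store, tid)
    if (mode == "add") {
      if (cur == eid_val) next
      store$traces[store$traces$trace_id == tid, "envelope_id" := eid_val]
      store$points[trace_id == tid, "envelope_id" := eid_val]
    } else {
      if (cur != eid_val) next
      store$traces[store$traces$trace_id == tid, "envelope_id" := 0L]
      store$points[trace_id == tid, "envelope_id" := 0L]
    }
    changed <- changed + 1L
  }
  changed
}

#' Mark every visible unannotated point in a window as noise
#'
#' The edit that closes out a fully curated view: every in-window point
#' with `trace_id == 0` gets `trace_id = -1` (noise); trace members are
#' untouched. It is guarded so that no unseen point can be condemned: the
#' window's true point count must not exceed `point_threshold` (the
#' render budget) and `rendered_count` — the number of points the client
#' actually displayed — must equal the true count. Any guard violation
#' raises an error and mutates nothing.
#'
#' @param store An `mz_store`.
#' @param window An [mz_window()].
#' @param rendered_count Number of points the client rendered for this
#'   window.
#' @param point_threshold The client's point render budget.
#' @return The number of points newly marked as noise.
#' @export
mark_noise <- function(store, window, rendered_count, point_threshold) {
  stopifnot(inherits(store, "mz_store"))
  w <- as_mz_window(window)
  if (!is_count(rendered_count) || !is_count(point_threshold))
    mz_stop("validation", "counts must be non-negative integers")
  n <- count_in_window(store, w)
  if (n > point_threshold)
    mz_stop("visibility_guard",
            "window holds %d points, above the point threshold %d", n,
            point_threshold)
  if (rendered_count != n)
    mz_stop("visibility_guard",
            "client rendered %d of %d in-window points; refusing to mark unseen points",
            rendered_count, n)
  sel <- window_mask(store$points, w) & store$points$trace_id == 0L
  store$points[sel, "trace_id" := -1L]
  sum(sel)
}

#' Check every store invariant by full scan
#'
#' Verifies the partition law after arbitrary edit sequences: annotation
#' field ranges, envelope-via-trace mediation, noise exclusion from
#' envelopes, registration of every referenced trace/envelope id, and
#' agreement between each point's `envelope_id` and its trace's envelope.
#'
#' @param store An `mz_store`.
#' @return `TRUE` invisibly; raises a validation error on the first
#'   violation found.
#' @export
validate_store <- function(store) {
  stopifnot(inherits(store, "mz_store"))
  pts <- store$points
  validate_peak_points(data.table::copy(pts), where = "store")
  used_t <- unique(pts$trace_id[pts$trace_id > 0L])
  if (!all(used_t %in% store$traces$trace_id))
    mz_stop("validation", "point references unregistered trace id")
  used_e <- unique(pts$envelope_id[pts$envelope_id > 0L])
  if (!all(used_e %in% store$envelopes$envelope_id))
    mz_stop("validation", "point references unregistered envelope id")
  if (!all(store$traces$envelope_id %in% c(0L, store$envelopes$envelope_id)))
    mz_stop("validation", "trace references unregistered envelope id")
  expect_e <- trace_envelope(store, pts$trace_id)
  expect_e[is.na(expect_e)] <- 0L
  if (!all(pts$envelope_id == expect_e))
    mz_stop("validation", "point envelope_id disagrees with its trace's envelope")
  if (length(store$intensity_order) != nrow(pts) ||
      !setequal(store$intensity_order, pts$point_id))
    mz_stop("validation", "intensity registry is not a permutation of point ids")
  invisible(TRUE)
}
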