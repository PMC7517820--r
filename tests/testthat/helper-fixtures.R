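# Shared fixture builders and independent oracles. Oracles deliberately use
# plain vector filtering / sorting, never the package's index or stride code.

# uniform random point cloud with exponential intensities
random_cloud <- function(n, seed, mz_range = c(100, 1100), rt_range = c(0, 3600)) {
  withr::with_seed(seed, peak_points(
    mz = runif(n, mz_range[1], mz_range[2]),
    rt = runif(n, rt_range[1], rt_range[2]),
    intensity = rexp(n, rate = 1e-4)
  ))
}

# brute-force closed-window filter (linear scan oracle)
linear_filter <- function(pts, w) {
  keep <- pts$mz >= w$mz_min & pts$mz <= w$mz_max &
    pts$rt >= w$rt_min & pts$rt <= w$rt_max
  pts[keep, ]
}

# brute-force weighted-stride oracle: traversal order (mz, rt, id), equal
# point-count strides, per-stride intensity maximum with min-id tie-break
stride_oracle <- function(pts, limit) {
  pts <- pts[order(pts$mz, pts$rt, pts$point_id), ]
  n <- nrow(pts)
  if (limit == 0) return(pts[0, ])
  if (n <= limit) return(pts)
  stride <- floor((seq_len(n) - 1) * limit / n) + 1
  pick <- integer(0)
  for (s in unique(stride)) {
    idx <- which(stride == s)
    best <- idx[order(-pts$intensity[idx], pts$point_id[idx])[1]]
    pick <- c(pick, best)
  }
  pts[sort(pick), ]
}

# sample() without the scalar-x surprise
resample <- function(x, n = 1) x[sample.int(length(x), n)]

# a random window inside the cloud's extent
random_window <- function(pts) {
  a <- sort(runif(2, min(pts$mz), max(pts$mz)))
  b <- sort(runif(2, min(pts$rt), max(pts$rt)))
  mz_window(a[1], a[2], b[1], b[2])
}

# exhaustive traversal of a store's tree
walk_tree <- function(node, visit) {
  if (is.null(node)) return(invisible())
  visit(node)
  if (is.null(node$point_ids))
    for (ch in node$children) walk_tree(ch, visit)
  invisible()
}

set_equal_points <- function(a, b) {
  setequal(a$point_id, b$point_id)
}

# snapshot of the annotation state for reversibility checks
annotation_state <- function(store) {
  data.frame(point_id = store$points$point_id,
             trace_id = store$points$trace_id,
             envelope_id = store$points$envelope_id)
}
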