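#' Define an (m/z, RT) query window
#'
#' An axis-aligned rectangle in the (m/z, retention time) plane. All four
#' bounds are closed: a point sitting exactly on an edge is inside. Closed
#' semantics matter for curation, where boundary points must be selectable
#' by a rectangle drawn onto them.
#'
#' @param mz_min,mz_max Window m/z bounds, Thomson, `mz_min <= mz_max`.
#' @param rt_min,rt_max Window RT bounds, seconds, `rt_min <= rt_max`.
#' @return An object of class `mz_window`.
#' @examples
#' mz_window(500, 510, 0, 120)
#' @export
mz_window <- function(mz_min, mz_max, rt_min, rt_max) {
  for (v in list(mz_min, mz_max, rt_min, rt_max))
    if (!is_num1(v)) mz_stop("validation", "window bounds must be single numbers")
  if (mz_min > mz_max)
    mz_stop("validation", "window requires mz_min <= mz_max")
  if (rt_min > rt_max)
    mz_stop("validation", "window requires rt_min <= rt_max")
  structure(
    list(mz_min = as.numeric(mz_min), mz_max = as.numeric(mz_max),
         rt_min = as.numeric(rt_min), rt_max = as.numeric(rt_max)),
    class = "mz_window"
  )
}

as_mz_window <- function(w) {
  if (inherits(w, "mz_window")) return(w)
  if (is.list(w) && all(c("mz_min", "mz_max", "rt_min", "rt_max") %in% names(w)))
    return(mz_window(w$mz_min, w$mz_max, w$rt_min, w$rt_max))
  if (is.numeric(w) && length(w) == 4L)
    return(mz_window(w[[1]], w[[2]], w[[3]], w[[4]]))
  mz_stop("validation", "not interpretable as an (m/z, RT) window")
}

# closed-interval membership on all four bounds
window_mask <- function(pts, w) {
  pts$mz >= w$mz_min & pts$mz <= w$mz_max &
    pts$rt >= w$rt_min & pts$rt <= w$rt_max
}

windows_overlap <- function(a, b) {
  a$mz_min <= b$mz_max & a$mz_max >= b$mz_min &
    a$rt_min <= b$rt_max & a$rt_max >= b$rt_min
}

window_contains <- function(outer, inner) {
  outer$mz_min <= inner$mz_min & outer$mz_max >= inner$mz_max &
    outer$rt_min <= inner$rt_min & outer$rt_max >= inner$rt_max
}

#' @export
print.mz_window <- function(x, ...) {
  cat(sprintf("<mz_window> m/z [%g, %g] Th, RT [%g, %g] s\n",
              x$mz_min, x$mz_max, x$rt_min, x$rt_max))
  invisible(x)
}
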