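#' Construct a table of MS1 peak points
#'
#' A peak point is one MS1 measurement: mass-to-charge (`mz`, Thomson),
#' retention time (`rt`, seconds), and abundance (`intensity`, arbitrary
#' units), plus two mutable annotation fields. `trace_id` is 0 for an
#' unannotated point, -1 for a point marked as noise, and a positive
#' integer for membership in that isotopic trace. `envelope_id` is 0 or the
#' positive id of the isotopic envelope the point's trace belongs to.
#'
#' Annotation invariants enforced here and throughout the package:
#' `envelope_id > 0` implies `trace_id > 0` (envelope membership is
#' mediated by traces), and `trace_id == -1` implies `envelope_id == 0`
#' (noise is never part of an envelope).
#'
#' @param mz Numeric vector of mass-to-charge values, Thomson, > 0.
#' @param rt Numeric vector of retention times, seconds, >= 0.
#' @param intensity Numeric vector of abundances, >= 0.
#' @param point_id Integer ids, unique; defaults to `seq_along(mz)`.
#' @param trace_id Integer trace annotations (default 0 = unannotated).
#' @param envelope_id Integer envelope annotations (default 0).
#' @return A `data.table` with columns `point_id`, `mz`, `rt`, `intensity`,
#'   `trace_id`, `envelope_id`, sorted by `point_id`.
#' @examples
#' peak_points(mz = c(500.1, 500.6), rt = c(60, 60), intensity = c(10, 5))
#' @export
peak_points <- function(mz, rt, intensity,
                        point_id = seq_along(mz),
                        trace_id = 0L, envelope_id = 0L) {
  n <- length(mz)
  rec <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  pts <- data.table::data.table(
    point_id    = as.integer(rec(point_id)),
    mz          = as.numeric(mz),
    rt          = as.numeric(rec(rt)),
    intensity   = as.numeric(rec(intensity)),
    trace_id    = as.integer(rec(trace_id)),
    envelope_id = as.integer(rec(envelope_id))
  )
  validate_peak_points(pts)
}

#' Coerce a data frame to a validated peak-point table
#'
#' Accepts any data frame with at least `mz`, `rt` and `intensity` columns;
#' missing `point_id` is filled with the row sequence and missing
#' annotation columns with 0.
#'
#' @param x A data frame of points.
#' @return A validated `data.table` (see [peak_points()]).
#' @export
as_peak_points <- function(x) {
  if (!is.data.frame(x))
    mz_stop("validation", "points must be a data frame")
  x <- data.table::as.data.table(x)
  need <- c("mz", "rt", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    mz_stop("validation", "points table lacks column(s): %s",
            paste(miss, collapse = ", "))
  if (!"point_id" %in% names(x)) x[, "point_id" := seq_len(nrow(x))]
  if (!"trace_id" %in% names(x)) x[, "trace_id" := 0L]
  if (!"envelope_id" %in% names(x)) x[, "envelope_id" := 0L]
  pts <- x[, list(point_id = as.integer(point_id), mz = as.numeric(mz),
                  rt = as.numeric(rt), intensity = as.numeric(intensity),
                  trace_id = as.integer(trace_id),
                  envelope_id = as.integer(envelope_id))]
  validate_peak_points(pts)
}

validate_peak_points <- function(pts, where = "points") {
  bad_row <- function(cond) if (any(cond)) which(cond)[1L] else 0L
  if (anyNA(pts))
    mz_stop("validation", "%s: missing values at row %d", where,
            bad_row(rowSums(is.na(pts)) > 0))
  if (anyDuplicated(pts$point_id))
    mz_stop("identity_conflict", "%s: duplicate point_id %d", where,
            pts$point_id[anyDuplicated(pts$point_id)])
  if (any(pts$mz <= 0))
    mz_stop("validation", "%s: mz must be > 0 (row %d)", where,
            bad_row(pts$mz <= 0))
  if (any(pts$rt < 0))
    mz_stop("validation", "%s: rt must be >= 0 (row %d)", where,
            bad_row(pts$rt < 0))
  if (any(pts$intensity < 0))
    mz_stop("validation", "%s: intensity must be >= 0 (row %d)", where,
            bad_row(pts$intensity < 0))
  if (any(pts$trace_id < -1L))
    mz_stop("validation", "%s: trace_id must be >= -1 (row %d)", where,
            bad_row(pts$trace_id < -1L))
  if (any(pts$envelope_id < 0L))
    mz_stop("validation", "%s: envelope_id must be >= 0 (row %d)", where,
            bad_row(pts$envelope_id < 0L))
  viol <- pts$envelope_id > 0L & pts$trace_id <= 0L
  if (any(viol))
    mz_stop("validation",
            "%s: envelope_id > 0 requires trace_id > 0 (row %d)", where,
            bad_row(viol))
  viol <- pts$trace_id == -1L & pts$envelope_id != 0L
  if (any(viol))
    mz_stop("validation",
            "%s: noise points cannot carry an envelope_id (row %d)", where,
            bad_row(viol))
  data.table::setorderv(pts, "point_id")
  data.table::setkeyv(pts, "point_id")
  pts[]
}
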