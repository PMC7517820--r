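#' Read MS1 spectra from an mzML file into peak points
#'
#' Parses the file with mzR, keeps MS level-1 spectra only, and emits one
#' peak point per (m/z, intensity) pair. Retention time is the scan start
#' time converted to seconds regardless of the unit declared in the file
#' (minute-declared scan times are multiplied by 60 on ingest — a single
#' canonical unit avoids silent 60x errors downstream). Point ids are
#' assigned in file order starting at 1; annotations start at 0.
#'
#' @param path Path to an mzML file.
#' @return A list with elements `points` (a peak-point `data.table`) and
#'   `metadata` (list: `source_path`, `scan_count` of MS1 spectra,
#'   `rt_unit_declared` as written in the file, `ms1_point_count`).
#'   A file with no MS1 spectra yields zero points with a warning.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path))
    mz_stop("io", "file not found: %s", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) mz_stop("parse", "cannot parse mzML '%s': %s",
                                                 path, conditionMessage(e)))
  on.exit(try(mzR::close(handle), silent = TRUE))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) {
    warning("no MS1 spectra in ", path)
    return(list(points = peak_points(numeric(0), numeric(0), numeric(0)),
                metadata = list(source_path = path, scan_count = 0L,
                                rt_unit_declared = mzml_declared_rt_unit(path),
                                ms1_point_count = 0L)))
  }
  chunks <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    pk <- mzR::peaks(handle, ms1[i])
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2L)
    chunks[[i]] <- data.table::data.table(
      mz = pk[, 1L], rt = hdr$retentionTime[ms1[i]], intensity = pk[, 2L])
  }
  pts <- data.table::rbindlist(chunks)
  pts[, "point_id" := seq_len(nrow(pts))]
  list(points = as_peak_points(pts),
       metadata = list(source_path = path,
                       scan_count = length(ms1),
                       rt_unit_declared = mzml_declared_rt_unit(path),
                       ms1_point_count = nrow(pts)))
}

# Declared unit of the first scan start time cvParam (PSI-MS MS:1000016).
# Light text scan; mzR normalizes RT to seconds but does not report the
# unit the file declared.
mzml_declared_rt_unit <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  repeat {
    lines <- readLines(con, n = 200L, warn = FALSE)
    if (length(lines) == 0L) return(NA_character_)
    hit <- grep("MS:1000016", lines, value = TRUE, fixed = TRUE)
    if (length(hit)) {
      m <- regmatches(hit[1L], regexec('unitName="([^"]*)"', hit[1L]))[[1L]]
      if (length(m) == 2L)
        return(if (m[2L] %in% c("minute", "minutes")) "minutes" else "seconds")
      return("seconds")
    }
  }
}

csv_header <- "point_id,mz,rt,intensity,trace_id,envelope_id"

#' Export store annotations to CSV
#'
#' Writes the package's annotated CSV dialect: header
#' `point_id,mz,rt,intensity,trace_id,envelope_id`, then one row per
#' point in ascending point id. Noise points carry trace_id -1,
#' unannotated points 0. Doubles are rendered in the shortest decimal
#' form that parses back to the identical value, so
#' export -> import -> re-export is byte-identical.
#'
#' @param store An `mz_store`.
#' @param path Output file path.
#' @return The number of data rows written.
#' @export
export_annotations_csv <- function(store, path) {
  stopifnot(inherits(store, "mz_store"))
  pts <- data.table::copy(store$points)
  data.table::setorderv(pts, "point_id")
  lines <- c(csv_header,
             if (nrow(pts)) paste(pts$point_id, format_dbl(pts$mz),
                                  format_dbl(pts$rt), format_dbl(pts$intensity),
                                  pts$trace_id, pts$envelope_id, sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mz_stop("io", "cannot write %s", path)
  nrow(pts)
}

#' Import an annotated CSV into a new store
#'
#' Inverse of [export_annotations_csv()]: reconstructs the point table,
#' re-registers traces and envelopes from the id columns, and re-validates
#' every annotation invariant. A row violating an invariant (for example
#' `envelope_id > 0` with `trace_id <= 0`) raises a validation error
#' naming the row.
#'
#' @param path Path to a CSV in the annotated dialect.
#' @param leaf_capacity Passed to [build_index()].
#' @return An `mz_store`.
#' @export
import_annotations_csv <- function(path, leaf_capacity = 512L) {
  if (!file.exists(path))
    mz_stop("io", "file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || first != csv_header)
    mz_stop("parse", "'%s' does not carry the annotated CSV header", path)
  tab <- data.table::fread(path, header = TRUE, sep = ",",
                           colClasses = list(
                             integer = c("point_id", "trace_id", "envelope_id"),
                             numeric = c("mz", "rt", "intensity")))
  if (!identical(names(tab), strsplit(csv_header, ",")[[1L]]))
    mz_stop("parse", "'%s' does not match the annotated CSV dialect", path)
  build_index(tab, leaf_capacity = leaf_capacity)
}

#' Read a bookmark list from tab-separated text
#'
#' Dialect: one bookmark per line, `label<TAB>mz<TAB>rt` (label may be
#' empty; m/z in Thomson, RT in seconds). A header line is detected by a
#' non-numeric second field and skipped.
#'
#' @param path Path to a bookmark TSV.
#' @return A data frame with columns `label`, `mz`, `rt`.
#' @export
read_bookmarks_tsv <- function(path) {
  if (!file.exists(path))
    mz_stop("io", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines))
  out <- list()
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L)
      mz_stop("parse", "line %d: expected 3 tab-separated fields, got %d",
              i, length(f))
    mz <- suppressWarnings(as.numeric(f[2L]))
    rt <- suppressWarnings(as.numeric(f[3L]))
    if (k == 1L && is.na(mz)) next  # header row
    if (is.na(mz) || is.na(rt))
      mz_stop("parse", "line %d: non-numeric mz/rt field", i)
    if (mz <= 0 || rt < 0)
      mz_stop("validation", "line %d: require mz > 0 and rt >= 0", i)
    out[[length(out) + 1L]] <- list(label = f[1L], mz = mz, rt = rt)
  }
  if (!length(out))
    return(data.frame(label = character(0), mz = numeric(0), rt = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(label = vapply(out, `[[`, "", "label"),
             mz = vapply(out, `[[`, 0, "mz"),
             rt = vapply(out, `[[`, 0, "rt"),
             stringsAsFactors = FALSE)
}

#' Write a bookmark list as tab-separated text
#'
#' Emits the same dialect [read_bookmarks_tsv()] parses, with a
#' `label	mz	rt` header line; `read(write(x))` reproduces `x`.
#'
#' @param bookmarks Data frame with columns `label`, `mz`, `rt`.
#' @param path Output file path.
#' @return The number of bookmarks written.
#' @export
write_bookmarks_tsv <- function(bookmarks, path) {
  if (!is.data.frame(bookmarks) ||
      !all(c("label", "mz", "rt") %in% names(bookmarks)))
    mz_stop("validation", "bookmarks must have columns label, mz, rt")
  if (any(grepl("[\t\n]", bookmarks$label)))
    mz_stop("validation", "bookmark labels may not contain tabs or newlines")
  if (any(bookmarks$mz <= 0) || any(bookmarks$rt < 0))
    mz_stop("validation", "bookmarks require mz > 0 and rt >= 0")
  lines <- c("label\tmz\trt",
             if (nrow(bookmarks))
               paste(bookmarks$label, format_dbl(bookmarks$mz),
                     format_dbl(bookmarks$rt), sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mz_stop("io", "cannot write %s", path)
  nrow(bookmarks)
}
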