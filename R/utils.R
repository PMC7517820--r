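# internal helpers shared across modules

#' @import data.table
#' @importFrom stats rnorm runif rpois rexp
NULL

utils::globalVariables(c("point_id", "mz", "rt", "intensity", "trace_id",
                         "envelope_id", "k", "d2", "stride"))

# classed error so the API layer can map condition classes to HTTP statuses
mz_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(paste0("mzcurate_", class), "mzcurate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Shortest decimal rendering that parses back to the identical double.
# Needed so export -> import -> re-export is byte-identical while files
# stay human-readable (500.5 stays "500.5", not "500.50000000000000").
format_dbl <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (!is.finite(v)) { out[[i]] <- as.character(v); next }
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.16g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[[i]] <- s
  }
  out
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == trunc(x) && x >= min
}

is_num1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
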