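#' Expected m/z positions of an isotopic envelope at a given charge
#'
#' Isotopes of a molecule at charge state z appear ~1/z Thomson apart, so
#' the ruler anchored at `anchor_mz` marks `anchor_mz + k/charge` for
#' k = 0, 1, 2, ... Positions are truncated at the window's upper m/z
#' bound (bounds checking keeps the ruler inside the plot range).
#'
#' @param anchor_mz Ruler anchor, Thomson; must lie within the window's
#'   m/z bounds.
#' @param charge Charge state z, integer >= 1.
#' @param window An [mz_window()] giving the current plot range.
#' @return Numeric vector of m/z positions, starting at `anchor_mz`,
#'   consecutive positions exactly 1/charge apart, all <= `window$mz_max`.
#' @examples
#' ruler_positions(500, charge = 2, mz_window(499, 501.6, 0, 1))
#' @export
ruler_positions <- function(anchor_mz, charge, window) {
  w <- as_mz_window(window)
  if (!is_count(charge, min = 1L))
    mz_stop("invalid_charge", "charge must be an integer >= 1")
  if (!is_num1(anchor_mz) || anchor_mz < w$mz_min || anchor_mz > w$mz_max)
    mz_stop("validation", "anchor_mz must lie within the window m/z bounds")
  k_max <- max(0, ceiling((w$mz_max - anchor_mz) * charge) + 1)
  pos <- anchor_mz + (0:k_max) / charge
  pos[pos <= w$mz_max]
}

#' Guard-rail bounds around an m/z of interest
#'
#' Isotopic traces run in near-straight lines along a given m/z; a pair
#' of parallel rails at `center_mz +/- width/2` helps judge which points
#' belong to a trace. Rails are clipped to the window's m/z bounds.
#'
#' @param center_mz Rail center, Thomson.
#' @param width Total rail separation, Thomson, > 0.
#' @param window An [mz_window()] giving the current plot range.
#' @return Named numeric vector `c(low_mz = , high_mz = )`.
#' @examples
#' guardrail_bounds(500, 0.02, mz_window(499, 501, 0, 1))
#' @export
guardrail_bounds <- function(center_mz, width, window) {
  w <- as_mz_window(window)
  if (!is_num1(width) || width <= 0)
    mz_stop("validation", "width must be > 0")
  if (!is_num1(center_mz))
    mz_stop("validation", "center_mz must be a single number")
  c(low_mz = max(center_mz - width / 2, w$mz_min),
    high_mz = min(center_mz + width / 2, w$mz_max))
}
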