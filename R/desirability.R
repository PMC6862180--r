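#' Larger-the-better desirability ramp
#'
#' Linear ramp from 0 at `lo` to 1 at `hi`, clipped outside; with
#' `exponent` the in-between section is raised to that power (default 1,
#' a straight ramp).
#'
#' @param value response value(s).
#' @param lo lower specification limit.
#' @param hi upper specification limit (`lo < hi`).
#' @param exponent shape power applied to the normalized value.
#' @return desirability in \[0, 1\].
#' @export
d_ramp_up <- function(value, lo, hi, exponent = 1) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("invalid bounds: need lo < hi")
  pmin(1, pmax(0, (value - lo) / (hi - lo)))^exponent
}

#' Smaller-the-better desirability ramp
#'
#' Linear ramp from 1 at `lo` down to 0 at `hi`, clipped outside.
#'
#' @inheritParams d_ramp_up
#' @return desirability in \[0, 1\].
#' @export
d_ramp_down <- function(value, lo, hi, exponent = 1) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("invalid bounds: need lo < hi")
  pmin(1, pmax(0, (value - hi) / (lo - hi)))^exponent
}

#' Derive desirability bounds from observed responses
#'
#' The study's specification limits are not published, so by default the
#' bounds are the extrema of the observed cell means, optionally widened
#' symmetrically by `margin` times the observed range.
#'
#' @param values observed response values (>= 2 distinct values).
#' @param margin fractional widening of the range on each side.
#' @return list with `lo`, `hi`.
#' @export
bounds_from_responses <- function(values, margin = 0) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2)
    stop("responses are constant; supply explicit bounds instead")
  r <- range(v)
  w <- margin * diff(r)
  list(lo = r[1] - w, hi = r[2] + w)
}

#' Total performance TP = d1 * d2^2
#'
#' Scalarizes the two desirabilities (d1 for EDWIN-C, d2 for system time)
#' into the quantity the genetic algorithm maximizes; the squared d2 weights
#' the system-time response more strongly.
#'
#' @param d1,d2 desirabilities in \[0, 1\].
#' @return TP in \[0, 1\].
#' @export
total_performance <- function(d1, d2) {
  if (any(!is.finite(c(d1, d2))) || any(c(d1, d2) < 0 | c(d1, d2) > 1))
    stop("d1 and d2 must lie in [0, 1]")
  d1 * d2^2
}

#' Map the two responses of a cell table to desirabilities
#'
#' Following the published response orientations, EDWIN-C enters as
#' larger-the-better (`d1`, ramp up) and system time as smaller-the-better
#' (`d2`, ramp down). `edwinc_orientation = "stb"` flips the EDWIN-C ramp
#' for the clinically intuitive direction (a crowding index one wants low).
#'
#' @param cells data.frame with columns `mean_EDWINC`, `mean_ST`.
#' @param bounds list with elements `edwinc` and `st`, each a
#'   `list(lo, hi)`; defaults to [bounds_from_responses()] of the table.
#' @param edwinc_orientation `"ltb"` (published) or `"stb"`.
#' @return `cells` with columns `d1`, `d2`, `tp` appended; the bounds used
#'   are attached as attribute `"bounds"`.
#' @export
add_desirabilities <- function(cells, bounds = NULL,
                               edwinc_orientation = c("ltb", "stb")) {
  edwinc_orientation <- match.arg(edwinc_orientation)
  if (is.null(bounds))
    bounds <- list(edwinc = bounds_from_responses(cells$mean_EDWINC),
                   st = bounds_from_responses(cells$mean_ST))
  be <- bounds$edwinc; bs <- bounds$st
  cells$d1 <- if (edwinc_orientation == "ltb")
    d_ramp_up(cells$mean_EDWINC, be$lo, be$hi)
  else d_ramp_down(cells$mean_EDWINC, be$lo, be$hi)
  cells$d2 <- d_ramp_down(cells$mean_ST, bs$lo, bs$hi)
  cells$tp <- total_performance(cells$d1, cells$d2)
  attr(cells, "bounds") <- bounds
  cells
}
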