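#' Autoregulatory flow-OPP curve specification
#'
#' Anchor parameters of the piecewise-linear relationship between ocular
#' perfusion pressure and relative blood flow used by the synthetic
#' cohort generator.  The curve has three segments: a linear decline
#' from zero flow at `zero_flow_opp` up to the lower edge of the
#' autoregulatory plateau, a flat plateau (autoregulation holds flow
#' constant), and a linear rise above the plateau (autoregulation
#' overwhelmed by high perfusion pressure).  The curve is normalized so
#' that the reference operating point (`reference_opp`, by default
#' OPP = 83 mmHg, i.e. MAP 93 minus IOP 10) maps to exactly 100\%.
#'
#' The default plateau of 50--90 mmHg OPP corresponds to the 60--100
#' mmHg MAP range over which flow is observed to plateau at baseline
#' IOP (10 mmHg).  The default slope above the plateau brings flow to
#' roughly 200\% at the starting point of an acutely hypertensive
#' cohort (MAP 159, IOP 10, OPP 149 mmHg).
#'
#' @param plateau_range Lower and upper OPP bounds of the autoregulatory
#'   plateau, mmHg.
#' @param plateau_flow Flow on the plateau before normalization, \%.
#' @param zero_flow_opp OPP at which flow reaches zero, mmHg.
#' @param slope_above Slope of the segment above the plateau,
#'   \% per mmHg.
#' @param reference_opp OPP of the normalization anchor, mmHg.
#'
#' @return An object of class `flow_curve`.
#' @export
flow_curve_spec <- function(plateau_range = c(50, 90),
                            plateau_flow = 100,
                            zero_flow_opp = 0,
                            slope_above = 100 / 59,
                            reference_opp = 83) {
  if (length(plateau_range) != 2L || diff(plateau_range) < 0) {
    stop("'plateau_range' must be c(lower, upper) with lower <= upper",
         call. = FALSE)
  }
  if (zero_flow_opp >= plateau_range[1]) {
    stop("anchors out of order: 'zero_flow_opp' must lie below the plateau",
         call. = FALSE)
  }
  if (plateau_flow <= 0 || slope_above < 0) {
    stop("'plateau_flow' must be positive and 'slope_above' non-negative",
         call. = FALSE)
  }
  structure(list(plateau_range = as.numeric(plateau_range),
                 plateau_flow = as.numeric(plateau_flow),
                 zero_flow_opp = as.numeric(zero_flow_opp),
                 slope_above = as.numeric(slope_above),
                 reference_opp = as.numeric(reference_opp)),
            class = "flow_curve")
}

#' Relative blood flow implied by perfusion pressure
#'
#' Evaluates the piecewise-linear autoregulation curve of a
#' [flow_curve_spec()] and rescales it so the reference operating point
#' returns 100\%.  OPP at or below the zero-flow anchor (including
#' negative OPP, which arises when IOP exceeds MAP) yields zero flow.
#'
#' @param opp Ocular perfusion pressure, mmHg (vectorized).
#' @param curve A [flow_curve_spec()].
#' @return Relative flow, \% of the reference operating point.
#' @export
#' @examples
#' flow_from_opp(c(0, 40, 83, 149), flow_curve_spec())
flow_from_opp <- function(opp, curve = flow_curve_spec()) {
  stopifnot(inherits(curve, "flow_curve"))
  raw <- flow_curve_raw(opp, curve)
  ref <- flow_curve_raw(curve$reference_opp, curve)
  if (ref <= 0) {
    stop("reference OPP lies at or below the zero-flow anchor", call. = FALSE)
  }
  100 * raw / ref
}

flow_curve_raw <- function(opp, curve) {
  lo <- curve$plateau_range[1]; hi <- curve$plateau_range[2]
  z <- curve$zero_flow_opp; f <- curve$plateau_flow
  below <- f * (opp - z) / (lo - z)
  above <- f + curve$slope_above * (opp - hi)
  out <- ifelse(opp < lo, below, ifelse(opp > hi, above, f))
  pmax(0, out)
}
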