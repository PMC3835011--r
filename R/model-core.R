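#' Oxygen extraction ratio as a function of relative blood flow
#'
#' The OER-flow law: an exponential that decays with increasing flow and
#' is anchored to pass exactly through the baseline operating point
#' (100\% blood flow, onefold OER),
#' \deqn{OER(f) = a e^{b f} + \left(1 - a e^{100 b}\right).}
#' With `a > 0` and `b < 0` the curve is strictly decreasing in flow:
#' reduced perfusion is compensated by increased extraction, while
#' hyperperfusion drives extraction below onefold.  The vertical span of
#' the curve (its limit at zero flow minus its limit at infinite flow)
#' equals `a`, the OER responsiveness.
#'
#' @param flow Relative blood flow, \% of baseline (baseline = 100).
#'   Vectorized; must be non-negative.
#' @param params A [model_params()] object (only `a` and `b` are used).
#'
#' @return OER in fold units (baseline = 1), same length as `flow`.
#' @export
#' @examples
#' oer_from_flow(c(0, 100, 200), published_params())
oer_from_flow <- function(flow, params) {
  params <- as_model_params(params)
  check_nonneg(flow, "flow")
  a <- params[["a"]]; b <- params[["b"]]
  a * exp(b * flow) + (1 - a * exp(100 * b))
}

#' Relative oxygen consumption
#'
#' Oxygen consumption expressed as a percentage of baseline: the product
#' of oxygen delivery (relative blood flow, with arterial oxygen content
#' held fixed at its baseline value) and the oxygen extraction ratio,
#' `flow(\%) * OER(fold)`.  Equals 100 at baseline flow by construction.
#'
#' @inheritParams oer_from_flow
#' @return Consumption in \% of baseline, same length as `flow`.
#' @export
#' @examples
#' oxygen_consumption(c(0, 100, 200), published_params())
oxygen_consumption <- function(flow, params) {
  flow * oer_from_flow(flow, params)
}

#' IOP-induced mechanical stress on neurons
#'
#' The two-line (hinge) component: zero up to the threshold `t`, then
#' linear with slope `m` above it,
#' \deqn{IOP_M(IOP) = \min(0,\; m (IOP - t)).}
#' The value is expressed in percentage points of baseline ERG amplitude
#' and is always \eqn{\le 0}; it is continuous at the threshold.
#'
#' @param iop Intraocular pressure, mmHg.  Vectorized; must be
#'   non-negative.
#' @param params A [model_params()] object (only `t` and `m` are used).
#'
#' @return Mechanical stress in \% baseline ERG (\eqn{\le 0}).
#' @export
#' @examples
#' iopm_from_iop(c(40, 50, 120), published_params())
iopm_from_iop <- function(iop, params) {
  params <- as_model_params(params)
  check_nonneg(iop, "iop")
  t <- params[["t"]]; m <- params[["m"]]
  ifelse(iop > t, m * (iop - t), 0)
}

#' Mechanical stress as a function of ocular perfusion pressure
#'
#' Re-expresses [iopm_from_iop()] in terms of OPP by substituting
#' `IOP = MAP - OPP`.
#'
#' @param opp Ocular perfusion pressure, mmHg.
#' @param map Mean arterial pressure, mmHg (must be positive).
#' @inheritParams iopm_from_iop
#' @return Mechanical stress in \% baseline ERG (\eqn{\le 0}).
#' @export
iopm_from_opp <- function(opp, map, params) {
  if (any(map <= 0)) stop("'map' must be positive", call. = FALSE)
  iopm_from_iop(map - opp, params)
}

#' Relative ERG amplitude predicted by the full model
#'
#' Combines the vascular and mechanical components additively, in
#' percentage points of baseline amplitude:
#' \deqn{ERG(\%) = \max\{0,\; flow \cdot OER(flow) + IOP_M(IOP)\}.}
#' Relative blood flow is an input (a measured quantity), never
#' predicted internally.  Predicted amplitudes are clamped at 0\%
#' because negative amplitudes are unphysical; there is no upper clamp.
#' At the baseline operating point (flow = 100\%, IOP below threshold)
#' the model returns exactly 100\%.
#'
#' @param flow Relative blood flow, \% of baseline.
#' @param iop Intraocular pressure, mmHg (recycled against `flow`).
#' @param params A [model_params()] object.
#'
#' @return Predicted ERG amplitude, \% of baseline (never negative).
#' @export
#' @examples
#' erg_model(flow = 100, iop = 10, params = published_params())
erg_model <- function(flow, iop, params) {
  params <- as_model_params(params)
  pmax(0, oxygen_consumption(flow, params) + iopm_from_iop(iop, params))
}

#' Critical IOP of the mechanical-stress component
#'
#' Scans the two-line mechanical-stress function over a fine IOP grid
#' and returns the largest IOP at which it is still zero, i.e. the
#' critical pressure above which mechanical stress begins to attenuate
#' the ERG.
#'
#' @param params A [model_params()] object.
#' @param from,to,by Scan grid in mmHg (default 10 to 120 in 0.1 steps).
#' @return The critical IOP in mmHg.
#' @export
#' @examples
#' mechanical_threshold(published_params())
mechanical_threshold <- function(params, from = 10, to = 120, by = 0.1) {
  grid <- seq(from, to, by = by)
  vals <- iopm_from_iop(grid, params)
  zero <- grid[vals == 0]
  if (length(zero) == 0L) {
    stop("mechanical stress is non-zero over the whole scan grid",
         call. = FALSE)
  }
  max(zero)
}

check_nonneg <- function(x, name) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("'", name, "' must be non-negative", call. = FALSE)
  }
  invisible(x)
}
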