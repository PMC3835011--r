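#' Model parameter vector
#'
#' Bundle the four parameters of the retinal-function model into a
#' validated object.  `a` and `b` shape the oxygen-extraction-ratio (OER)
#' response to blood flow; `t` and `m` define the two-line
#' mechanical-stress component of IOP.
#'
#' @param a OER responsiveness: vertical span of the exponential OER-flow
#'   curve (fold, dimensionless).  Must be positive.
#' @param b Exponential decay rate of the OER-flow curve
#'   (per \% blood flow).  Must be negative; the half-life of the
#'   exponential term is `-log(2)/b` percentage points of flow.
#' @param t IOP threshold above which mechanical stress attenuates the
#'   ERG (mmHg).  Must lie in \[10, 120\].
#' @param m Mechanical-stress slope above threshold
#'   (\% ERG per mmHg).  Must be non-positive.
#'
#' @return An object of class `model_params`: a named numeric vector
#'   with elements `a`, `b`, `t`, `m`.
#' @seealso [published_params()] for the reference best-fit vector.
#' @export
#' @examples
#' model_params(a = 4.03, b = -0.019, t = 50, m = -0.70)
model_params <- function(a, b, t, m) {
  p <- c(a = as.numeric(a), b = as.numeric(b),
         t = as.numeric(t), m = as.numeric(m))
  validate_params(p)
  structure(p, class = "model_params")
}

#' Reference best-fit parameters
#'
#' The published best-fit parameterization of the model, obtained from
#' the acutely hypertensive (high blood pressure) cohort:
#' `a = 4.03` fold, `b = -0.019` per \% flow, `t = 50.0` mmHg,
#' `m = -0.70` \% per mmHg.
#'
#' @return A [model_params()] object.
#' @export
#' @examples
#' published_params()
published_params <- function() {
  model_params(a = 4.03, b = -0.019, t = 50.0, m = -0.70)
}

validate_params <- function(p) {
  if (length(p) != 4L || anyNA(p)) {
    stop("parameters must be four finite numbers (a, b, t, m)", call. = FALSE)
  }
  if (p[["a"]] <= 0) {
    stop("parameter-domain error: 'a' must be > 0 (got ", p[["a"]], ")",
         call. = FALSE)
  }
  if (p[["b"]] >= 0) {
    stop("parameter-domain error: 'b' must be < 0 (got ", p[["b"]], ")",
         call. = FALSE)
  }
  if (p[["t"]] < 10 || p[["t"]] > 120) {
    stop("parameter-domain error: 't' must lie in [10, 120] mmHg (got ",
         p[["t"]], ")", call. = FALSE)
  }
  if (p[["m"]] > 0) {
    stop("parameter-domain error: 'm' must be <= 0 (got ", p[["m"]], ")",
         call. = FALSE)
  }
  invisible(p)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || !all(c("a", "b", "t", "m") %in% names(x))) {
    if (length(x) == 4L) names(x) <- c("a", "b", "t", "m")
    else stop("cannot interpret 'params'; supply model_params(a, b, t, m)",
              call. = FALSE)
  }
  model_params(x[["a"]], x[["b"]], x[["t"]], x[["m"]])
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  a = %.4g fold (OER span)\n", x[["a"]]))
  cat(sprintf("  b = %.4g per %% flow (OER decay; half-life %.3g %%)\n",
              x[["b"]], -log(2) / x[["b"]]))
  cat(sprintf("  t = %.4g mmHg (mechanical threshold)\n", x[["t"]]))
  cat(sprintf("  m = %.4g %% ERG per mmHg (stress slope)\n", x[["m"]]))
  invisible(x)
}
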