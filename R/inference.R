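#' Default parameter bounds for fitting
#'
#' The box over which parameters are searched: `a` in (0, 20] fold,
#' `b` in \[-0.2, 0) per \% flow, `t` in \[10, 120\] mmHg, `m` in
#' \[-5, 0\] \% per mmHg.  Generous relative to physiology, but finite
#' so the multi-start design and the grid-search oracle are well
#' defined.
#'
#' @return A list with numeric vectors `lower` and `upper`, named
#'   `a`, `b`, `t`, `m`.
#' @export
default_bounds <- function() {
  list(lower = c(a = 1e-6, b = -0.2, t = 10, m = -5),
       upper = c(a = 20, b = -1e-8, t = 120, m = 0))
}

# Sum of squared residuals between observed ERG and the forward model.
# Parameters outside the box are clamped and penalized quadratically,
# which keeps the derivative-free search inside the box without flat
# regions.
sse_objective <- function(theta, flow, iop, erg, lo, hi) {
  .Call(C_sse, as.numeric(theta), flow, iop, erg, lo, hi)
}

# Pure-R rendering of the same penalized objective; the compiled
# version must agree with it to machine precision (checked in tests).
sse_objective_r <- function(theta, flow, iop, erg, lo, hi) {
  th <- pmin(pmax(theta, lo), hi)
  pen <- sum((theta - th)^2)
  a <- th[1]; b <- th[2]; t <- th[3]; m <- th[4]
  cons <- flow * (a * exp(b * flow) + (1 - a * exp(100 * b)))
  iopm <- ifelse(iop > t, m * (iop - t), 0)
  pred <- pmax(0, cons + iopm)
  sum((erg - pred)^2) + 1e6 * pen
}

# One local derivative-free minimization with Nelder-Mead restarts until
# the objective stops improving (the simplex can collapse prematurely on
# the piecewise-smooth hinge objective; restarting re-expands it).
local_fit <- function(start, flow, iop, erg, lower, upper,
                      max_restarts = 3, reltol = 1e-12) {
  best <- stats::optim(start, sse_objective, flow = flow, iop = iop,
                       erg = erg, lo = lower, hi = upper,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = reltol))
  for (i in seq_len(max_restarts)) {
    nxt <- stats::optim(best$par, sse_objective, flow = flow, iop = iop,
                        erg = erg, lo = lower, hi = upper,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = reltol))
    improved <- best$value - nxt$value
    if (nxt$value <= best$value) best <- nxt
    if (improved < max(1e-12, 1e-10 * abs(best$value))) break
  }
  best
}

#' Fit the retinal-function model by least squares
#'
#' Estimates the four parameters (a, b, t, m) by minimizing the
#' sum-of-squares merit function between observed relative ERG
#' amplitudes and the forward model evaluated at the measured relative
#' blood flow and the protocol IOP.  Because the mechanical-stress
#' hinge makes the objective only piecewise smooth, optimization uses a
#' multi-start protocol: `n_starts` Latin-hypercube starting points
#' over the bounds box (plus any user-supplied `init`), each refined by
#' a derivative-free Nelder-Mead search with restarts; the solution
#' with the lowest SSE is returned (ties broken by the smaller
#' parameter norm).  The result does not depend on the order of the
#' records.
#'
#' When the data carry per-point SEMs (`erg_sem_pct` all positive), a
#' chi-square goodness of fit is attached with
#' `df = n_points - 4` (all four parameters estimated).
#'
#' @param data Data frame of measurement records with columns
#'   `flow_pct`, `erg_pct`, `iop_mmHg` (and optionally `erg_sem_pct`).
#'   At least 5 records are required, spanning IOPs on both sides of
#'   any plausible threshold for `t` to be identifiable.
#' @param init Optional [model_params()] (or named vector) added to the
#'   start set.
#' @param bounds Parameter box as returned by [default_bounds()].
#' @param n_starts Number of Latin-hypercube starting points
#'   (default 16).
#' @param seed RNG seed controlling the start design.
#'
#' @return An object of class `erg_fit`: a list with `params`
#'   ([model_params()]), `sse`, `fitted`, `residuals`, `gof` (a
#'   [chi_square_gof()] result or `NULL`), `flags` (character; e.g.
#'   `"t_unidentifiable"` when no observed IOP exceeds the fitted
#'   threshold, with `t` then reported at the data/box edge),
#'   `convergence`, `n_starts`, `seed`, `bounds` and the `data` used.
#' @export
#' @examples
#' cfg <- cohort_config(noise_sd = 0, n_animals = 1, seed = 1)
#' fit <- fit_erg_model(cohort_means(generate_cohort(cfg)), seed = 1)
#' fit$params
fit_erg_model <- function(data, init = NULL, bounds = default_bounds(),
                          n_starts = 16, seed = NULL) {
  req <- c("flow_pct", "erg_pct", "iop_mmHg")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[, req])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 5) {
    stop("need at least 5 complete records to fit four parameters",
         call. = FALSE)
  }
  flow <- as.numeric(data$flow_pct)
  iop <- as.numeric(data$iop_mmHg)
  erg <- as.numeric(data$erg_pct)
  lower <- as.numeric(bounds$lower); upper <- as.numeric(bounds$upper)
  names(lower) <- names(upper) <- c("a", "b", "t", "m")

  starts <- with_seed(seed, lhs_starts(n_starts, lower, upper))
  if (!is.null(init)) {
    starts <- rbind(unclass(as_model_params(init)), starts)
  }

  fits <- apply(starts, 1, local_fit, flow = flow, iop = iop, erg = erg,
                lower = lower, upper = upper, simplify = FALSE)
  sses <- vapply(fits, `[[`, numeric(1), "value")
  norms <- vapply(fits, function(f) sqrt(sum(f$par^2)), numeric(1))
  best <- fits[[order(sses, norms)[1]]]
  if (!is.finite(best$value)) {
    stop("optimizer failed to converge from every start; SSEs: ",
         paste(signif(sses, 3), collapse = ", "), call. = FALSE)
  }

  theta <- pmin(pmax(best$par, lower), upper)
  names(theta) <- c("a", "b", "t", "m")
  params <- model_params(theta[["a"]], theta[["b"]], theta[["t"]],
                         theta[["m"]])
  fitted <- erg_model(flow, iop, params)

  flags <- character()
  if (max(iop) <= theta[["t"]]) {
    # no observation above the hinge: t (and m) carry no information
    flags <- c(flags, "t_unidentifiable")
  }

  gof <- NULL
  if ("erg_sem_pct" %in% names(data) &&
      isTRUE(all(data$erg_sem_pct > 0)) && nrow(data) > 4) {
    gof <- chi_square_gof(erg, fitted, data$erg_sem_pct, n_free_params = 4)
  }

  structure(list(params = params,
                 sse = best$value,
                 fitted = fitted,
                 residuals = erg - fitted,
                 gof = gof,
                 flags = flags,
                 convergence = best$convergence,
                 n_starts = nrow(starts),
                 seed = seed,
                 bounds = bounds,
                 data = tibble::as_tibble(data)),
            class = "erg_fit")
}

lhs_starts <- function(n, lower, upper) {
  if (n <= 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(lower)))
  }
  u <- lhs::randomLHS(n, length(lower))
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

#' @export
print.erg_fit <- function(x, ...) {
  cat("Retinal-function model fit (", nrow(x$data), " records, ",
      x$n_starts, " starts)\n", sep = "")
  print(x$params)
  cat(sprintf("  SSE = %.6g\n", x$sse))
  if (!is.null(x$gof)) {
    cat(sprintf("  chi2 = %.4g on %d df, Q = %.3g (%s fit)\n",
                x$gof$chi2, x$gof$df, x$gof$q, x$gof$grade))
  }
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "),
                               "\n")
  invisible(x)
}

#' Chi-square goodness of fit with Q-probability grading
#'
#' Computes \eqn{\chi^2 = \sum_i ((obs_i - pred_i)/sem_i)^2}, which
#' weighs the model-data discrepancy by the per-point dispersion, and
#' the upper-tail probability \eqn{Q(\chi^2 | df)} (the regularized
#' incomplete gamma function \eqn{Q(df/2, \chi^2/2)}) that a
#' discrepancy at least this large arises by chance.  The fit is graded
#' `"poor"` when Q < 0.001, `"acceptable"` for Q in \[0.001, 0.1\] (both
#' boundaries inclusive) and `"good"` above 0.1.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param sem Per-point standard errors (all positive; recycled if
#'   scalar).
#' @param n_free_params Number of fitted parameters to subtract from
#'   the degrees of freedom: 4 when grading a fit of the full model, 0
#'   in pure-prediction mode (parameters fixed in advance).
#'
#' @return An object of class `gof`: list with `chi2`, `df`, `q`,
#'   `grade`.
#' @export
#' @examples
#' chi_square_gof(c(99, 101, 100, 98, 102, 100), rep(100, 6), sem = 1.5)
chi_square_gof <- function(observed, predicted, sem, n_free_params = 0) {
  n <- length(observed)
  if (length(predicted) != n) {
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  }
  sem <- rep_len(sem, n)
  if (any(!is.finite(sem)) || any(sem <= 0)) {
    stop("all 'sem' must be positive and finite", call. = FALSE)
  }
  df <- n - as.integer(n_free_params)
  if (df <= 0) {
    stop("degrees of freedom must be positive (n = ", n,
         ", free parameters = ", n_free_params, ")", call. = FALSE)
  }
  chi2 <- sum(((observed - predicted) / sem)^2)
  q <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, q = q, grade = gof_grade(q)),
            class = "gof")
}

gof_grade <- function(q) {
  if (q < 0.001) "poor" else if (q <= 0.1) "acceptable" else "good"
}

#' @export
print.gof <- function(x, ...) {
  cat(sprintf("chi2 = %.4g on %d df; Q = %.4g -> %s fit\n",
              x$chi2, x$df, x$q, x$grade))
  invisible(x)
}

#' Predict ERG amplitudes for a cohort with fixed parameters
#'
#' Evaluates the forward model on each record without any refitting
#' (the cross-cohort validation mode: parameters estimated in one
#' cohort are carried to another, and the agreement is graded with
#' [chi_square_gof()] in prediction mode, `n_free_params = 0`).
#'
#' @param data Data frame with columns `flow_pct` and `iop_mmHg`; may
#'   be empty.
#' @param params A [model_params()] object.
#' @return Numeric vector of predicted ERG amplitudes (\% baseline),
#'   one per record.
#' @export
predict_cohort <- function(data, params) {
  if (nrow(data) == 0L) return(numeric(0))
  erg_model(data$flow_pct, data$iop_mmHg, params)
}
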