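#' Bootstrap confidence intervals for the fitted parameters
#'
#' Monte-Carlo estimate of the sampling distribution of the four model
#' parameters.  By default each replicate resamples whole records with
#' replacement (case resampling, robust to heteroscedastic ERG noise)
#' and refits the model; `type = "residual"` instead resamples the fit
#' residuals with replacement and adds them to the fitted values,
#' keeping the pressure/flow design fixed.  Per-parameter 95\%
#' intervals are the 2.5 and 97.5 percentiles of the replicate
#' estimates.  Replicates whose refit fails (or leaves the threshold
#' unidentifiable under case resampling) are dropped and counted; a
#' warning is raised when more than 20\% are dropped.  Results are
#' fully reproducible given `seed`.
#'
#' Replicate refits start from the original point estimate (plus a few
#' Latin-hypercube starts when `n_starts > 1`), the usual shortcut for
#' bootstrap refitting.
#'
#' @param fit An [fit_erg_model()] result.
#' @param n_boot Number of bootstrap replicates (at least 100; default
#'   1000).
#' @param seed RNG seed.
#' @param type `"case"` (default) or `"residual"` resampling.
#' @param n_starts Starts per replicate refit (default 1, from the
#'   original estimate).
#'
#' @return A tibble with one row per parameter: `parameter`,
#'   `estimate`, `lower`, `upper` (percentile 95\% CI), with attributes
#'   `n_boot`, `n_failed`, `seed`, `type` and `replicates` (the matrix
#'   of replicate estimates).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' fit <- fit_erg_model(cohort_means(generate_cohort(cfg)), seed = 7)
#' bootstrap_ci(fit, n_boot = 100, seed = 7)
bootstrap_ci <- function(fit, n_boot = 1000, seed = NULL,
                         type = c("case", "residual"), n_starts = 1) {
  stopifnot(inherits(fit, "erg_fit"))
  type <- match.arg(type)
  if (n_boot < 100) stop("'n_boot' must be at least 100", call. = FALSE)
  data <- as.data.frame(fit$data)
  n <- nrow(data)
  seeds <- child_seeds(seed, n_boot)
  est <- unclass(fit$params)

  reps <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                 dimnames = list(NULL, c("a", "b", "t", "m")))
  for (i in seq_len(n_boot)) {
    boot_data <- with_seed(seeds[[i]], {
      if (type == "case") {
        data[sample.int(n, n, replace = TRUE), , drop = FALSE]
      } else {
        d <- data
        d$erg_pct <- pmax(0, fit$fitted +
                            sample(fit$residuals, n, replace = TRUE))
        d
      }
    })
    refit <- tryCatch(
      fit_erg_model(boot_data, init = est, n_starts = n_starts - 1,
                    bounds = fit$bounds, seed = seeds[[i]]),
      error = function(e) NULL)
    if (!is.null(refit) && !("t_unidentifiable" %in% refit$flags)) {
      reps[i, ] <- unclass(refit$params)
    }
  }

  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates dropped (> 20%%)",
                    n_failed, n_boot), call. = FALSE)
  }
  if (sum(ok) < 2) stop("too few successful bootstrap replicates",
                        call. = FALSE)
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(parameter = colnames(reps),
                        estimate = unname(est[colnames(reps)]),
                        lower = qs[1, ],
                        upper = qs[2, ])
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  attr(out, "type") <- type
  attr(out, "replicates") <- reps[ok, , drop = FALSE]
  out
}
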