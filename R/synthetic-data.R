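#' Synthetic cohort configuration
#'
#' Settings for the synthetic cohort generator, which emulates the
#' acute pressure-challenge protocol: an IOP staircase (default 10 to
#' 120 mmHg in 5 mmHg steps, 23 levels) at a fixed mean arterial
#' pressure, a flow-OPP autoregulation curve, forward-model oxygen
#' tension and ERG amplitude, and additive Gaussian measurement noise
#' truncated at zero.
#'
#' The three MAP defaults used in the study design are 159 (high), 104
#' (moderate) and 61 mmHg (low); `map_level` takes any positive value.
#'
#' @param map_level Mean arterial pressure held during the staircase,
#'   mmHg.
#' @param iop_start,iop_stop,iop_step IOP staircase specification, mmHg.
#' @param flow_curve A [flow_curve_spec()] giving the flow-OPP
#'   relationship for this cohort.
#' @param gen_params Ground-truth [model_params()] used to generate
#'   oxygen tension and ERG (default [published_params()]).
#' @param noise_sd Named per-channel Gaussian noise SD in percentage
#'   points, with names `flow`, `erg`, `po2`; a single number is
#'   recycled to all three channels.
#' @param n_animals Animals per arm.
#' @param group Cohort label stored in generated records; defaults to
#'   `"high"`, `"moderate"`, `"low"` when `map_level` matches a study
#'   default, else `"map<level>"`.
#' @param seed RNG seed for reproducible generation.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(map_level = 159,
                          iop_start = 10, iop_stop = 120, iop_step = 5,
                          flow_curve = flow_curve_spec(),
                          gen_params = published_params(),
                          noise_sd = c(flow = 8, erg = 8, po2 = 8),
                          n_animals = 6,
                          group = NULL,
                          seed = NULL) {
  if (iop_step <= 0) stop("'iop_step' must be positive", call. = FALSE)
  if (iop_stop < iop_start) stop("'iop_stop' must be >= 'iop_start'",
                                 call. = FALSE)
  if (map_level <= 0) stop("'map_level' must be positive", call. = FALSE)
  if (n_animals < 1) stop("'n_animals' must be at least 1", call. = FALSE)
  if (length(noise_sd) == 1L) {
    noise_sd <- c(flow = noise_sd, erg = noise_sd, po2 = noise_sd)
  }
  if (!all(c("flow", "erg", "po2") %in% names(noise_sd)) ||
      any(noise_sd < 0)) {
    stop("'noise_sd' must be non-negative with names flow, erg, po2",
         call. = FALSE)
  }
  if (is.null(group)) {
    group <- switch(as.character(map_level),
                    "159" = "high", "104" = "moderate", "61" = "low",
                    paste0("map", map_level))
  }
  structure(list(map_level = map_level,
                 iop_start = iop_start, iop_stop = iop_stop,
                 iop_step = iop_step,
                 flow_curve = flow_curve,
                 gen_params = as_model_params(gen_params),
                 noise_sd = noise_sd[c("flow", "erg", "po2")],
                 n_animals = as.integer(n_animals),
                 group = group,
                 seed = seed),
            class = "cohort_config")
}

#' Pressure states of the staircase protocol
#'
#' Expands a [cohort_config()] into the ordered sequence of protocol
#' steps, one row per IOP level, with OPP = MAP - IOP on every row.
#' The default staircase (10 to 120 by 5 mmHg) yields 23 states.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `step`, `iop_mmHg`, `map_mmHg`,
#'   `opp_mmHg`.
#' @export
#' @examples
#' protocol_grid(cohort_config(map_level = 159))
protocol_grid <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  iop <- seq(config$iop_start, config$iop_stop, by = config$iop_step)
  tibble::tibble(step = seq_along(iop),
                 iop_mmHg = iop,
                 map_mmHg = config$map_level,
                 opp_mmHg = config$map_level - iop)
}

#' Generate a synthetic cohort
#'
#' Simulates per-animal measurements over the staircase protocol.  For
#' each step the noise-free truth is: flow from the autoregulation
#' curve at that OPP; oxygen tension (as \% baseline, a surrogate for
#' oxygen consumption) from the OER-flow law applied to the true flow;
#' and ERG amplitude from the full forward model.  Independent Gaussian
#' noise with the configured per-channel SD is then added per animal
#' and channel, and all channels are truncated at zero.  Records are
#' reproducible given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble of per-animal records with columns `group`,
#'   `animal_id`, `step`, `iop_mmHg`, `map_mmHg`, `flow_pct`,
#'   `erg_pct`, `po2_pct`, plus the noise-free truth in attributes
#'   `"truth"` and the generating config in `"config"`.
#' @seealso [cohort_means()] to collapse to group-mean records with
#'   SEMs, the form used for fitting.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- protocol_grid(config)
  flow_true <- flow_from_opp(grid$opp_mmHg, config$flow_curve)
  po2_true <- oxygen_consumption(flow_true, config$gen_params)
  erg_true <- erg_model(flow_true, grid$iop_mmHg, config$gen_params)
  n <- config$n_animals
  k <- nrow(grid)
  sd <- config$noise_sd
  noisy <- with_seed(config$seed, {
    list(flow = rep(flow_true, times = n) + stats::rnorm(n * k, 0, sd[["flow"]]),
         erg  = rep(erg_true,  times = n) + stats::rnorm(n * k, 0, sd[["erg"]]),
         po2  = rep(po2_true,  times = n) + stats::rnorm(n * k, 0, sd[["po2"]]))
  })
  out <- tibble::tibble(
    group = config$group,
    animal_id = rep(seq_len(n), each = k),
    step = rep(grid$step, times = n),
    iop_mmHg = rep(grid$iop_mmHg, times = n),
    map_mmHg = config$map_level,
    flow_pct = pmax(0, noisy$flow),
    erg_pct = pmax(0, noisy$erg),
    po2_pct = pmax(0, noisy$po2)
  )
  attr(out, "truth") <- tibble::tibble(
    grid, flow_pct = flow_true, erg_pct = erg_true, po2_pct = po2_true)
  attr(out, "config") <- config
  out
}

#' Collapse per-animal records to group means with SEMs
#'
#' Produces one record per protocol step: the across-animal mean of
#' each channel together with its standard error (SD / sqrt(n)), the
#' form in which staircase data are usually plotted and fitted.
#'
#' @param animals Per-animal records from [generate_cohort()] (or any
#'   data frame with the same columns).
#' @return A tibble with one row per step: `group`, `step`, `iop_mmHg`,
#'   `map_mmHg`, means `flow_pct`, `erg_pct`, `po2_pct`, their SEMs
#'   (`*_sem_pct`) and `n` (animals contributing).
#' @export
cohort_means <- function(animals) {
  req <- c("step", "iop_mmHg", "map_mmHg", "flow_pct", "erg_pct")
  missing <- setdiff(req, names(animals))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_po2 <- "po2_pct" %in% names(animals)
  split_idx <- split(seq_len(nrow(animals)), animals$step)
  rows <- lapply(split_idx, function(i) {
    d <- animals[i, ]
    n <- nrow(d)
    sem <- function(x) stats::sd(x) / sqrt(n)
    tibble::tibble(
      group = d$group[1] %||% NA_character_,
      step = d$step[1],
      iop_mmHg = d$iop_mmHg[1],
      map_mmHg = d$map_mmHg[1],
      flow_pct = mean(d$flow_pct),
      erg_pct = mean(d$erg_pct),
      po2_pct = if (has_po2) mean(d$po2_pct) else NA_real_,
      flow_sem_pct = sem(d$flow_pct),
      erg_sem_pct = sem(d$erg_pct),
      po2_sem_pct = if (has_po2) sem(d$po2_pct) else NA_real_,
      n = n
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$step), ]
}
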