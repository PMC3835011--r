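# Shared fixtures and the brute-force grid-search oracle.

table1 <- c(a = 4.03, b = -0.019, t = 50, m = -0.70)

# Noise-free group-mean records on the default 23-step staircase.
noise_free_means <- function(map_level = 159) {
  cohort_means(generate_cohort(
    cohort_config(map_level = map_level, noise_sd = 0, n_animals = 1)))
}

# Exhaustive SSE minimum over a 4-D parameter lattice, computed by
# direct enumeration (vectorized in chunks).  Independent oracle for
# the optimizer: written from the model formulas, not via fit_erg_model.
grid_search_sse <- function(flow, iop, erg,
                            a_grid, b_grid, t_grid, m_grid, chunk = 200) {
  nr <- length(flow)
  ab <- expand.grid(a = a_grid, b = b_grid)
  cons <- matrix(0, nrow(ab), nr)
  for (i in seq_len(nr)) {
    cons[, i] <- flow[i] * (ab$a * exp(ab$b * flow[i]) +
                              1 - ab$a * exp(100 * ab$b))
  }
  tm <- expand.grid(t = t_grid, m = m_grid)
  iopm <- matrix(0, nrow(tm), nr)
  for (i in seq_len(nr)) {
    iopm[, i] <- ifelse(iop[i] > tm$t, tm$m * (iop[i] - tm$t), 0)
  }
  best <- Inf
  for (s0 in seq(1, nrow(tm), by = chunk)) {
    idx <- s0:min(s0 + chunk - 1, nrow(tm))
    sse <- matrix(0, nrow(ab), length(idx))
    for (i in seq_len(nr)) {
      pred <- pmax(outer(cons[, i], iopm[idx, i], "+"), 0)
      sse <- sse + (erg[i] - pred)^2
    }
    best <- min(best, min(sse))
  }
  best
}

# Random valid parameter vectors for property-style tests.
random_params <- function(n, seed = 99) {
  withr::with_seed(seed, replicate(n, simplify = FALSE, {
    model_params(a = stats::runif(1, 0.5, 10),
                 b = stats::runif(1, -0.1, -0.001),
                 t = stats::runif(1, 15, 110),
                 m = stats::runif(1, -3, 0))
  }))
}
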