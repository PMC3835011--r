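test_that("compiled objective agrees with its pure-R rendering", {
  m <- noise_free_means()
  b <- default_bounds()
  withr::with_seed(3, {
    for (i in 1:20) {
      th <- c(runif(1, -1, 25), runif(1, -0.3, 0.05),
              runif(1, 0, 150), runif(1, -6, 1))
      expect_equal(
        opperg:::sse_objective(th, m$flow_pct, m$iop_mmHg, m$erg_pct,
                               as.numeric(b$lower), as.numeric(b$upper)),
        opperg:::sse_objective_r(th, m$flow_pct, m$iop_mmHg, m$erg_pct,
                                 as.numeric(b$lower), as.numeric(b$upper)),
        tolerance = 1e-12)
    }
  })
})

test_that("data equal to model predictions are refit with zero SSE", {
  theta0 <- model_params(a = 3, b = -0.015, t = 60, m = -0.5)
  g <- protocol_grid(cohort_config(map_level = 120))
  flow <- flow_from_opp(g$opp_mmHg)
  data <- tibble::tibble(iop_mmHg = g$iop_mmHg, flow_pct = flow,
                         erg_pct = erg_model(flow, g$iop_mmHg, theta0))
  fit <- fit_erg_model(data, init = theta0, n_starts = 4, seed = 2)
  expect_lt(fit$sse, 1e-12)
  expect_equal(unclass(fit$params), unclass(theta0), tolerance = 1e-6)
})

test_that("fitted values do not depend on record order", {
  m <- cohort_means(generate_cohort(cohort_config(seed = 21)))
  fit1 <- fit_erg_model(m, seed = 5)
  fit2 <- fit_erg_model(m[rev(seq_len(nrow(m))), ], seed = 5)
  # identical up to the non-associativity of summation over records
  expect_equal(unclass(fit1$params), unclass(fit2$params),
               tolerance = 1e-9)
  expect_equal(fit1$sse, fit2$sse, tolerance = 1e-12)
})

test_that("threshold is flagged unidentifiable without data above it", {
  cfg <- cohort_config(iop_stop = 40, seed = 31)
  m <- cohort_means(generate_cohort(cfg))
  fit <- fit_erg_model(m, seed = 31)
  expect_true("t_unidentifiable" %in% fit$flags)
})

test_that("fit refuses unusable inputs", {
  m <- noise_free_means()
  expect_error(fit_erg_model(m[, c("iop_mmHg", "flow_pct")]), "erg_pct")
  expect_error(fit_erg_model(m[1:3, ]), "at least 5")
})

test_that("optimizer beats a coarse exhaustive lattice on a small instance", {
  m <- cohort_means(generate_cohort(cohort_config(seed = 11)))
  rec <- m[c(1, 4, 7, 10, 13, 16, 19, 23), ]
  fit <- fit_erg_model(rec, seed = 11)
  oracle <- grid_search_sse(rec$flow_pct, rec$iop_mmHg, rec$erg_pct,
                            a_grid = seq(1, 20, 1),
                            b_grid = seq(-0.2, -0.01, 0.01),
                            t_grid = seq(10, 120, 10),
                            m_grid = seq(-5, 0, 0.25))
  expect_lte(fit$sse, oracle)
})

test_that("chi-square statistic, Q and grade follow the definitions", {
  # perfect agreement: chi2 = 0, Q = 1, graded good
  g <- chi_square_gof(rep(100, 7), rep(100, 7), sem = 2, n_free_params = 2)
  expect_identical(g$chi2, 0)
  expect_identical(g$df, 5L)
  expect_identical(g$q, 1)
  expect_identical(g$grade, "good")
  # chi2 is the SEM-weighted sum of squared discrepancies
  g2 <- chi_square_gof(c(102, 99), c(100, 100), sem = c(2, 1))
  expect_equal(g2$chi2, 1^2 + 1^2)
  # grade bands: Q < 0.001 poor, 0.001..0.1 acceptable (boundaries
  # inclusive), above 0.1 good
  expect_identical(opperg:::gof_grade(5e-4), "poor")
  expect_identical(opperg:::gof_grade(0.001), "acceptable")
  expect_identical(opperg:::gof_grade(0.05), "acceptable")
  expect_identical(opperg:::gof_grade(0.1), "acceptable")
  expect_identical(opperg:::gof_grade(0.101), "good")
  expect_identical(opperg:::gof_grade(0.858), "good")
})

test_that("chi-square guards its preconditions", {
  expect_error(chi_square_gof(1:3, 1:2, sem = 1), "equal length")
  expect_error(chi_square_gof(1:3, 1:3, sem = c(1, 0, 1)), "positive")
  expect_error(chi_square_gof(1:3, 1:3, sem = 1, n_free_params = 3),
               "degrees of freedom")
})

test_that("a fit on SEM-carrying records attaches a graded chi-square", {
  m <- cohort_means(generate_cohort(cohort_config(seed = 2)))
  fit <- fit_erg_model(m, seed = 2)
  expect_s3_class(fit$gof, "gof")
  expect_identical(fit$gof$df, nrow(m) - 4L)
  expect_true(fit$gof$grade %in% c("poor", "acceptable", "good"))
})

test_that("prediction mode evaluates the fixed model per record", {
  expect_identical(predict_cohort(tibble::tibble(flow_pct = numeric(0),
                                                 iop_mmHg = numeric(0)),
                                  published_params()),
                   numeric(0))
  one <- tibble::tibble(flow_pct = 100, iop_mmHg = 10)
  expect_identical(predict_cohort(one, published_params()), 100)
  # self-consistency: generator output at default noise predicts well
  m <- cohort_means(generate_cohort(cohort_config(seed = 13)))
  pred <- predict_cohort(m, published_params())
  g <- chi_square_gof(m$erg_pct, pred, m$erg_sem_pct, n_free_params = 0)
  expect_true(g$grade %in% c("acceptable", "good"))
})
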