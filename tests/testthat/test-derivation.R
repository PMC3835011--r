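test_that("baseline normalization rescales a raw series to percent", {
  # raw vitreal pO2 in mmHg: baseline 31.5 maps to 100
  expect_equal(normalize_to_baseline(c(31.5, 15.75)), c(100, 50))
  expect_equal(normalize_to_baseline(rep(7.3, 5)), rep(100, 5))
  expect_equal(normalize_to_baseline(c(2, 1, 0)), c(100, 50, 0))
  expect_identical(normalize_to_baseline(numeric(0)), numeric(0))
  expect_error(normalize_to_baseline(c(0, 1)), "baseline")
  expect_error(normalize_to_baseline(c(-2, 1)), "baseline")
})

test_that("putative OER is the pO2/flow ratio with a low-flow guard", {
  expect_identical(derive_oer(100, 100), 1)
  expect_identical(derive_oer(50, 25), 2)
  expect_true(is.na(derive_oer(60, 0)))
  expect_true(is.na(derive_oer(60, 2)))    # at the floor: undefined
  expect_identical(derive_oer(60, 2, flow_floor = 1), 30)
})

test_that("putative mechanical stress is function minus oxygen tension", {
  expect_identical(derive_iopm(100, 100), 0)
  expect_identical(derive_iopm(40, 80), -40)
  expect_identical(derive_iopm(97, 97), 0)
  # noise-positive values are reported, not clipped
  expect_identical(derive_iopm(102, 99), 3)
})

test_that("noise-free derivation round-trips the generating curves", {
  # generator output is already on the common baseline scale, so no
  # renormalization: the high-MAP cohort starts at ~200% flow
  cfg <- cohort_config(noise_sd = 0, n_animals = 1)
  m <- cohort_means(generate_cohort(cfg))
  d <- derive_cohort(m, renormalize = FALSE)
  expect_true(all(d$flag == "ok"))
  expect_equal(d$oer_putative, oer_from_flow(m$flow_pct, cfg$gen_params),
               tolerance = 1e-12)
  expect_equal(d$iopm_putative, iopm_from_iop(m$iop_mmHg, cfg$gen_params),
               tolerance = 1e-12)
  # and the comparison grades the agreement as perfect
  cmp <- compare_derived_to_model(d, cfg$gen_params,
                                  sem_oer = 0.05, sem_iopm = 2)
  expect_gt(cmp$oer$q, 1 - 1e-6)
  expect_gt(cmp$iopm$q, 1 - 1e-6)
  expect_identical(cmp$oer$grade, "good")
  expect_identical(cmp$iopm$grade, "good")
})

test_that("self-normalized normotensive data anchor and round-trip", {
  # a cohort whose baseline sits at the reference operating point:
  # renormalization is then an exact no-op and the identities hold on
  # every record with defined flow and an unclamped prediction
  cfg <- cohort_config(map_level = 93, noise_sd = 0, n_animals = 1)
  m <- cohort_means(generate_cohort(cfg))
  d <- derive_cohort(m)   # renormalize = TRUE
  expect_equal(d$oer_putative[1], 1)
  expect_equal(d$iopm_putative[1], 0)
  ok <- d$flag == "ok" & m$erg_pct > 0
  expect_equal(d$oer_putative[ok],
               oer_from_flow(m$flow_pct[ok], cfg$gen_params),
               tolerance = 1e-12)
  expect_equal(d$iopm_putative[ok],
               iopm_from_iop(m$iop_mmHg[ok], cfg$gen_params),
               tolerance = 1e-12)
})

test_that("renormalization anchors the baseline record at (1, 0)", {
  x <- cohort_means(generate_cohort(cohort_config(seed = 55)))
  d <- derive_cohort(x)
  expect_equal(d$oer_putative[1], 1)
  expect_equal(d$iopm_putative[1], 0)
})

test_that("collapsed flow is flagged rather than divided by", {
  # low blood pressure: OPP reaches zero inside the staircase
  cfg <- cohort_config(map_level = 61, noise_sd = 0, n_animals = 1)
  d <- derive_cohort(cohort_means(generate_cohort(cfg)))
  expect_true(any(d$flag == "low_flow"))
  expect_true(all(is.na(d$oer_putative[d$flag == "low_flow"])))
  expect_true(all(!is.na(d$iopm_putative)))  # difference needs no flow
})

test_that("derived-agreement experiment passes at default noise", {
  # derived points from noisy cohorts (n = 11 animals, the size of a
  # simultaneous-measurement arm) grade well against the generating
  # curves when weighted by the known generative SEMs; with correct
  # weights q is uniform, so "good" should dominate and "poor" should
  # be rare
  n_animals <- 11
  sem_ch <- 8 / sqrt(n_animals)          # per-channel SEM of a step mean
  seeds <- opperg:::child_seeds(77, 20)
  qs <- t(vapply(seeds, function(s) {
    cfg <- cohort_config(n_animals = n_animals, seed = s)
    m <- cohort_means(generate_cohort(cfg))
    truth <- attr(generate_cohort(
      cohort_config(n_animals = 1, noise_sd = 0)), "truth")
    d <- derive_cohort(m, renormalize = FALSE)
    # delta-method SEMs of the pO2/flow ratio and the ERG - pO2
    # difference at the noise-free operating points
    sem_oer <- sqrt((sem_ch / truth$flow_pct)^2 +
                      (truth$po2_pct * sem_ch / truth$flow_pct^2)^2)
    sem_iopm <- sqrt(2) * sem_ch
    cmp <- compare_derived_to_model(d, published_params(),
                                    sem_oer = sem_oer,
                                    sem_iopm = sem_iopm)
    c(cmp$oer$q, cmp$iopm$q)
  }, numeric(2)))
  # both panels at least acceptable in nearly every seed,
  # and jointly good in the majority
  acceptable <- qs[, 1] > 0.001 & qs[, 2] > 0.001
  good <- qs[, 1] > 0.1 & qs[, 2] > 0.1
  expect_gte(mean(acceptable), 0.9)
  expect_gt(mean(good), 0.5)
})
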