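test_that("the same seed reproduces a cohort byte-for-byte", {
  cfg <- sim_config(n_subjects = 5, n_streamlines = 3, n_points = c(5, 9),
                    subject_effect_sd = 0.3, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$bundles, b$bundles)
  expect_identical(a$design, b$design)
})

test_that("per-subject substreams make subject data independent of cohort size", {
  cfg5 <- sim_config(n_subjects = 5, n_streamlines = 2, n_points = 6, seed = 11)
  cfg3 <- sim_config(n_subjects = 3, n_streamlines = 2, n_points = 6, seed = 11)
  a <- simulate_cohort(cfg5)
  b <- simulate_cohort(cfg3)
  expect_identical(a$bundles[1:3], b$bundles)
})

test_that("configs with non-positive subject scale are rejected", {
  cfg <- sim_config(n_subjects = 10, gamma = c(0.5, 0.1), delta = c(0.01, -0.5),
                    seed = 3)
  expect_error(simulate_cohort(cfg), "non-positive scale")
})

test_that("true quantile coefficients follow gamma + delta * F^{-1}(tau)", {
  # symmetric noise: median coefficients are the location part
  cfg <- sim_config(n_subjects = 2, gamma = c(0.5), delta = c(0.1), seed = 1)
  expect_equal(true_quantile_coefficients(cfg, 0.5), 0.5)
  # gaussian noise + gaussian subject effect of sd 1: variance addition
  cfg2 <- sim_config(n_subjects = 2, gamma = c(0.4, 0.1), delta = c(0.1, 0.05),
                     subject_effect_sd = 1, seed = 1)
  expect_equal(true_quantile_coefficients(cfg2, 0.8),
               c(0.4, 0.1) + c(0.1, 0.05) * sqrt(2) * qnorm(0.8))
  # delta = 0 collapses all quantile levels onto the location coefficients
  cfg3 <- sim_config(n_subjects = 2, gamma = c(0.3, 0.2), delta = c(0.1, 0),
                     seed = 1)
  betas <- sapply(c(0.1, 0.5, 0.9), function(t)
    true_quantile_coefficients(cfg3, t)[2])
  expect_equal(betas, rep(0.2, 3))
  # tau outside the open unit interval is rejected (uniform has bounded support)
  cfg4 <- sim_config(n_subjects = 2, noise_family = "uniform", seed = 1)
  expect_error(true_quantile_coefficients(cfg4, 1.0), "inside")
  expect_error(true_quantile_coefficients(cfg4, 0), "inside")
})

test_that("numerically convolved quantiles match Monte-Carlo quantiles of eps + b", {
  cfg <- sim_config(n_subjects = 2, gamma = 0, delta = 1, noise_family = "t",
                    noise_df = 6, subject_effect_sd = 0.7, seed = 1)
  draws <- withr::with_seed(99, {
    rt(2e5, df = 6) / sqrt(6 / 4) + rnorm(2e5, sd = 0.7)
  })
  for (tau in c(0.1, 0.5, 0.9)) {
    truth <- true_quantile_coefficients(cfg, tau) # gamma=0, delta=1 => F^{-1}
    mc <- quantile(draws, tau, names = FALSE)
    expect_lt(abs(truth - mc), 0.03)
  }
})

test_that("generated values follow the location-scale law at the median", {
  # pooled median of a single subject's points converges to X'gamma for
  # symmetric noise with no subject effect
  cfg <- sim_config(n_subjects = 6, n_streamlines = 20, n_points = 50,
                    gamma = c(0.5, 0.2), delta = c(0.1, 0), seed = 21)
  coh <- simulate_cohort(cfg)
  for (i in seq_len(6)) {
    med <- median(unlist(lapply(coh$bundles[[i]]$streamlines, `[[`, "value")))
    truth <- sum(coh$design[i, ] * cfg$gamma)
    expect_lt(abs(med - truth), 0.025)
  }
})

test_that("a positive subject effect induces positive intraclass correlation", {
  cfg <- sim_config(n_subjects = 40, n_streamlines = 4, n_points = 10,
                    subject_effect_sd = 1, seed = 5)
  pool <- pool_bundles(simulate_cohort(cfg)$bundles)
  expect_gt(sample_icc(pool), 0.2)
  cfg0 <- sim_config(n_subjects = 40, n_streamlines = 4, n_points = 10,
                     subject_effect_sd = 0, seed = 5)
  pool0 <- pool_bundles(simulate_cohort(cfg0)$bundles)
  expect_lt(abs(sample_icc(pool0)), 0.1)
})

test_that("tube geometry shapes values from core to surface", {
  cfg <- sim_config(n_subjects = 4, n_streamlines = 40, n_points = 12,
                    gamma = c(0.5, 0), delta = c(0.05, 0), geometry = "tube",
                    tube_contrast = 0.3, seed = 13)
  coh <- simulate_cohort(cfg)
  b <- coh$bundles[[1]]
  rad <- vapply(b$streamlines, function(s) {
    mid <- s[round(nrow(s) / 2), ]
    sqrt((mid$x - 2 * sin(pi * 0.5))^2 + mid$y^2)
  }, numeric(1))
  mv <- vapply(b$streamlines, function(s) mean(s$value), numeric(1))
  # inner third of streamlines should carry higher values than outer third
  expect_gt(mean(mv[rad < quantile(rad, 1 / 3)]),
            mean(mv[rad > quantile(rad, 2 / 3)]))
})

test_that("streamline point counts honor the configured range", {
  cfg <- sim_config(n_subjects = 3, n_streamlines = 30, n_points = c(4, 8),
                    seed = 2)
  coh <- simulate_cohort(cfg)
  np <- unlist(lapply(coh$bundles, function(b)
    vapply(b$streamlines, nrow, integer(1))))
  expect_true(all(np >= 4 & np <= 8))
  expect_gt(length(unique(np)), 1)
})
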