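test_that("tract means are plain unweighted point averages", {
  expect_equal(mean_per_subject(toy_bundle("s", list(c(0.2, 0.4)))), 0.3)
  expect_equal(mean_per_subject(toy_bundle("s", list(rep(0.7, 3), rep(0.7, 5)))),
               0.7)
  # mean of per-subject means != pooled mean when point counts differ
  a <- toy_bundle("a", list(c(0, 0)))        # mean 0, 2 points
  b <- toy_bundle("b", list(c(1, 1, 1, 1)))  # mean 1, 4 points
  M <- mean_summary(list(a, b))
  pooled <- mean(c(0, 0, 1, 1, 1, 1))
  expect_equal(unname(mean(M)), 0.5)
  expect_false(isTRUE(all.equal(mean(M), pooled)))
})

test_that("mean regression matches closed-form OLS", {
  ids <- sprintf("s%d", 1:8)
  M <- withr::with_seed(10, rnorm(8, 0.5, 0.05))
  names(M) <- ids
  X <- matrix(1, 8, 1, dimnames = list(ids, "(Intercept)"))
  f <- fit_mean_regression(M, X)
  expect_equal(unname(f$coefficients), mean(M))
  expect_equal(unname(f$se), sd(M) / sqrt(8))
  expect_equal(f$df_residual, 7)
  # noiseless linear response: zero residuals, zero residual variance
  X2 <- cbind(`(Intercept)` = 1, x = 1:8)
  rownames(X2) <- ids
  f2 <- fit_mean_regression(setNames(drop(X2 %*% c(2, 0.5)), ids), X2)
  expect_lt(f2$sigma2, 1e-20)
  expect_equal(unname(f2$coefficients), c(2, 0.5))
  # permuting subjects leaves the statistics unchanged
  perm <- withr::with_seed(11, sample(8))
  f3 <- fit_mean_regression(M[perm], X)
  expect_equal(f3$t_scores, f$t_scores)
  expect_equal(f3$p_values, f$p_values)
})

test_that("a straight streamline with arc-length scalar resamples to (0, 0.5, 1)", {
  b <- new_subject_bundle("s", list(
    data.frame(x = c(0, 1, 2, 3, 4), y = 0, z = 0,
               value = c(0, 0.25, 0.5, 0.75, 1))))
  expect_equal(as.numeric(afq_profile(b, L = 3, weighting = "uniform")),
               c(0, 0.5, 1))
  expect_equal(as.numeric(afq_profile(b, L = 5, weighting = "uniform")),
               c(0, 0.25, 0.5, 0.75, 1))
})

test_that("profiles are invariant to streamline duplication and point density", {
  cfg <- sim_config(n_subjects = 2, n_streamlines = 8, n_points = 15,
                    geometry = "tube", seed = 19)
  b <- simulate_cohort(cfg)$bundles[[1]]
  p1 <- afq_profile(b, L = 12, weighting = "uniform")
  dup <- b; dup$streamlines <- c(b$streamlines, b$streamlines)
  p2 <- afq_profile(dup, L = 12, weighting = "uniform")
  expect_equal(as.numeric(p2), as.numeric(p1), tolerance = 1e-12)
  # doubling points by midpoint interpolation barely moves the profile
  dense <- b
  dense$streamlines <- lapply(b$streamlines, function(s) {
    n <- nrow(s)
    mid <- (s[-n, c("x", "y", "z", "value")] + s[-1, c("x", "y", "z", "value")]) / 2
    out <- s[rep(seq_len(n), each = 2)[-2 * n], ]
    out[seq(2, 2 * n - 2, by = 2), ] <- mid
    out
  })
  p3 <- afq_profile(dense, L = 12, weighting = "uniform")
  expect_equal(as.numeric(p3), as.numeric(p1), tolerance = 1e-6)
})

test_that("orientation harmonization makes profiles flip-invariant", {
  cfg <- sim_config(n_subjects = 2, n_streamlines = 10, n_points = 20,
                    geometry = "tube", seed = 23)
  b <- simulate_cohort(cfg)$bundles[[1]]
  for (weighting in c("uniform", "gaussian_core")) {
    p1 <- afq_profile(b, L = 15, weighting = weighting)
    flipped <- b
    flipped$streamlines[[3]] <- flipped$streamlines[[3]][20:1, ]
    flipped$streamlines[[7]] <- flipped$streamlines[[7]][20:1, ]
    p2 <- afq_profile(flipped, L = 15, weighting = weighting)
    expect_equal(as.numeric(p2), as.numeric(p1), tolerance = 1e-10)
  }
})

test_that("gaussian-core weighting down-weights an aberrant streamline", {
  # nine coherent streamlines at value 0.5, one far-away outlier at 0.9
  mk <- function(offset, v) data.frame(x = offset, y = seq(0, 10, length.out = 8),
                                       z = 0, value = v)
  sls <- c(lapply(seq(-0.4, 0.4, length.out = 9), mk, v = 0.5),
           list(mk(50, 0.9)))
  b <- new_subject_bundle("s", sls)
  pu <- afq_profile(b, L = 5, weighting = "uniform")
  pg <- afq_profile(b, L = 5, weighting = "gaussian_core")
  expect_true(all(pg < pu))
  expect_lt(max(abs(pg - 0.5)), 0.02)
})

test_that("profile regression is per-location OLS with BH over locations", {
  ids <- sprintf("s%d", 1:10)
  X <- cbind(`(Intercept)` = 1, x = withr::with_seed(3, rnorm(10)))
  rownames(X) <- ids
  attr(X, "scalar_cols") <- "x"
  # noiseless linear profiles: zero residuals everywhere
  beta_l <- rbind(seq(0.3, 0.5, length.out = 6), seq(0.01, 0.06, length.out = 6))
  T_mat <- X %*% beta_l
  rownames(T_mat) <- ids
  f <- fit_profile_regression(T_mat, X)
  expect_equal(unname(f$coefficients), unname(t(beta_l)))
  expect_true(all(f$sigma2 < 1e-20))
  # identical data at every location: identical fits, BH leaves the
  # (all-equal) p-values unchanged
  T_same <- matrix(rep(withr::with_seed(4, 0.5 + 0.02 * X[, 2] + rnorm(10, 0, 0.01)),
                       4), ncol = 4)
  rownames(T_same) <- ids
  f2 <- fit_profile_regression(T_same, X)
  expect_equal(f2$p_values[1, ], f2$p_values[3, ])
  expect_equal(unname(f2$p_adjusted[, "x"]), unname(f2$p_values[, "x"]))
})

test_that("cohort profile matrices share one orientation reference", {
  cfg <- sim_config(n_subjects = 5, n_streamlines = 6, n_points = 12,
                    geometry = "tube", seed = 29)
  coh <- simulate_cohort(cfg)
  T_mat <- afq_profile_matrix(coh$bundles, L = 10, weighting = "uniform")
  expect_equal(dim(T_mat), c(5L, 10L))
  expect_equal(rownames(T_mat), names(coh$bundles))
  expect_true(all(is.finite(T_mat)))
  expect_false(is.null(attr(T_mat, "orientation_reference")))
})
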