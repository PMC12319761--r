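covariate_fixture <- function() {
  data.frame(subject_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
             sex = c("female", "male", "female", "male", "female", "male"),
             age = c(25, 30, 22, 36, 28, 33),
             ReadEng = c(10, 20, 30, 15, 25, 12))
}

test_that("the sex-stratified design rows are built exactly as specified", {
  cov <- covariate_fixture()
  X <- build_design(cov, "ReadEng")
  expect_equal(colnames(X), c("I_Female", "I_Male", "Age:I_Male",
                              "Scalar:I_Female", "Scalar:I_Male"))
  s1 <- (cov$ReadEng - 10) / 20  # min-max scaled scalar
  expect_equal(unname(unclass(X)["s1", ]), c(1, 0, 0, s1[1], 0))
  expect_equal(unname(unclass(X)["s4", ]), c(0, 1, 36, 0, s1[4]))
  expect_true(all(X[, "Scalar:I_Female"] + X[, "Scalar:I_Male"] >= 0 &
                  X[, "Scalar:I_Female"] + X[, "Scalar:I_Male"] <= 1))
  expect_equal(attr(X, "scalar_cols"), c("Scalar:I_Female", "Scalar:I_Male"))
  expect_equal(unname(attr(X, "scalar_scaling")), c(10, 30))
  # each row carries exactly one nonzero sex indicator
  expect_true(all(X[, "I_Female"] + X[, "I_Male"] == 1))
})

test_that("min-max scaling maps {10, 20, 30} to {0, 0.5, 1}", {
  cov <- data.frame(subject_id = sprintf("s%d", 1:6),
                    sex = c("female", "male", "female", "male", "female", "male"),
                    age = c(25, 30, 22, 36, 29, 24),
                    ReadEng = c(10, 20, 30, 25, 22, 14))
  X <- build_design(cov, "ReadEng")
  expect_equal(unname(X[, "Scalar:I_Female"] + X[, "Scalar:I_Male"]),
               (cov$ReadEng - 10) / 20)
  expect_equal(sort(unname(X[c("s1", "s2", "s3"), "Scalar:I_Female"] +
                             X[c("s1", "s2", "s3"), "Scalar:I_Male"])),
               c(0, 0.5, 1))
})

test_that("the symmetric-age preset adds Age x I_Female", {
  X <- build_design(covariate_fixture(), "ReadEng",
                    preset = "sex_stratified_sym_age")
  expect_true("Age:I_Female" %in% colnames(X))
  expect_equal(ncol(X), 6L)
})

test_that("degenerate designs are rejected with named culprits", {
  cov <- covariate_fixture()
  cov$Flat <- 7
  expect_error(build_design(cov, "Flat"), "constant")
  cov2 <- cov[cov$sex == "female", ]  # one sex only: I_Male column all zero
  expect_error(build_design(cov2, "ReadEng"), "collinear.*I_Male")
})

test_that("pooled QR on a population bundle recovers the pooled quantile", {
  pool <- toy_pool(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  X <- intercept_design(pool)
  f <- fit_pooled_qr(pool, X, 0.43)
  # inverse-ECDF quantile at rank ceiling(0.43 * 10) = 5
  expect_equal(unname(f$coefficients), 5, tolerance = 1e-6)
  expect_equal(f$n, 10L)
})

test_that("sandwich matrices equal the hand-computed estimators", {
  vals <- withr::with_seed(8, rnorm(40, mean = 0.5, sd = 0.1))
  pool <- toy_pool(vals, n_subjects = 4)
  ids <- unique(pool$records$subject_id)
  X <- cbind(1, c(0.1, 0.4, 0.6, 0.9))
  rownames(X) <- ids; colnames(X) <- c("b0", "b1")
  f <- fit_pooled_qr(pool, X, 0.5)
  sw <- sandwich_covariance(pool, X, f)
  n <- 40
  psi <- 0.5 - (f$residuals < 0)
  Xp <- X[match(pool$records$subject_id, ids), ]
  # A: cluster-summed scores, outer product of per-subject design rows
  A_hand <- matrix(0, 2, 2)
  for (i in seq_along(ids)) {
    gi <- sum(psi[pool$records$subject_id == ids[i]])
    A_hand <- A_hand + gi^2 * tcrossprod(X[i, ])
  }
  A_hand <- A_hand / n
  expect_equal(unname(sw$A), unname(A_hand), tolerance = 1e-12)
  # B: Powell kernel density estimate at the fitted hyperplane
  h <- sw$bandwidth
  B_hand <- crossprod(Xp * dnorm(f$residuals / h), Xp) / (n * h)
  expect_equal(unname(sw$B), unname(B_hand), tolerance = 1e-12)
  expect_equal(unname(sw$omega),
               unname(solve(B_hand) %*% A_hand %*% solve(B_hand)),
               tolerance = 1e-8)
  expect_equal(sw$vcov, sw$omega / n, tolerance = 1e-12)
  # the naive variant accumulates per-point scores instead
  sw0 <- sandwich_covariance(pool, X, f, cluster = FALSE)
  A0_hand <- crossprod(Xp * psi) / n
  expect_equal(unname(sw0$A), unname(A0_hand), tolerance = 1e-12)
  # omega is symmetric PSD
  expect_equal(sw$omega, t(sw$omega))
  expect_true(all(eigen(sw$omega, symmetric = TRUE)$values >= -1e-10))
})

test_that("duplicating every point leaves coefficients and cluster SEs stable", {
  cfg <- sim_config(n_subjects = 25, n_streamlines = 3, n_points = 10,
                    gamma = c(0.5, 0.03), delta = c(0.08, 0.02),
                    subject_effect_sd = 0.6, seed = 14)
  coh <- simulate_cohort(cfg)
  pool <- pool_bundles(coh$bundles)
  dup_bundles <- lapply(coh$bundles, function(b) {
    b$streamlines <- c(b$streamlines, b$streamlines)
    b
  })
  pool2 <- pool_bundles(dup_bundles)
  f1 <- fit_pooled_qr(pool, coh$design, 0.5)
  f2 <- fit_pooled_qr(pool2, coh$design, 0.5)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-5)
  sw1 <- sandwich_covariance(pool, coh$design, f1)
  sw2 <- sandwich_covariance(pool2, coh$design, f2)
  # cluster-robust SEs must not shrink like 1/sqrt(2) under duplication
  expect_gt(sw2$se[2] / sw1$se[2], 0.85)
  sw1n <- sandwich_covariance(pool, coh$design, f1, cluster = FALSE)
  sw2n <- sandwich_covariance(pool2, coh$design, f2, cluster = FALSE)
  expect_lt(sw2n$se[2] / sw1n$se[2], 0.85)
})

test_that("BH adjustment reproduces the step-up worked example and properties", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.031), 0.031)      # m = 1 identity
  p <- withr::with_seed(2, runif(30)^2)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q[order(p)] == cummax(q[order(p)])))  # step-up monotone
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("region fits at identical tau are identical and C = 1 is a median fit", {
  cfg <- sim_config(n_subjects = 12, n_streamlines = 2, n_points = 8, seed = 3)
  coh <- simulate_cohort(cfg)
  pool <- pool_bundles(coh$bundles)
  spec1 <- make_regions(pool, C = 1)
  fits1 <- fit_all_regions(pool, coh$design, spec1)
  expect_length(fits1$fits, 1L)
  expect_equal(fits1$fits[[1]]$tau, 0.5)
  direct <- fit_pooled_qr(pool, coh$design, 0.5)
  expect_equal(fits1$fits[[1]]$coefficients, direct$coefficients)
  fits1b <- fit_all_regions(pool, coh$design, spec1)
  expect_identical(region_matrix(fits1, "coefficients"),
                   region_matrix(fits1b, "coefficients"))
})

test_that("estimated slope-vs-tau curve tracks the location-scale truth", {
  cfg <- sim_config(n_subjects = 150, n_streamlines = 3, n_points = 12,
                    gamma = c(0.5, 0.05), delta = c(0.08, 0.04), seed = 77)
  coh <- simulate_cohort(cfg)
  pool <- pool_bundles(coh$bundles)
  for (tau in c(0.25, 0.5, 0.75)) {
    fit <- fit_pooled_qr(pool, coh$design, tau)
    truth <- true_quantile_coefficients(cfg, tau)
    expect_lt(max(abs(fit$coefficients - truth)), 0.03)
  }
})

test_that("significance report encodes contiguous significant quantile runs", {
  cfg <- sim_config(n_subjects = 30, n_streamlines = 3, n_points = 10,
                    seed = 5)
  coh <- simulate_cohort(cfg)
  pool <- pool_bundles(coh$bundles)
  spec <- make_regions(pool, C = 6)
  fits <- fit_all_regions(pool, coh$design, spec)
  # overwrite p-values with a crafted alternating pattern
  crafted <- c(1e-6, 0.9, 1e-6, 1e-6, 0.9, 1e-6)
  for (k in seq_along(fits$fits)) {
    fits$fits[[k]]$p_values["scalar"] <- crafted[k]
    fits$fits[[k]]$z_scores["scalar"] <- if (crafted[k] < 0.5) 8 else 0.1
  }
  rep <- significance_report(fits, alpha = 0.05, coefficients = "scalar")
  rng <- rep$significant_ranges
  expect_equal(nrow(rng), 3L)  # one row per maximal run
  expect_equal(rng$n_regions, c(1L, 2L, 1L))
  tau_pct <- 100 * spec$tau_levels
  expect_equal(rng$tau_start_pct, tau_pct[c(1, 3, 6)])
  expect_equal(rng$tau_end_pct, tau_pct[c(1, 4, 6)])
  # no-signal report: empty range table
  for (k in seq_along(fits$fits))
    fits$fits[[k]]$p_values["scalar"] <- 0.9
  rep0 <- significance_report(fits, coefficients = "scalar")
  expect_equal(nrow(rep0$significant_ranges), 0L)
  expect_true(all(rep0$table$p_adjusted >= rep0$table$p))
})

test_that("too few subjects for the design triggers an error", {
  pool <- toy_pool(rnorm(8), n_subjects = 2)
  X <- cbind(1, c(0.2, 0.8))
  rownames(X) <- unique(pool$records$subject_id)
  expect_error(fit_pooled_qr(pool, X, 0.5), "more subjects")
})
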