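#' Build the per-subject design matrix
#'
#' Constructs one covariate row per subject from the covariate table. Under
#' the default sex-stratified preset the columns are exactly
#' `[I_Female, I_Male, Age x I_Male, Scalar x I_Female, Scalar x I_Male]`:
#' sex-specific intercepts and sex-specific scalar slopes, with age entering
#' through the male indicator only. A symmetric variant that also includes
#' `Age x I_Female` is available as `preset = "sex_stratified_sym_age"`. The
#' scalar factor is min-max scaled to [0, 1] over the analyzed cohort so
#' coefficient magnitudes are comparable across scalar factors; the scaling
#' parameters are recorded in the `scalar_scaling` attribute.
#'
#' @param covariates data frame from [read_covariates()].
#' @param scalar_name name of the scalar-factor column to analyze.
#' @param preset `"sex_stratified"` (default) or `"sex_stratified_sym_age"`.
#' @return Numeric matrix with one row per subject (rownames = subject ids),
#'   attributes `scalar_cols` (names of the scalar-factor columns) and
#'   `scalar_scaling` (`c(min, max)` used for the rescale); class
#'   `fmq_design`.
#' @export
build_design <- function(covariates, scalar_name,
                         preset = c("sex_stratified", "sex_stratified_sym_age")) {
  preset <- match.arg(preset)
  need <- c("subject_id", "sex", "age", scalar_name)
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stopf("covariate table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(covariates[need]))
    stopf("missing values among used covariate columns")
  sc <- as.numeric(covariates[[scalar_name]])
  rng <- range(sc)
  if (rng[1] == rng[2])
    stopf("scalar factor '%s' is constant; cannot min-max scale", scalar_name)
  s <- (sc - rng[1]) / (rng[2] - rng[1])
  f <- as.numeric(covariates$sex == "female")
  m <- as.numeric(covariates$sex == "male")
  age <- covariates$age
  X <- cbind(I_Female = f, I_Male = m, `Age:I_Male` = age * m,
             `Scalar:I_Female` = s * f, `Scalar:I_Male` = s * m)
  if (preset == "sex_stratified_sym_age")
    X <- cbind(X[, 1:2], `Age:I_Female` = age * f, X[, 3:5])
  rownames(X) <- covariates$subject_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[-qx$pivot[seq_len(qx$rank)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  structure(X,
            scalar_cols = grep("^Scalar:", colnames(X), value = TRUE),
            scalar_scaling = c(min = rng[1], max = rng[2]),
            preset = preset,
            class = c("fmq_design", "matrix", "array"))
}

# Per-point expansion: row of `design` for each pooled point's subject.
expand_design <- function(pool, design) {
  ids <- pool$records$subject_id
  idx <- match(ids, rownames(design))
  if (anyNA(idx))
    stopf("pooled subjects missing from design: %s",
          paste(unique(ids[is.na(idx)]), collapse = ", "))
  list(X = unclass(design)[idx, , drop = FALSE], subject_index = idx)
}

#' Pooled quantile regression over a population fiber bundle
#'
#' Fits \eqn{\hat\beta(\tau) = \arg\min_\beta \sum_i \sum_p
#' \rho_\tau(Y_{ip} - X_i'\beta)}: every streamline point of every subject
#' contributes one check-loss term, with the subject's covariate row repeated
#' across its points. The fitted linear predictor \eqn{X_i'\hat\beta(\tau)}
#' models the region's typical value \eqn{G_Y(\tau)}.
#'
#' @param pool a [pool_bundles()] result.
#' @param design an [build_design()] matrix (or any matrix with subject
#'   rownames covering the pool).
#' @param tau quantile level in (0, 1).
#' @param ... passed to [pinball_fit()] (`tol`, `max_iter`).
#' @return Object of class `fmq_qrfit`: list with `tau`, `coefficients`,
#'   `objective`, `residuals` (per pooled point), `subject_index`,
#'   `converged`, `iterations`. Standard errors are added by
#'   [sandwich_covariance()] / [fit_all_regions()].
#' @export
fit_pooled_qr <- function(pool, design, tau, ...) {
  stopifnot(inherits(pool, "population_pool"))
  if ((nrow(design) - 1) < qr(design)$rank)
    stopf("need more subjects than design columns for inference")
  ed <- expand_design(pool, design)
  fit <- pinball_fit(ed$X, pool_values(pool), tau, ...)
  structure(list(tau = tau,
                 coefficients = fit$coefficients,
                 objective = fit$objective,
                 residuals = fit$residuals,
                 subject_index = ed$subject_index,
                 n = length(fit$residuals),
                 converged = fit$converged,
                 iterations = fit$iterations),
            class = "fmq_qrfit")
}

#' @export
print.fmq_qrfit <- function(x, ...) {
  cat(sprintf("Pooled quantile regression, tau = %.4g (n = %d points)\n",
              x$tau, x$n))
  print(round(x$coefficients, 6))
  if (!is.null(x$se)) {
    tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z_scores,
                 p = x$p_values)
    print(round(tab, 6))
  }
  invisible(x)
}

# Hall-Sheather bandwidth in quantile space, then mapped to the residual
# scale the Powell kernel density estimate needs (the construction standard
# for kernel-based quantile-regression inference).
residual_bandwidth <- function(res, tau, n, rule = c("hall-sheather", "bofinger")) {
  rule <- match.arg(rule)
  alpha <- 0.05
  h_tau <- if (rule == "hall-sheather") {
    n^(-1 / 3) * stats::qnorm(1 - alpha / 2)^(2 / 3) *
      ((1.5 * stats::dnorm(stats::qnorm(tau))^2) /
         (2 * stats::qnorm(tau)^2 + 1))^(1 / 3)
  } else {
    n^(-1 / 5) * ((4.5 * stats::dnorm(stats::qnorm(tau))^4) /
                    (2 * stats::qnorm(tau)^2 + 1)^2)^(1 / 5)
  }
  while (tau - h_tau <= 0 || tau + h_tau >= 1) h_tau <- h_tau / 2
  scale_est <- min(stats::sd(res),
                   (stats::quantile(res, 0.75) - stats::quantile(res, 0.25)) / 1.34)
  if (scale_est <= 0) scale_est <- stats::sd(res)
  h <- (stats::qnorm(tau + h_tau) - stats::qnorm(tau - h_tau)) * scale_est
  unname(max(h, .Machine$double.eps^0.5))
}

#' Cluster-robust sandwich covariance for the pooled quantile regression
#'
#' Estimates the asymptotic covariance \eqn{\Omega(\tau) =
#' B(\tau)^{-1} A(\tau) B(\tau)^{-1}} of the pooled estimator, treating
#' subjects as clusters so that the strong within-subject correlation of
#' streamline-point values yields honest standard errors:
#' \deqn{\hat A = \frac{1}{n}\sum_i \Big(\sum_p \psi_\tau(\hat e_{ip})\Big)^2
#'   X_i X_i', \qquad
#'   \hat B = \frac{1}{nh}\sum_i \sum_p \kappa(\hat e_{ip}/h)\, X_i X_i',}
#' with score \eqn{\psi_\tau(e) = \tau - 1[e < 0]}, Gaussian kernel
#' \eqn{\kappa}, and bandwidth h from the Hall-Sheather rule at the pooled
#' n mapped to the residual scale. The reported variance of
#' \eqn{\hat\beta} is \eqn{\hat\Omega / n}. With `cluster = FALSE` the score
#' outer product is accumulated per point instead (the naive independent-data
#' sandwich, which understates uncertainty when points are correlated within
#' subject — retained for comparison only).
#'
#' @param pool,design the pool and design the fit was computed on.
#' @param fit a [fit_pooled_qr()] result.
#' @param bandwidth_rule `"hall-sheather"` (default) or `"bofinger"`.
#' @param cluster cluster scores within subject (default TRUE).
#' @return List of class `fmq_sandwich`: `omega` (the \eqn{\Omega} matrix),
#'   `vcov` (= omega/n, covariance of the coefficients), `se`, `bandwidth`,
#'   `A`, `B`.
#' @export
sandwich_covariance <- function(pool, design, fit,
                                bandwidth_rule = c("hall-sheather", "bofinger"),
                                cluster = TRUE) {
  stopifnot(inherits(fit, "fmq_qrfit"))
  bandwidth_rule <- match.arg(bandwidth_rule)
  ed <- expand_design(pool, design)
  X <- ed$X
  n <- nrow(X); p <- ncol(X)
  res <- fit$residuals
  tau <- fit$tau
  psi <- tau - (res < 0)
  if (cluster) {
    # sum scores within subject, then outer-product the per-subject totals
    g <- rowsum(psi, ed$subject_index)            # one total per subject
    Xs <- unclass(design)[as.integer(rownames(g)), , drop = FALSE]
    A <- crossprod(Xs * as.numeric(g)) / n
  } else {
    A <- crossprod(X * psi) / n
  }
  h <- residual_bandwidth(res, tau, n, bandwidth_rule)
  kern <- stats::dnorm(res / h)
  B <- crossprod(X * kern, X) / (n * h)
  Binv <- tryCatch(solve(B), error = function(e)
    stopf("singular B matrix at tau = %.4g; consider a larger bandwidth or more data",
          tau))
  omega <- Binv %*% A %*% Binv
  # enforce symmetric PSD (numerical asymmetry / tiny negative eigenvalues)
  omega <- (omega + t(omega)) / 2
  ev <- eigen(omega, symmetric = TRUE)
  if (any(ev$values < 0)) {
    if (any(ev$values < -1e-8 * max(abs(ev$values))))
      warnf("covariance had negative eigenvalues; floored at zero")
    ev$values <- pmax(ev$values, 0)
    omega <- ev$vectors %*% (ev$values * t(ev$vectors))
  }
  vcov <- omega / n
  dimnames(vcov) <- dimnames(omega) <- list(colnames(X), colnames(X))
  structure(list(omega = omega, vcov = vcov, se = sqrt(diag(vcov)),
                 bandwidth = h, A = A, B = B, cluster = cluster),
            class = "fmq_sandwich")
}

# Attach inference to a fit: SEs, Z-scores, two-sided normal p-values.
add_inference <- function(fit, sw) {
  fit$se <- sw$se
  fit$omega <- sw$omega
  fit$vcov <- sw$vcov
  fit$bandwidth <- sw$bandwidth
  fit$z_scores <- fit$coefficients / sw$se
  fit$p_values <- 2 * stats::pnorm(-abs(fit$z_scores))
  fit
}

#' Fit the pooled quantile regression in every quantile-specific region
#'
#' One pooled fit per region level \eqn{\tau_c}, each with cluster-robust
#' sandwich inference. The response for region c is the pooled value sample
#' at level \eqn{\tau_c} (region labels are used for reporting and
#' annotation, not for subsetting the loss). Fits are mutually independent;
#' they are computed sequentially and deterministically.
#'
#' @param pool a [pool_bundles()] result.
#' @param design a [build_design()] matrix.
#' @param spec a [make_regions()] result (its `tau_levels` are used).
#' @param bandwidth_rule,cluster passed to [sandwich_covariance()].
#' @param ... passed to [pinball_fit()].
#' @return Object of class `fmq_region_fits`: list of `fmq_qrfit` (one per
#'   region, with inference attached) plus the `spec`.
#' @export
fit_all_regions <- function(pool, design, spec,
                            bandwidth_rule = "hall-sheather", cluster = TRUE,
                            ...) {
  stopifnot(inherits(spec, "region_spec"))
  fits <- vector("list", spec$C)
  for (c_idx in seq_len(spec$C)) {
    fits[[c_idx]] <- tryCatch({
      f <- fit_pooled_qr(pool, design, spec$tau_levels[c_idx], ...)
      add_inference(f, sandwich_covariance(pool, design, f,
                                           bandwidth_rule = bandwidth_rule,
                                           cluster = cluster))
    }, error = function(e)
      stopf("region %d (tau = %.4g): %s", c_idx, spec$tau_levels[c_idx],
            conditionMessage(e)))
  }
  structure(list(fits = fits, spec = spec,
                 coef_names = colnames(design),
                 scalar_cols = attr(design, "scalar_cols")),
            class = "fmq_region_fits")
}

#' @export
print.fmq_region_fits <- function(x, ...) {
  cat(sprintf("fmq_region_fits: %d regions, tau %.3g%% to %.3g%%\n",
              x$spec$C, 100 * min(x$spec$tau_levels),
              100 * max(x$spec$tau_levels)))
  invisible(x)
}

#' Extract a per-region coefficient matrix
#' @param fits an [fit_all_regions()] result.
#' @param what one of `"coefficients"`, `"se"`, `"z_scores"`, `"p_values"`.
#' @return C x p matrix, rows indexed by region.
#' @export
region_matrix <- function(fits, what = c("coefficients", "se", "z_scores",
                                         "p_values")) {
  what <- match.arg(what)
  m <- do.call(rbind, lapply(fits$fits, `[[`, what))
  rownames(m) <- sprintf("region%03d", seq_len(nrow(m)))
  m
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjusted p-values (delegating to [stats::p.adjust()]): sort
#' ascending, take \eqn{q_{(k)} = \min_{j \ge k} \min(1, p_{(j)} m / j)},
#' unsort. Applied across the C quantile-specific regions for each scalar
#' factor (never across bundles or factors).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.020 0.040 0.040
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-region significance report
#'
#' Builds the primary results table of the analysis: for every
#' quantile-specific region, the quantile level (percent), the typical
#' value, and for each scalar-factor coefficient the estimate, cluster-robust
#' Z-score, raw and BH-adjusted p-value (adjustment across regions, per
#' coefficient) and a significance flag at level `alpha`. Also returns the
#' contiguous runs of significant quantile levels per coefficient (e.g.,
#' "quantiles 0.5% to 90.5%") for compact summaries.
#'
#' @param fits an [fit_all_regions()] result.
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @param coefficients which coefficients to report; defaults to the design's
#'   scalar-factor columns.
#' @return List of class `fmq_report`: `table` (long data frame with one row
#'   per region x coefficient) and `significant_ranges` (data frame
#'   `coefficient`, `tau_start_pct`, `tau_end_pct`, `n_regions`).
#' @export
significance_report <- function(fits, alpha = 0.05, coefficients = NULL) {
  stopifnot(inherits(fits, "fmq_region_fits"))
  if (is.null(coefficients)) coefficients <- fits$scalar_cols
  if (!length(coefficients)) coefficients <- fits$coef_names
  est <- region_matrix(fits, "coefficients")
  z <- region_matrix(fits, "z_scores")
  p <- region_matrix(fits, "p_values")
  tau_pct <- 100 * fits$spec$tau_levels
  rows <- list(); ranges <- list()
  for (cf in coefficients) {
    if (!cf %in% colnames(est)) stopf("no coefficient named '%s'", cf)
    padj <- bh_adjust(p[, cf])
    sig <- padj < alpha
    rows[[cf]] <- data.frame(
      region = seq_along(tau_pct), tau_pct = tau_pct,
      typical_value = fits$spec$typical_values,
      coefficient = cf, estimate = est[, cf], z = z[, cf],
      p = p[, cf], p_adjusted = padj, significant = sig,
      row.names = NULL)
    if (any(sig)) {
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      ranges[[cf]] <- data.frame(
        coefficient = cf,
        tau_start_pct = tau_pct[starts[keep]],
        tau_end_pct = tau_pct[ends[keep]],
        n_regions = r$lengths[keep], row.names = NULL)
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 significant_ranges = if (length(ranges))
                   do.call(rbind, c(ranges, list(make.row.names = FALSE)))
                 else data.frame(coefficient = character(0),
                                 tau_start_pct = numeric(0),
                                 tau_end_pct = numeric(0),
                                 n_regions = integer(0)),
                 alpha = alpha),
            class = "fmq_report")
}

#' @export
print.fmq_report <- function(x, ...) {
  cat(sprintf("FMQ significance report (alpha = %.3g, BH-FDR over regions)\n",
              x$alpha))
  if (nrow(x$significant_ranges)) {
    for (i in seq_len(nrow(x$significant_ranges))) {
      r <- x$significant_ranges[i, ]
      cat(sprintf("  %s: quantiles %.3g%% to %.3g%% significant (%d regions)\n",
                  r$coefficient, r$tau_start_pct, r$tau_end_pct, r$n_regions))
    }
  } else cat("  no significant quantile-specific regions\n")
  invisible(x)
}
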