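#' Per-quantile MSE of the quantile-region regression
#'
#' For each region c, the mean over subjects of the squared difference
#' between the region's (population-constant) typical value
#' \eqn{G_Y(\tau_c)} and the subject-level prediction
#' \eqn{X_i'\hat\beta(\tau_c)}:
#' \deqn{\mathrm{MSE}(\tau_c) = \frac{1}{I}\sum_{i=1}^I
#'   (G_Y(\tau_c) - X_i'\hat\beta(\tau_c))^2.}
#' The divisor is I with no degrees-of-freedom correction, and the same
#' typical value is compared against every subject — an unusual fit metric,
#' implemented verbatim because the published model comparison depends on
#' it. A conventional pooled mean check loss per point is available as
#' [check_loss_per_point()] and is clearly a different, diagnostic quantity.
#'
#' @param fits an [fit_all_regions()] result.
#' @param spec the [make_regions()] spec the fits were computed at.
#' @param design the per-subject design matrix.
#' @return Numeric vector of length C.
#' @export
mse_fmq <- function(fits, spec, design) {
  stopifnot(inherits(fits, "fmq_region_fits"), inherits(spec, "region_spec"))
  if (length(fits$fits) != spec$C)
    stopf("fits (%d) and spec (C = %d) are misaligned", length(fits$fits), spec$C)
  X <- unclass(design)
  vapply(seq_len(spec$C), function(c_idx) {
    pred <- drop(X %*% fits$fits[[c_idx]]$coefficients)
    mean((spec$typical_values[c_idx] - pred)^2)
  }, numeric(1))
}

#' Pooled mean check loss per point (diagnostic)
#'
#' Mean pinball loss over all pooled points at each region's \eqn{\tau_c}:
#' the in-sample value of the objective the estimator actually minimizes.
#' Not part of the published MSE comparison; provided as a conventional
#' goodness-of-fit diagnostic.
#'
#' @param fits an [fit_all_regions()] result.
#' @return Numeric vector of length C.
#' @export
check_loss_per_point <- function(fits) {
  stopifnot(inherits(fits, "fmq_region_fits"))
  vapply(fits$fits, function(f) f$objective / f$n, numeric(1))
}

#' Per-location MSE of the along-tract profile regression
#'
#' Residual mean square at each location, divisor I (not I - rank):
#' \eqn{\mathrm{MSE}(l) = \sum_i (T_{il} - X_i'\hat\beta_l)^2 / I}.
#'
#' @param fit an [fit_profile_regression()] result.
#' @return Numeric vector of length L.
#' @export
mse_afq <- function(fit) {
  stopifnot(inherits(fit, "fmq_profilefit"))
  colMeans(fit$residuals^2)
}

#' MSE of the whole-tract mean regression
#'
#' \eqn{\mathrm{MSE} = \sum_i (M_i - X_i'\hat\beta)^2 / I} (divisor I):
#' the mean of squared OLS residuals.
#'
#' @param fit an [fit_mean_regression()] result.
#' @return Scalar MSE.
#' @export
mse_mean <- function(fit) {
  stopifnot(inherits(fit, "fmq_meanfit"))
  mean(fit$residuals^2)
}

#' Compare the three methods' model fit
#'
#' Assembles the comparison row for one (bundle, scalar factor) analysis:
#' the mean-regression MSE, and mean (sd) over locations/quantiles for the
#' profile and quantile-region methods, flagging the best (lowest-mean)
#' method(s); ties report all minimizers.
#'
#' @param mse_mean scalar from [mse_mean()], or NULL if not run.
#' @param mse_afq per-location vector from [mse_afq()], or NULL.
#' @param mse_fmq per-quantile vector from [mse_fmq()], or NULL.
#' @param label optional row label (e.g., `"AF left / PicVocab"`).
#' @return Data frame of class `fmq_comparison` with one row: columns
#'   `label`, `mse_mean`, `mse_afq_mean`, `mse_afq_sd`, `mse_fmq_mean`,
#'   `mse_fmq_sd`, `best_method` (comma-joined minimizers). Missing methods
#'   produce NA columns with a warning.
#' @export
compare_methods <- function(mse_mean = NULL, mse_afq = NULL, mse_fmq = NULL,
                            label = "") {
  means <- c(mean = if (!is.null(mse_mean)) mse_mean else NA_real_,
             afq = if (!is.null(mse_afq)) mean(mse_afq) else NA_real_,
             fmq = if (!is.null(mse_fmq)) mean(mse_fmq) else NA_real_)
  if (anyNA(means))
    warnf("method(s) missing from comparison: %s",
          paste(names(means)[is.na(means)], collapse = ", "))
  if (all(is.na(means))) stopf("no method results supplied")
  best <- names(means)[which(means == min(means, na.rm = TRUE))]
  structure(data.frame(
    label = label,
    mse_mean = means[["mean"]],
    mse_afq_mean = means[["afq"]],
    mse_afq_sd = if (!is.null(mse_afq)) stats::sd(mse_afq) else NA_real_,
    mse_fmq_mean = means[["fmq"]],
    mse_fmq_sd = if (!is.null(mse_fmq)) stats::sd(mse_fmq) else NA_real_,
    best_method = paste(best, collapse = ","),
    row.names = NULL), class = c("fmq_comparison", "data.frame"))
}
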