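#' Whole-tract mean of the per-point scalar
#'
#' The simplest tract summary: the unweighted mean over all points of all
#' (sampled) streamlines of one subject's bundle. Note that the mean of
#' per-subject means differs from the pooled mean whenever subjects
#' contribute different point counts.
#'
#' @param bundle a `subject_bundle`.
#' @return Scalar mean value.
#' @export
mean_per_subject <- function(bundle) {
  stopifnot(inherits(bundle, "subject_bundle"))
  mean(bundle_values(bundle))
}

#' Per-subject tract means for a cohort
#' @param bundles list of `subject_bundle` objects.
#' @return Named numeric vector `M`, one mean per subject.
#' @export
mean_summary <- function(bundles) {
  vapply(bundles, mean_per_subject, numeric(1))
}

#' Whole-tract mean regression
#'
#' Ordinary least squares of the per-subject tract means on the covariate
#' design, \eqn{M_i = X_i'\beta + \epsilon_i}, \eqn{\epsilon_i \sim
#' N(0, \sigma^2)}: classical (homoskedastic) standard errors, T-scores and
#' two-sided t p-values with \eqn{I - \mathrm{rank}(X)} degrees of freedom.
#' A single test per coefficient, so p-values are reported unadjusted.
#'
#' @param M named vector of tract means from [mean_summary()].
#' @param design a [build_design()] matrix whose rownames cover `names(M)`.
#' @return Object of class `fmq_meanfit`: `coefficients`, `se`, `t_scores`,
#'   `p_values`, `sigma2` (residual variance, df-corrected), `df_residual`,
#'   `fitted`, `residuals`.
#' @export
fit_mean_regression <- function(M, design) {
  X <- unclass(design)
  if (!is.null(names(M))) {
    idx <- match(names(M), rownames(X))
    if (anyNA(idx)) stopf("subjects missing from design: %s",
                          paste(names(M)[is.na(idx)], collapse = ", "))
    X <- X[idx, , drop = FALSE]
  }
  if (length(M) != nrow(X)) stopf("need one tract mean per design row")
  fit <- stats::lm.fit(X, as.numeric(M))
  rk <- fit$rank
  if (rk < ncol(X)) stopf("design is rank deficient")
  df <- length(M) - rk
  if (df <= 0) stopf("no residual degrees of freedom (I <= rank(X))")
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- fit$coefficients / se
  structure(list(coefficients = fit$coefficients, se = se, t_scores = tval,
                 p_values = 2 * stats::pt(-abs(tval), df),
                 sigma2 = sigma2, df_residual = df,
                 fitted = fit$fitted.values, residuals = fit$residuals,
                 scalar_cols = attr(design, "scalar_cols")),
            class = "fmq_meanfit")
}

#' @export
print.fmq_meanfit <- function(x, ...) {
  cat("Whole-tract mean regression (OLS)\n")
  print(round(cbind(estimate = x$coefficients, se = x$se, t = x$t_scores,
                    p = x$p_values), 6))
  invisible(x)
}

# --- streamline geometry helpers -------------------------------------------

# Resample a streamline to L equidistant arc-length nodes, linearly
# interpolating coordinates and the scalar value.
resample_streamline <- function(s, L) {
  xyz <- as.matrix(s[c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(xyz)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stopf("degenerate zero-length streamline")
  target <- seq(0, total, length.out = L)
  out <- matrix(NA_real_, L, 4)
  for (k in 1:3)
    out[, k] <- stats::approx(arc, xyz[, k], xout = target, ties = "ordered")$y
  out[, 4] <- stats::approx(arc, s$value, xout = target, ties = "ordered")$y
  colnames(out) <- c("x", "y", "z", "value")
  out
}

endpoints <- function(s) {
  xyz <- as.matrix(s[c("x", "y", "z")])
  rbind(xyz[1, ], xyz[nrow(xyz), ])
}

# Squared endpoint distance between two streamlines, direct and flipped.
endpoint_dist2 <- function(ea, eb) {
  direct <- sum((ea[1, ] - eb[1, ])^2) + sum((ea[2, ] - eb[2, ])^2)
  flipped <- sum((ea[1, ] - eb[2, ])^2) + sum((ea[2, ] - eb[1, ])^2)
  c(direct = direct, flipped = flipped)
}

# Orientation reference: the streamline closest to the bundle's medoid under
# (orientation-invariant) endpoint distance; ties by lowest streamline index.
# The reference's own orientation is canonicalized lexicographically so the
# result does not depend on the stored point order of any streamline.
orientation_reference <- function(streamlines) {
  eps <- lapply(streamlines, endpoints)
  S <- length(eps)
  ref <- if (S == 1L) eps[[1]] else {
    total <- numeric(S)
    for (a in seq_len(S)) {
      d <- 0
      for (b in seq_len(S)) if (b != a) d <- d + min(endpoint_dist2(eps[[a]], eps[[b]]))
      total[a] <- d
    }
    eps[[which.min(total)]]
  }
  key <- sign(ref[1, ] - ref[2, ])
  first_nz <- key[key != 0]
  if (length(first_nz) && first_nz[1] > 0) ref <- ref[2:1, , drop = FALSE]
  ref
}

#' Along-tract profile of a subject's bundle
#'
#' Computes the per-subject tract profile used by along-tract ("automated
#' fiber quantification" style) analysis: every streamline is resampled to L
#' equidistant arc-length nodes with linear interpolation of the scalar,
#' streamline orientations are harmonized (a streamline is flipped when
#' flipping reduces its summed endpoint distance to the orientation
#' reference), and the profile value at location l is the mean over
#' streamlines of the node values — unweighted (`"uniform"`) or weighted by
#' Gaussian affinity to the per-location node cloud's center
#' (`"gaussian_core"`, weights \eqn{\exp(-d_M^2/2)} from each node's
#' Mahalanobis distance \eqn{d_M} to the location's streamline-node cloud,
#' which down-weights aberrant streamlines).
#'
#' @param bundle a `subject_bundle`.
#' @param L number of along-tract locations (>= 2; 100 is the field's
#'   default convention).
#' @param weighting `"gaussian_core"` (default) or `"uniform"`.
#' @param reference optional 2 x 3 endpoint matrix fixing the orientation
#'   reference (pass a cohort-level reference so locations match across
#'   subjects); defaults to this bundle's medoid streamline.
#' @return Numeric profile of length L with attribute `n_flipped`.
#' @export
afq_profile <- function(bundle, L = 100,
                        weighting = c("gaussian_core", "uniform"),
                        reference = NULL) {
  stopifnot(inherits(bundle, "subject_bundle"))
  weighting <- match.arg(weighting)
  if (!is_count(L) || L < 2) stopf("`L` must be an integer >= 2")
  if (is.null(reference)) reference <- orientation_reference(bundle$streamlines)
  S <- length(bundle$streamlines)
  vals <- matrix(NA_real_, S, L)
  coords <- array(NA_real_, c(S, L, 3))
  n_flipped <- 0L
  for (s_idx in seq_len(S)) {
    rs <- resample_streamline(bundle$streamlines[[s_idx]], L)
    d <- endpoint_dist2(rbind(rs[1, 1:3], rs[L, 1:3]), reference)
    if (d["flipped"] < d["direct"]) {
      rs <- rs[L:1, , drop = FALSE]
      n_flipped <- n_flipped + 1L
    }
    vals[s_idx, ] <- rs[, "value"]
    coords[s_idx, , ] <- rs[, 1:3]
  }
  prof <- if (weighting == "uniform" || S == 1L) {
    colMeans(vals)
  } else {
    out <- numeric(L)
    for (l in seq_len(L)) {
      P <- coords[, l, ]
      ctr <- colMeans(P)
      Pc <- sweep(P, 2, ctr)
      sig <- crossprod(Pc) / (S - 1)
      sig <- sig + diag(3) * (1e-8 + 1e-6 * mean(diag(sig)))
      md2 <- rowSums((Pc %*% solve(sig)) * Pc)
      wgt <- exp(-md2 / 2)
      wgt <- wgt / sum(wgt)
      out[l] <- sum(wgt * vals[, l])
    }
    out
  }
  attr(prof, "n_flipped") <- n_flipped
  prof
}

#' Along-tract profile matrix for a cohort
#'
#' Stacks per-subject profiles into the I x L matrix \eqn{T_{il}}. A single
#' cohort-level orientation reference (the medoid streamline of the first
#' subject's bundle) is used for every subject so that location l means the
#' same tract position in all rows.
#'
#' @param bundles named list of `subject_bundle` objects.
#' @param L number of locations.
#' @param weighting passed to [afq_profile()].
#' @return I x L matrix with subject rownames; attribute
#'   `orientation_reference` records the endpoint pair used.
#' @export
afq_profile_matrix <- function(bundles, L = 100,
                               weighting = c("gaussian_core", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(bundles) < 2L) stopf("need at least 2 subjects")
  ref <- orientation_reference(bundles[[1]]$streamlines)
  T_mat <- t(vapply(bundles, function(b)
    as.numeric(afq_profile(b, L, weighting, reference = ref)), numeric(L)))
  rownames(T_mat) <- unname(vapply(bundles, `[[`, character(1), "subject_id"))
  attr(T_mat, "orientation_reference") <- ref
  T_mat
}

#' Along-tract profile regression
#'
#' Independent OLS at each of the L tract locations,
#' \eqn{T_{il} = X_i'\beta_l + \epsilon_{il}}, with classical standard
#' errors, T-scores, and BH-FDR adjustment across the L locations per
#' scalar-factor coefficient.
#'
#' @param profiles I x L matrix from [afq_profile_matrix()].
#' @param design a [build_design()] matrix covering the profile rows.
#' @return Object of class `fmq_profilefit`: `coefficients`, `se`,
#'   `t_scores`, `p_values` (all L x p matrices), `p_adjusted` (L x
#'   n_scalar_cols, BH across locations), `sigma2`, `df_residual`, `L`.
#' @export
fit_profile_regression <- function(profiles, design) {
  X <- unclass(design)
  if (!is.null(rownames(profiles))) {
    idx <- match(rownames(profiles), rownames(X))
    if (anyNA(idx)) stopf("subjects missing from design: %s",
                          paste(rownames(profiles)[is.na(idx)], collapse = ", "))
    X <- X[idx, , drop = FALSE]
  }
  if (nrow(profiles) != nrow(X)) stopf("need one profile row per design row")
  if (anyNA(profiles) || any(!is.finite(profiles)))
    stopf("profile matrix has non-finite entries")
  L <- ncol(profiles); p <- ncol(X); I <- nrow(X)
  qx <- qr(X)
  if (qx$rank < p) stopf("design is rank deficient")
  df <- I - qx$rank
  if (df <= 0) stopf("no residual degrees of freedom")
  coefs <- qr.coef(qx, profiles)                # p x L
  res <- profiles - X %*% coefs                 # I x L
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(sigma2, diag(XtXinv)))       # L x p
  beta <- t(coefs)                              # L x p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  colnames(beta) <- colnames(se) <- colnames(tval) <- colnames(pval) <- colnames(X)
  scalar_cols <- attr(design, "scalar_cols")
  if (is.null(scalar_cols) || !length(scalar_cols)) scalar_cols <- colnames(X)
  padj <- vapply(scalar_cols, function(cf) bh_adjust(pval[, cf]),
                 numeric(L))
  structure(list(coefficients = beta, se = se, t_scores = tval,
                 p_values = pval, p_adjusted = padj,
                 sigma2 = sigma2, df_residual = df, L = L,
                 residuals = res, scalar_cols = scalar_cols),
            class = "fmq_profilefit")
}

#' @export
print.fmq_profilefit <- function(x, ...) {
  cat(sprintf("Along-tract profile regression: %d locations, df = %d\n",
              x$L, x$df_residual))
  nsig <- colSums(x$p_adjusted < 0.05)
  for (cf in colnames(x$p_adjusted))
    cat(sprintf("  %s: %d/%d locations significant (BH-FDR < 0.05)\n",
                cf, nsig[cf], x$L))
  invisible(x)
}
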