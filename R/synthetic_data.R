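#' Configuration for the synthetic multi-subject bundle generator
#'
#' Defines a cohort of subjects, each carrying a bundle of streamlines with a
#' per-point scalar value generated under a location-scale law
#' \deqn{Y_{ip} = X_i'\gamma + (X_i'\delta)\,(\epsilon_{ip} + b_i),}
#' where \eqn{\epsilon_{ip}} is standardized iid noise, and \eqn{b_i} is a
#' subject-level shift inducing within-subject correlation. Under this law the
#' true conditional quantile coefficients are linear in the covariates,
#' \eqn{\beta(\tau) = \gamma + \delta F^{-1}(\tau)} with \eqn{F} the
#' distribution of \eqn{\epsilon + b}, which makes estimator recovery exactly
#' checkable (see [true_quantile_coefficients()]).
#'
#' The design preset is keyed by `length(gamma)`:
#' \describe{
#'   \item{1}{intercept only.}
#'   \item{2}{`[intercept, scalar]` with the scalar drawn uniform on (0, 1).}
#'   \item{5}{sex-stratified preset
#'     `[I_Female, I_Male, Age x I_Male, Scalar x I_Female, Scalar x I_Male]`.}
#' }
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_streamlines streamlines generated per subject.
#' @param n_points points per streamline; either a single count or a
#'   length-2 range `c(lo, hi)` from which each streamline's count is drawn
#'   uniformly (bundles in real tractography have varying point counts).
#' @param gamma numeric vector of location coefficients, one per design column.
#' @param delta numeric vector of scale coefficients, same length as `gamma`;
#'   every subject's scale \eqn{X_i'\delta} must be strictly positive.
#' @param noise_family one of `"gaussian"`, `"t"`, `"uniform"`; all families
#'   are standardized to mean 0, variance 1 so `gamma`/`delta` are comparable.
#' @param noise_df degrees of freedom for the t family (must exceed 2).
#' @param subject_effect_sd standard deviation of the Gaussian subject effect
#'   `b_i`; 0 gives independent points.
#' @param geometry `"none"` (points on a trivial straight line; the
#'   location-scale law holds exactly for pooled values — use this for
#'   estimator-recovery work) or `"tube"` (points on 3-D curves in a
#'   cylindrical bundle with the value shaped to decrease from tube axis to
#'   surface and to vary along the tract, for I/O, region-map and
#'   profile-baseline testing; pooled values then include the geometric
#'   shaping terms).
#' @param tube_radius cylinder radius in mm (tube geometry only).
#' @param tube_contrast amplitude of the axis-to-surface value gradient.
#' @param along_contrast amplitude of the along-tract value bump.
#' @param seed master integer seed. Per-subject substreams are derived
#'   deterministically from it, so any subject subset is reproducible.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()], [true_quantile_coefficients()]
#' @export
sim_config <- function(n_subjects,
                       n_streamlines = 10,
                       n_points = 20,
                       gamma = c(0.5, 0.02),
                       delta = c(0.08, 0.02),
                       noise_family = c("gaussian", "t", "uniform"),
                       noise_df = 5,
                       subject_effect_sd = 0,
                       geometry = c("none", "tube"),
                       tube_radius = 5,
                       tube_contrast = 0.1,
                       along_contrast = 0.05,
                       seed = 1L) {
  noise_family <- match.arg(noise_family)
  geometry <- match.arg(geometry)
  if (!is_count(n_subjects)) stopf("`n_subjects` must be a positive integer")
  if (!is_count(n_streamlines)) stopf("`n_streamlines` must be a positive integer")
  if (!(length(n_points) %in% 1:2) || any(n_points < 2))
    stopf("`n_points` must be a count >= 2 or a range c(lo, hi) with lo >= 2")
  if (length(n_points) == 2 && n_points[1] > n_points[2])
    stopf("`n_points` range must be nondecreasing")
  if (length(gamma) != length(delta))
    stopf("`gamma` and `delta` must have the same length")
  if (!(length(gamma) %in% c(1L, 2L, 5L)))
    stopf("supported design presets have 1, 2 or 5 columns; got %d", length(gamma))
  if (noise_family == "t" && noise_df <= 2)
    stopf("t noise requires `noise_df` > 2 for a finite variance")
  if (subject_effect_sd < 0) stopf("`subject_effect_sd` must be nonnegative")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_streamlines = as.integer(n_streamlines),
    n_points = as.integer(n_points),
    gamma = as.numeric(gamma),
    delta = as.numeric(delta),
    noise_family = noise_family,
    noise_df = noise_df,
    subject_effect_sd = subject_effect_sd,
    geometry = geometry,
    tube_radius = tube_radius,
    tube_contrast = tube_contrast,
    along_contrast = along_contrast,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d subjects x %d streamlines, %s points/streamline\n",
    x$n_subjects, x$n_streamlines, paste(x$n_points, collapse = "-")))
  cat(sprintf("  design columns: %d (%s)\n", length(x$gamma),
              design_preset_name(length(x$gamma))))
  cat(sprintf("  gamma: %s;  delta: %s\n", paste(x$gamma, collapse = ", "),
              paste(x$delta, collapse = ", ")))
  cat(sprintf("  noise: %s, subject effect sd %.3g, geometry %s, seed %d\n",
              x$noise_family, x$subject_effect_sd, x$geometry, x$seed))
  invisible(x)
}

design_preset_name <- function(p) {
  switch(as.character(p),
         "1" = "intercept",
         "2" = "intercept + scalar",
         "5" = "sex-stratified",
         "custom")
}

# Standardized (mean 0, var 1) quantile function of the noise family alone.
noise_quantile <- function(config, p) {
  switch(config$noise_family,
    gaussian = stats::qnorm(p),
    t        = stats::qt(p, df = config$noise_df) /
                 sqrt(config$noise_df / (config$noise_df - 2)),
    uniform  = stats::qunif(p, -sqrt(3), sqrt(3)))
}

noise_sample <- function(config, n) {
  switch(config$noise_family,
    gaussian = stats::rnorm(n),
    t        = stats::rt(n, df = config$noise_df) /
                 sqrt(config$noise_df / (config$noise_df - 2)),
    uniform  = stats::runif(n, -sqrt(3), sqrt(3)))
}

# CDF of (epsilon + b), b ~ N(0, sd_b), by numerical convolution.
noise_plus_effect_cdf <- function(config, q) {
  sd_b <- config$subject_effect_sd
  cdf_eps <- switch(config$noise_family,
    gaussian = function(x) stats::pnorm(x),
    t        = function(x) stats::pt(x * sqrt(config$noise_df / (config$noise_df - 2)),
                                     df = config$noise_df),
    uniform  = function(x) stats::punif(x, -sqrt(3), sqrt(3)))
  if (sd_b == 0) return(cdf_eps(q))
  vapply(q, function(qq) {
    stats::integrate(function(s) cdf_eps(qq - s) * stats::dnorm(s, sd = sd_b),
                     lower = -9 * sd_b, upper = 9 * sd_b,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

#' True conditional quantile coefficients of a simulated cohort
#'
#' Returns the exact coefficient vector \eqn{\beta(\tau) = \gamma + \delta
#' F^{-1}(\tau)}, where \eqn{F} is the distribution of the standardized noise
#' plus the Gaussian subject effect. For Gaussian noise the convolution is
#' closed-form (\eqn{F^{-1}(\tau) = \sqrt{1 + \sigma_b^2}\,\Phi^{-1}(\tau)});
#' otherwise \eqn{F} is computed by numerical convolution and inverted to high
#' precision. Serves as the ground-truth oracle for estimator recovery.
#'
#' @param config a [sim_config()]; must have `geometry = "none"` (with tube
#'   geometry the per-point values include geometric shaping, so the truth is
#'   no longer linear in the covariates).
#' @param tau quantile level, strictly inside (0, 1).
#' @return Numeric vector, one coefficient per design column.
#' @export
true_quantile_coefficients <- function(config, tau) {
  stopifnot(inherits(config, "sim_config"))
  if (config$geometry != "none")
    stopf("true coefficients are only defined for geometry = \"none\"")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1)
    stopf("`tau` must lie strictly inside (0, 1)")
  sd_b <- config$subject_effect_sd
  if (config$noise_family == "gaussian") {
    finv <- sqrt(1 + sd_b^2) * stats::qnorm(tau)
  } else if (sd_b == 0) {
    finv <- noise_quantile(config, tau)
  } else {
    lim <- abs(noise_quantile(config, c(1e-9, 1 - 1e-9)))
    bound <- max(lim) + 9 * sd_b
    finv <- stats::uniroot(function(q) noise_plus_effect_cdf(config, q) - tau,
                           lower = -bound, upper = bound, tol = 1e-10)$root
  }
  config$gamma + config$delta * finv
}

# Build one subject's design row from its covariates, per the preset keyed by
# the number of design columns.
sim_design_row <- function(p, sex, age, scalar) {
  switch(as.character(p),
    "1" = 1,
    "2" = c(1, scalar),
    "5" = c(sex == "female", sex == "male",
            age * (sex == "male"),
            scalar * (sex == "female"), scalar * (sex == "male")) * 1)
}

#' Generate a synthetic cohort of subject bundles with covariates
#'
#' Draws per-subject covariates (sex Bernoulli(1/2), age uniform on 22–36
#' years, scalar factor uniform on 0–1), builds the design row for the
#' configured preset, and generates every streamline point's value under the
#' location-scale law described in [sim_config()]. Each subject is generated
#' in its own deterministically derived RNG substream, so the same seed gives
#' byte-identical output and any subject subset is individually reproducible.
#'
#' @param config a [sim_config()].
#' @return A list of class `fmq_cohort` with elements
#'   \describe{
#'     \item{bundles}{named list of [subject_bundle] objects.}
#'     \item{covariates}{data frame with columns `subject_id`, `sex`, `age`,
#'       `scalar`.}
#'     \item{design}{the exact per-subject design matrix used by the
#'       generator (rows named by subject), with attribute `scalar_cols`
#'       marking the scalar-factor columns.}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' cfg <- sim_config(n_subjects = 4, n_streamlines = 2, n_points = 5, seed = 7)
#' coh <- simulate_cohort(cfg)
#' names(coh$bundles)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- length(config$gamma)
  ids <- sprintf("subj%03d", seq_len(config$n_subjects))
  bundles <- vector("list", config$n_subjects)
  names(bundles) <- ids
  cov_rows <- vector("list", config$n_subjects)
  design <- matrix(NA_real_, config$n_subjects, p)
  rownames(design) <- ids

  for (i in seq_len(config$n_subjects)) {
    sub <- with_seed(derive_seed(config$seed, i), {
      sex <- if (stats::runif(1) < 0.5) "female" else "male"
      age <- stats::runif(1, 22, 36)
      scalar <- stats::runif(1)
      x <- sim_design_row(p, sex, age, scalar)
      scale_i <- sum(x * config$delta)
      if (scale_i <= 0)
        stopf("subject %s has non-positive scale X'delta = %.4g; reject config",
              ids[i], scale_i)
      loc_i <- sum(x * config$gamma)
      b_i <- if (config$subject_effect_sd > 0)
        stats::rnorm(1, sd = config$subject_effect_sd) else 0
      streamlines <- vector("list", config$n_streamlines)
      for (j in seq_len(config$n_streamlines)) {
        np <- if (length(config$n_points) == 2)
          sample(config$n_points[1]:config$n_points[2], 1) else config$n_points
        eps <- noise_sample(config, np)
        value <- loc_i + scale_i * (eps + b_i)
        t_frac <- seq(0, 1, length.out = np)
        if (config$geometry == "tube") {
          theta <- stats::runif(1, 0, 2 * pi)
          r <- config$tube_radius * sqrt(stats::runif(1))
          xyz <- cbind(x = r * cos(theta) + 2 * sin(pi * t_frac),
                       y = r * sin(theta),
                       z = 100 * t_frac)
          value <- value +
            config$tube_contrast * (1 - r / config$tube_radius) +
            config$along_contrast * sin(pi * t_frac)
        } else {
          xyz <- cbind(x = 0, y = 0, z = as.numeric(seq_len(np) - 1L))
        }
        streamlines[[j]] <- data.frame(xyz, value = value)
      }
      list(sex = sex, age = age, scalar = scalar, x = x,
           bundle = new_subject_bundle(ids[i], streamlines))
    })
    bundles[[i]] <- sub$bundle
    design[i, ] <- sub$x
    cov_rows[[i]] <- data.frame(subject_id = ids[i], sex = sub$sex,
                                age = sub$age, scalar = sub$scalar,
                                stringsAsFactors = FALSE)
  }
  covariates <- do.call(rbind, cov_rows)
  colnames(design) <- design_colnames(p)
  attr(design, "scalar_cols") <- design_scalar_cols(p)
  structure(list(bundles = bundles, covariates = covariates,
                 design = design, config = config),
            class = "fmq_cohort")
}

design_colnames <- function(p) {
  switch(as.character(p),
    "1" = "(Intercept)",
    "2" = c("(Intercept)", "scalar"),
    "5" = c("I_Female", "I_Male", "Age:I_Male",
            "Scalar:I_Female", "Scalar:I_Male"))
}

design_scalar_cols <- function(p) {
  switch(as.character(p),
    "1" = character(0),
    "2" = "scalar",
    "5" = c("Scalar:I_Female", "Scalar:I_Male"))
}

#' @export
print.fmq_cohort <- function(x, ...) {
  cat(sprintf("fmq_cohort: %d subjects, %d design columns (%s)\n",
              length(x$bundles), ncol(x$design),
              design_preset_name(ncol(x$design))))
  invisible(x)
}
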