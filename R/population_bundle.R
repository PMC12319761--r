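#' Randomly sample K streamlines from a subject's bundle
#'
#' Each subject contributes the same number K of streamlines to the
#' population fiber bundle so that every subject has equal weight. Sampling
#' is uniform without replacement and deterministic given `seed` and the
#' subject id (each subject draws from its own derived RNG substream).
#'
#' @param bundle a `subject_bundle`.
#' @param K number of streamlines to keep.
#' @param seed integer seed.
#' @param shortfall what to do when the bundle has fewer than K streamlines:
#'   `"error"` (default) or `"take_all"` (keep every streamline, with a
#'   warning).
#' @return A `subject_bundle` with K streamlines (order of first selection).
#' @export
sample_streamlines <- function(bundle, K, seed = 1L,
                               shortfall = c("error", "take_all")) {
  stopifnot(inherits(bundle, "subject_bundle"))
  shortfall <- match.arg(shortfall)
  if (!is_count(K)) stopf("`K` must be a positive integer")
  S <- length(bundle$streamlines)
  if (S < K) {
    if (shortfall == "error")
      stopf("subject %s has %d streamlines, fewer than K = %d",
            bundle$subject_id, S, K)
    warnf("subject %s has %d < K = %d streamlines; taking all",
          bundle$subject_id, S, K)
    return(bundle)
  }
  if (S == K) return(bundle)
  idx <- with_seed(derive_seed(seed, bundle$subject_id),
                   sort(sample.int(S, K)))
  out <- bundle
  out$streamlines <- bundle$streamlines[idx]
  attr(out, "sampled_from") <- idx
  out
}

#' Pool subject bundles into a population fiber bundle
#'
#' Concatenates all subjects' streamline points into one long record table
#' (the population fiber bundle), preserving provenance
#' (subject, streamline, point index). The pooled values are the response
#' sample for quantile-region construction and pooled quantile regression.
#'
#' @param bundles list of `subject_bundle` objects, each already reduced to
#'   K streamlines with [sample_streamlines()].
#' @return An object of class `population_pool` with element `records` (data
#'   frame: `subject_id`, `streamline_id`, `point_index`, `x`, `y`, `z`,
#'   `value`) and attributes `n_subjects`, `K` (NA if unequal), `n` (total
#'   points).
#' @export
pool_bundles <- function(bundles) {
  if (inherits(bundles, "subject_bundle"))
    stopf("need at least 2 subjects to build a population bundle")
  ids <- vapply(bundles, `[[`, character(1), "subject_id")
  if (length(bundles) < 2L)
    stopf("need at least 2 subjects to build a population bundle")
  if (anyDuplicated(ids))
    stopf("duplicate subject_id in pooled bundles: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  counts <- vapply(bundles, function(b) length(b$streamlines), integer(1))
  K <- if (length(unique(counts)) == 1L) counts[1] else {
    warnf("subjects contribute unequal streamline counts (%d-%d); per-subject weights differ",
          min(counts), max(counts))
    NA_integer_
  }
  records <- do.call(rbind, lapply(bundles, bundle_to_long))
  rownames(records) <- NULL
  structure(list(records = records),
            n_subjects = length(bundles), K = K, n = nrow(records),
            class = "population_pool")
}

#' @export
print.population_pool <- function(x, ...) {
  cat(sprintf("population_pool: %d subjects, K = %s, n = %d points\n",
              attr(x, "n_subjects"),
              ifelse(is.na(attr(x, "K")), "varies", attr(x, "K")),
              attr(x, "n")))
  invisible(x)
}

pool_values <- function(pool) pool$records$value

#' Create quantile-specific bundle regions
#'
#' Partitions the pooled value distribution into C regions from bundle
#' periphery (low values) to bundle core (high values). The region boundaries
#' are the empirical quantiles \eqn{G_Y(c/C)} for \eqn{c = 1, \dots, C-1};
#' region c's representative level is the midpoint
#' \eqn{\tau_c = ((c-1)/C + c/C)/2} and its *typical value* is
#' \eqn{G_Y(\tau_c)}, the modeled response of the per-region quantile
#' regression. With C = 100 the studied levels run from 0.5\% to 99.5\%.
#'
#' @param pool a [pool_bundles()] result.
#' @param C number of regions (>= 1, <= number of pooled points).
#' @param quantile_estimator `"inverse_ecdf"` (value at rank
#'   \eqn{\lceil \tau n \rceil}; default, makes equal-size rank regions
#'   exact) or `"linear"` (interpolating type-7 estimate; at realistic pooled
#'   n the difference is negligible).
#' @return An object of class `region_spec`: list with `C`, `cutoffs`
#'   (length C-1), `tau_levels` (length C), `typical_values` (length C),
#'   `quantile_estimator`, `n`.
#' @export
make_regions <- function(pool, C,
                         quantile_estimator = c("inverse_ecdf", "linear")) {
  stopifnot(inherits(pool, "population_pool"))
  quantile_estimator <- match.arg(quantile_estimator)
  if (!is_count(C)) stopf("`C` must be a positive integer")
  y <- pool_values(pool)
  n <- length(y)
  if (C > n) stopf("C = %d exceeds the number of pooled points (%d)", C, n)
  cc <- seq_len(C)
  tau_levels <- ((cc - 1) / C + cc / C) / 2
  cutoffs <- if (C > 1)
    empirical_quantile(y, seq_len(C - 1) / C, quantile_estimator) else numeric(0)
  typical <- empirical_quantile(y, tau_levels, quantile_estimator)
  structure(list(C = as.integer(C), cutoffs = cutoffs, tau_levels = tau_levels,
                 typical_values = typical,
                 quantile_estimator = quantile_estimator, n = n),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("region_spec: C = %d regions over n = %d pooled points (%s quantiles)\n",
              x$C, x$n, x$quantile_estimator))
  cat(sprintf("  tau levels %.3g%% to %.3g%%\n",
              100 * min(x$tau_levels), 100 * max(x$tau_levels)))
  invisible(x)
}

#' Assign every pooled point to a quantile-specific bundle region
#'
#' Points are ranked by value (ties broken stably by subject, streamline and
#' point index) and split into C consecutive rank blocks whose sizes differ
#' by at most one, so every region holds the same number of streamline points
#' even in the presence of ties. This is a rank partition, not a value
#' threshold: ties straddling a cutoff are divided to keep region sizes
#' balanced.
#'
#' @param pool a [pool_bundles()] result.
#' @param spec a [make_regions()] result built from the same pool.
#' @return Integer vector of region labels in 1..C, aligned with
#'   `pool$records`.
#' @export
assign_regions <- function(pool, spec) {
  stopifnot(inherits(pool, "population_pool"), inherits(spec, "region_spec"))
  r <- pool$records
  n <- nrow(r)
  if (n != spec$n)
    stopf("spec was built from a pool of %d points, this pool has %d",
          spec$n, n)
  C <- spec$C
  sizes <- rep(n %/% C, C)
  extra <- n %% C
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(r$value, r$subject_id, r$streamline_id, r$point_index)
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(C), sizes)
  labels
}
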