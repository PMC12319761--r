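---
title: "Quantile-specific bundle regions: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-specific bundle regions: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmqreg)
```

## The problem and the model

Diffusion-MRI tractography represents a white matter fiber bundle as a set of
streamlines, each carrying a scalar microstructure value (typically
fractional anisotropy, FA) at every point. Classic group analyses either
collapse a subject's bundle to a single mean (losing all within-tract
structure) or cut the bundle into locations along its length. This package
implements a third approach: regions defined by the *values themselves*.

The pipeline has three steps.

1. **Population fiber bundle.** From each of the I subjects we draw the same
   number K of streamlines uniformly at random (equal weight per subject)
   and pool every streamline point's value, keeping subject provenance. The
   pooled sample is `[Y_1, ..., Y_I]` with `Y_i = (Y_i1, ..., Y_ip_i)`.

2. **Quantile-specific bundle regions.** Let `G_Y(tau)` be the empirical
   quantile of the pooled values. Cutoffs `G_Y(c/C)`, `c = 1..C-1`, split the
   pooled points into C regions of equal size, running from bundle periphery
   (low FA) to bundle core (high FA). Region c is summarized by the midpoint
   level `tau_c = ((c-1)/C + c/C)/2` and its *typical value* `G_Y(tau_c)`.
   With C = 100 the studied levels run from 0.5% to 99.5%. (The midpoint
   index runs over all C regions; running it only to C-1 would leave the
   top region without a level and could not produce the 99.5% endpoint.)

3. **Pooled quantile regression per region.** For each `tau_c` we model the
   typical value as `G_Y(tau_c) = X_i' beta(tau_c)` and estimate beta by
   minimizing the pooled check loss `sum_i sum_p rho_tau(Y_ip - X_i' beta)`,
   `rho_tau(a) = a (tau - 1[a < 0])`. Every point contributes a term; the
   subject's covariate row is constant across its points. Inference uses the
   sandwich covariance `Omega = B^{-1} A B^{-1}` with subjects as clusters
   (below), two-sided normal p-values, and BH-FDR adjustment across the C
   regions per scalar factor.

The default covariate row is the sex-stratified preset
`[I_Female, I_Male, Age x I_Male, Scalar x I_Female, Scalar x I_Male]`, with
the scalar factor min-max scaled to [0, 1] over the analyzed cohort so
coefficient magnitudes are comparable across scalar factors. Age interacting
with the male indicator only is deliberate: it reproduces the published
design verbatim. Because a sex-symmetric age adjustment is the more common
epidemiological choice and the printed asymmetry may be unintended, the
symmetric variant is available as `preset = "sex_stratified_sym_age"`; the
asymmetric form stays the default so results are comparable with the
original analysis.

## The solver

`pinball_fit()` solves the check-loss minimization exactly as a linear
program, by a Mehrotra predictor-corrector primal-dual interior-point method
on the bounded-variable dual (the Frisch–Newton formulation standard in
quantile regression). Each iteration costs one p x p Cholesky solve plus
O(np) vector work, so the pooled problems this package targets (tens of
thousands of points, a handful of design columns) solve in milliseconds to
seconds. Convergence is declared when the relative duality gap and the
complementarity measure fall below `tol` (default 1e-10); non-convergence is
an error carrying tau, n and p, never a silent result.

Degenerate optima deserve a note: when `tau * n` is integer in an
intercept-only fit, every value of an interval minimizes the loss, and an
interior-point method returns a point of the optimal face rather than a
particular vertex. Tests and downstream comparisons therefore compare
objectives, not coefficient identity, in such cases. Extreme levels for
which `ceiling(tau * n)` would fall outside `{1, ..., n}` cannot arise from
region construction (`tau_c` is strictly inside (0, 1) and `C <= n` is
enforced).

## Cluster-robust covariance

Streamline points within a subject are strongly correlated — thousands of
points share one brain. The pooled estimator is consistent anyway, but naive
standard errors that treat points as independent are far too small. We use
the cluster-robust sandwich for pooled quantile regression: with residual
scores `psi_tau(e) = tau - 1[e < 0]`,

* `A_hat = (1/n) sum_i (sum_p psi_tau(e_ip))^2 X_i X_i'` — scores are summed
  within subject before the outer product, so within-subject correlation
  inflates `A_hat` exactly as it inflates the estimator's sampling noise;
* `B_hat = (1/(n h)) sum_i sum_p kernel(e_ip / h) X_i X_i'` — a Powell-type
  kernel estimate of the residual density at the fitted hyperplane, with a
  Gaussian kernel;
* the coefficient covariance is `B_hat^{-1} A_hat B_hat^{-1} / n` with n the
  total point count.

The bandwidth h uses the Hall–Sheather rule at the pooled n, mapped from
quantile space to the residual scale via the normal quantile function and a
robust scale estimate (`min(sd, IQR/1.34)`); a Bofinger variant is exposed
through `bandwidth_rule`. No published bandwidth accompanies the method, so
the choice is validated behaviorally: in the simulation study under the
default study conditions (200 subjects, 20 points each, intraclass
correlation induced by a subject-level effect), nominal 95% intervals cover
the true coefficient at 91–98%, while the naive independent-point variant
(`cluster = FALSE`, kept only for comparison) undercovers badly. The same
normalization question — per-point versus per-subject n — is settled the
same way: the covariance is reported as `Omega/n` with n total points, and
the coverage study is the evidence that this scaling is right.

Ill-conditioned cases are handled explicitly: a singular `B_hat` raises an
error suggesting a larger bandwidth or more data; the assembled covariance
is symmetrized and any tiny negative eigenvalues are floored at zero with a
warning.

## Region construction details

The quantile estimator is the inverse empirical CDF (value at rank
`ceiling(tau * n)`, `stats::quantile` type 1). Two reasons: region
membership then coincides exactly with a rank partition, making "every
region has the same number of points" true to ±1 by construction; and the
small worked examples in the tests are hand-checkable order statistics. An
interpolating estimator (type 7) is available via `quantile_estimator`; at
pooled sizes in the millions the difference is far below any other source of
variation.

Region labels are assigned by **rank**, not by value thresholding: points
are sorted by value (ties broken stably by subject, streamline and point
index) and cut into C consecutive blocks whose sizes differ by at most one.
Thresholding at the cutoff values — the naive reading of a cutoff diagram —
would break the equal-size property whenever ties straddle a boundary, e.g.
in heavily quantized FA data. Streamline sampling is uniform *without*
replacement; subjects with fewer than K streamlines are an error by default
(`shortfall = "take_all"` opts into keeping them all with a warning). Both
conventions are implementation choices the original description leaves open.

The response of region c's regression is the full pooled sample at level
`tau_c`, not the subset of points with label c: the model is about the
pooled quantile `G_Y(tau_c)`, and the labels exist for reporting and for
exporting per-point annotations (`write_point_annotations()`) that external
3-D viewers can render.

## The comparison methods

*Whole-tract mean regression* reduces each subject to the unweighted mean of
its point values and fits OLS with classical standard errors, t reference
distribution, no multiplicity correction (one test per coefficient).

*Along-tract profile regression* resamples each streamline to L equidistant
arc-length nodes (linear interpolation), harmonizes streamline orientations
(a streamline is flipped when flipping reduces its endpoint distance to the
reference; the reference is the bundle's medoid streamline under
orientation-invariant endpoint distance, its own orientation canonicalized
lexicographically so the profile is invariant to stored point order), and
averages node values across streamlines — unweighted, or with Gaussian
weights `exp(-d_M^2/2)` on each node's Mahalanobis distance to the
per-location node cloud (`gaussian_core`, the default, which down-weights
aberrant streamlines). Location l then gets its own OLS fit, with BH-FDR
across the L locations per scalar factor; L defaults to 100, the field's
convention. This profile implementation is written here from its standard
description rather than wrapping an external tractometry package, so its
guarantees are the property tests it ships with (flip invariance, density
invariance, exact interpolation on straight lines), not bit-identity with
any particular external tool.

*Model fit* is compared by MSE with divisor I and no degrees-of-freedom
correction, exactly as the published comparison defines it. For the
quantile-region method the MSE at level `tau_c` compares the
population-constant typical value against each subject's prediction,
`mean_i (G_Y(tau_c) - X_i' beta_hat(tau_c))^2`. That is an unusual metric —
it rewards predictions that vary little across subjects — and it is
implemented verbatim because the published model comparison depends on it;
`check_loss_per_point()` provides the conventional pooled check-loss
diagnostic, clearly labeled as a different quantity.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed. Point values follow the
location-scale law

    Y_ip = X_i' gamma + (X_i' delta) (eps_ip + b_i)

with standardized noise `eps` (gaussian, t, or uniform, all unit variance so
gamma and delta are comparable across families) and a Gaussian subject
effect `b_i` that induces within-subject correlation. Because the subject
effect enters *inside* the scale term, the conditional quantiles stay linear
in the covariates and the true coefficients are known exactly:
`beta(tau) = gamma + delta F^{-1}(tau)` with F the distribution of
`eps + b` (`true_quantile_coefficients()`; closed form for Gaussian noise,
high-precision numerical convolution otherwise). This is a testing
construction, not a claim about real FA physiology.

Default study conditions, chosen once to be realistic for FA tractometry
and used by the simulation studies throughout: FA-like location 0.5,
within-bundle scale 0.08, a small scalar-factor effect of 0.02 on both
location and scale (brain-behavior effects are small), subject effect sd
0.5 (intraclass correlation roughly 0.2), sex drawn evenly, age uniform on
22–36 years, the scalar factor uniform on [0, 1]. Streamline point counts
may be drawn from a range to emulate varying `p_i`. Seeding is hierarchical:
one master seed, per-subject substreams derived deterministically, so any
subject subset is reproducible on its own.

With `geometry = "tube"`, points lie on curves inside a bent cylinder and
the value is additionally shaped to fall from tube axis to surface and to
bump along the tract, so region maps look core-to-periphery and along-tract
profiles are non-trivial. The location-scale truth then no longer holds
exactly for pooled values; estimator-recovery work uses `geometry = "none"`.
What the generator does **not** emulate: crossing-fiber geometry, scanner
noise, tract segmentation errors, non-linear covariate effects. Passing
simulation studies here shows the estimator and its inference are correct
under the stated law, not that any particular real dataset satisfies it.

## Simulation study sizes

The packaged studies (the acceptance test suite and `scripts/acceptance.R`)
use: 30 replicate cohorts of 200 subjects x 50 points for coefficient
recovery at five levels; 500 replicates of 200 subjects x 20 points for CI
coverage; 100 null cohorts x 10 regions (1000 tests) for the type-I error
of the per-region test; and 100 tube cohorts of 50 subjects for the
three-method MSE comparison, with C = L = 10 there so the three methods are
compared at matched granularity on cohorts of that size. These sizes give
Monte-Carlo standard errors comfortably inside the bands being checked
(e.g. ~1% on a 95% coverage rate at 500 replicates) while keeping each
study to a few minutes on one core.

## Known limitations

* The per-region fits at very extreme levels lean on kernel density
  estimation in a sparse tail; standard errors there are the least stable,
  which is why degenerate-`B` conditions error loudly rather than warn.
* Quantile-crossing of fitted curves across levels is not corrected
  (a monotone-rearrangement check is a diagnostic, not an enforcement).
* The profile baseline implements the standard resample-orient-average
  recipe, not any specific external package's heuristics (no tract cropping
  or cleaning).
* TRK/TCK adapters pass coordinates through verbatim; no registration,
  resampling or unit interpretation happens at I/O time, and FA-range
  violations warn rather than error because MD-like scalars are legitimate
  inputs.
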