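# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit stream seed derived from a master seed and a label
# (subject index or id), so per-subject draws are reproducible in isolation.
derive_seed <- function(seed, label) {
  if (is.character(label)) label <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) + 48271 * as.numeric(label)) %% 2147483629L + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

# Empirical quantile, inverse-ECDF form: value at rank ceiling(tau * n),
# clamped to {1, ..., n}. Equivalent to stats::quantile type 1 for
# tau in (0, 1]; kept explicit because region construction depends on the
# exact rank convention.
quantile_rank_ceiling <- function(x_sorted, tau) {
  n <- length(x_sorted)
  idx <- pmin(pmax(ceiling(tau * n), 1L), n)
  x_sorted[idx]
}

empirical_quantile <- function(x, tau, estimator = c("inverse_ecdf", "linear")) {
  estimator <- match.arg(estimator)
  if (estimator == "inverse_ecdf") {
    quantile_rank_ceiling(sort(x), tau)
  } else {
    unname(stats::quantile(x, probs = tau, type = 7))
  }
}
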