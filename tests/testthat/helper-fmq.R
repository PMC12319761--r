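# Shared fixture builders: everything is generated in code at test time.

# A bundle whose streamlines carry prescribed values; coordinates are a
# straight line along z unless xyz is supplied.
toy_bundle <- function(subject_id, value_list, xyz = NULL) {
  streamlines <- lapply(seq_along(value_list), function(j) {
    v <- value_list[[j]]
    if (is.null(xyz)) {
      data.frame(x = 0, y = 0, z = seq_along(v) - 1, value = v)
    } else {
      data.frame(xyz[[j]], value = v)
    }
  })
  new_subject_bundle(subject_id, streamlines)
}

# A pool with prescribed values split evenly over two subjects.
toy_pool <- function(values, n_subjects = 2) {
  stopifnot(length(values) %% n_subjects == 0, length(values) >= 2 * n_subjects)
  per <- length(values) / n_subjects
  bundles <- lapply(seq_len(n_subjects), function(i) {
    toy_bundle(sprintf("s%02d", i),
               list(values[((i - 1) * per + 1):(i * per)]))
  })
  pool_bundles(bundles)
}

# Intercept-only design for a pool's subjects.
intercept_design <- function(pool) {
  ids <- unique(pool$records$subject_id)
  X <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  X
}

# Brute-force pinball minimization oracle, exact for p = 1 and p = 2:
# an LP optimum lies at a vertex, i.e. a coefficient vector interpolating
# p data points, so enumerating all p-subsets and scoring the objective
# yields the global minimum.
oracle_pinball_objective <- function(X, y, tau) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 2)
  best <- Inf
  if (p == 1) {
    for (k in seq_len(n)) {
      b <- y[k] / X[k, 1]
      if (!is.finite(b)) next
      obj <- sum(check_loss(y - X[, 1] * b, tau))
      if (obj < best) best <- obj
    }
  } else {
    for (a in seq_len(n - 1)) for (b2 in (a + 1):n) {
      M <- X[c(a, b2), , drop = FALSE]
      if (abs(det(M)) < 1e-12) next
      beta <- solve(M, y[c(a, b2)])
      obj <- sum(check_loss(y - drop(X %*% beta), tau))
      if (obj < best) best <- obj
    }
  }
  best
}

# Sample intraclass correlation of point values within subjects.
sample_icc <- function(pool) {
  v <- pool$records$value
  g <- pool$records$subject_id
  m <- tapply(v, g, mean)
  nb <- tapply(v, g, length)
  grand <- mean(v)
  msb <- sum(nb * (m[unique(g)] - grand)^2) / (length(m) - 1)
  msw <- sum((v - m[g])^2) / (length(v) - length(m))
  n0 <- mean(nb)
  (msb - msw) / (msb + (n0 - 1) * msw)
}
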