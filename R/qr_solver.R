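#' Check (pinball) loss
#'
#' \eqn{\rho_\tau(a) = a(\tau - 1[a < 0])}: the asymmetric absolute loss
#' whose expected-loss minimizer is the \eqn{\tau}-quantile. Convex,
#' piecewise linear, zero only at 0.
#'
#' @param a numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return Nonnegative numeric vector, same length as `a`.
#' @examples
#' check_loss(2, 0.3)   # 0.6
#' check_loss(-2, 0.3)  # 1.4
#' @export
check_loss <- function(a, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stopf("`tau` must lie strictly inside (0, 1)")
  a * (tau - (a < 0))
}

#' Linear quantile regression by interior-point linear programming
#'
#' Minimizes the summed check loss \eqn{\sum_k \rho_\tau(y_k - x_k'\beta)}
#' exactly, via a Mehrotra predictor-corrector primal-dual interior-point
#' method on the bounded-variable dual linear program
#' \deqn{\max\{y'a : X'a = (1-\tau)X'\mathbf{1},\ a \in [0,1]^n\},}
#' whose equality multipliers recover \eqn{-\hat\beta}. This is the
#' Frisch-Newton approach standard for quantile regression; each iteration
#' costs one p x p Cholesky solve, so dense problems with many points and few
#' design columns (the pooled-bundle case) solve in milliseconds.
#'
#' At quantile levels where the LP optimum is a face rather than a vertex
#' (\eqn{\tau n} integer for an intercept-only fit, say), any point of the
#' optimal face minimizes the loss; compare objectives, not coefficients, in
#' such degenerate cases.
#'
#' @param X numeric design matrix (n x p), full column rank.
#' @param y numeric response vector (length n).
#' @param tau quantile level in (0, 1).
#' @param tol duality-gap convergence tolerance (relative).
#' @param max_iter iteration cap; exceeding it throws an error with
#'   diagnostics.
#' @return List with `coefficients`, `objective` (minimized check loss),
#'   `residuals`, `iterations`, `converged`.
#' @export
pinball_fit <- function(X, y, tau, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("length(y) = %d but nrow(X) = %d", length(y), n)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stopf("`tau` must lie strictly inside (0, 1)")
  if (n < p) stopf("need at least as many points as design columns")
  qrX <- qr(X)
  if (qrX$rank < p)
    stopf("design matrix is rank deficient (rank %d < %d columns)", qrX$rank, p)

  # LP (in x): min c'x s.t. A x = b, 0 <= x <= 1, with A = t(X), c = -y.
  cvec <- -y
  b <- (1 - tau) * colSums(X)
  x <- rep(1 - tau, n); s <- rep(tau, n)            # primal, strictly interior
  yd <- qr.coef(qrX, -y)                            # equality multipliers
  r <- cvec - drop(X %*% yd)                        # must equal z - w
  eps0 <- 1e-5 * max(1, mean(abs(r)))
  z <- pmax(r, 0) + eps0
  w <- z - r                                        # >= eps0, dual feasible
  beta_factor <- 0.99995

  gap_denom <- function() 1 + abs(sum(cvec * x))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- (sum(x * z) + sum(s * w)) / (2 * n)
    # duality gap: c'x - (b'yd - 1'w)
    gap <- sum(cvec * x) - (sum(b * yd) - sum(w))
    if (abs(gap) / gap_denom() < tol && mu < tol) { converged <- TRUE; break }

    d <- 1 / (z / x + w / s)
    XD <- X * d
    M <- crossprod(XD, X)                           # X' D X, p x p
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch))
      stopf("interior-point normal matrix became singular at iteration %d", it)

    solve_dir <- function(t1, t2) {
      # Newton direction for complementarity targets X Z e -> t1, S W e -> t2;
      # the linear residuals are held at zero exactly (A dx = 0, dx + ds = 0,
      # A'dy + dz - dw = 0), which reduces to (A D A') dy = A D rhs_v with
      # rhs_v = -t1/x + t2/s and dx = D (A'dy - rhs_v).
      rhs_v <- -t1 / x + t2 / s
      dy <- backsolve(ch, forwardsolve(t(ch), crossprod(XD, rhs_v)))
      dx <- d * (drop(X %*% dy) - rhs_v)
      ds <- -dx
      dz <- (t1 - z * dx) / x
      dw <- (t2 + w * dx) / s
      list(dy = dy, dx = dx, ds = ds, dz = dz, dw = dw)
    }
    step_len <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, beta_factor * min(-v[neg] / dv[neg]))
    }

    aff <- solve_dir(-x * z, -s * w)
    ap <- min(step_len(x, aff$dx), step_len(s, aff$ds))
    ad <- min(step_len(z, aff$dz), step_len(w, aff$dw))
    mu_aff <- (sum((x + ap * aff$dx) * (z + ad * aff$dz)) +
               sum((s + ap * aff$ds) * (w + ad * aff$dw))) / (2 * n)
    sigma <- (mu_aff / mu)^3

    cor <- solve_dir(-x * z - aff$dx * aff$dz + sigma * mu,
                     -s * w - aff$ds * aff$dw + sigma * mu)
    ap <- min(step_len(x, cor$dx), step_len(s, cor$ds))
    ad <- min(step_len(z, cor$dz), step_len(w, cor$dw))
    x <- x + ap * cor$dx; s <- s + ap * cor$ds
    z <- z + ad * cor$dz; w <- w + ad * cor$dw
    yd <- yd + ad * cor$dy
  }
  if (!converged) {
    mu <- (sum(x * z) + sum(s * w)) / (2 * n)
    stopf(paste0("quantile regression did not converge in %d iterations ",
                 "(duality measure %.3g, tau = %.4g, n = %d, p = %d)"),
          max_iter, mu, tau, n, p)
  }
  beta <- -drop(yd)
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  list(coefficients = beta,
       objective = sum(check_loss(res, tau)),
       residuals = res,
       iterations = it,
       converged = converged)
}
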