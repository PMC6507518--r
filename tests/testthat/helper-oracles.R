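# Independent dense-matrix oracles and small data builders shared across
# the test files.  The oracles deliberately build full per-cluster
# covariance matrices and use solve()/determinant(), taking a different
# route than the package's 2x2 Woodbury implementation.

toy_dataset <- function(K = 4, sizes = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(sizes)) sizes <- sample(2:4, K, replace = TRUE)
  cl <- rep(sprintf("k%02d", seq_len(K)), sizes)
  t <- unlist(lapply(sizes, function(n) {
    # guarantee at least one treated and one control where possible
    if (n >= 2) sample(c(1L, 0L, sample(0:1, n - 2, replace = TRUE)))
    else sample(0:1, 1)
  }))
  clustered_dataset(cl, t, rnorm(length(cl), mean = 10, sd = 3))
}

dense_cluster_V <- function(t, w, vc) {
  Z <- cbind(t, 1 - t)
  Omega <- matrix(c(vc$sigma1_sq,
                    vc$rho * sqrt(vc$sigma1_sq * vc$sigma0_sq),
                    vc$rho * sqrt(vc$sigma1_sq * vc$sigma0_sq),
                    vc$sigma0_sq), 2, 2)
  Z %*% Omega %*% t(Z) + vc$sigma_eps_sq * diag(1 / w, length(w))
}

# full multivariate-normal weighted log-likelihood, dense route
dense_loglik <- function(d, w, v, spec, beta, vc) {
  ids <- unique(d$cluster_id)
  tbar_all <- tapply(d$t, factor(d$cluster_id, levels = ids), mean)
  ll <- 0
  for (k in seq_along(ids)) {
    rows <- which(d$cluster_id == ids[k])
    t <- d$t[rows]
    X <- spec$build(t, rep(tbar_all[k], length(rows)))
    V <- dense_cluster_V(t, w[rows], vc)
    r <- d$y[rows] - as.numeric(X %*% beta)
    ll <- ll + v[k] * (-0.5) * (length(rows) * log(2 * pi) +
      determinant(V, logarithm = TRUE)$modulus +
      sum(r * solve(V, r)))
  }
  as.numeric(ll)
}

dense_gls <- function(d, w, v, spec, vc) {
  ids <- unique(d$cluster_id)
  tbar_all <- tapply(d$t, factor(d$cluster_id, levels = ids), mean)
  p <- ncol(spec$build(0, 0))
  A <- matrix(0, p, p); b <- numeric(p)
  for (k in seq_along(ids)) {
    rows <- which(d$cluster_id == ids[k])
    t <- d$t[rows]
    X <- spec$build(t, rep(tbar_all[k], length(rows)))
    V <- dense_cluster_V(t, w[rows], vc)
    A <- A + v[k] * t(X) %*% solve(V, X)
    b <- b + v[k] * t(X) %*% solve(V, d$y[rows])
  }
  list(beta = as.numeric(solve(A, b)), cov = solve(A))
}

dense_sandwich <- function(d, w, beta, vc) {
  ids <- unique(d$cluster_id)
  p <- 2
  bread <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (k in seq_along(ids)) {
    rows <- which(d$cluster_id == ids[k])
    t <- d$t[rows]
    X <- cbind(beta1 = t, beta0 = 1 - t)
    W <- solve(dense_cluster_V(t, w[rows], vc))
    r <- d$y[rows] - as.numeric(X %*% beta[c("beta1", "beta0")])
    bread <- bread + t(X) %*% W %*% X
    m <- t(X) %*% W %*% r
    meat <- meat + m %*% t(m)
  }
  cov <- solve(bread) %*% meat %*% solve(bread)
  dimnames(cov) <- list(c("beta1", "beta0"), c("beta1", "beta0"))
  cov[c("beta0", "beta1"), c("beta0", "beta1")]
}

# Monte Carlo oracle for the latent-index assignment mechanism: simulates
# units directly from the mechanism and measures (p, r0, r1) and the
# violating-cluster fraction.
mc_assignment_oracle <- function(coeffs, sigma0, sigma1, rho, nk_range,
                                 nclust = 2e5, seed = 99) {
  set.seed(seed)
  z1 <- rnorm(nclust); z2 <- rnorm(nclust)
  b1 <- sigma1 * z1
  b0 <- sigma0 * (rho * z1 + sqrt(1 - rho^2) * z2)
  u <- coeffs$c1 + coeffs$c2 * b0 + coeffs$c3 * b1 +
    coeffs$c4 * rnorm(nclust)
  # one unit per cluster for the unit-level moments
  t1 <- as.integer(u + rnorm(nclust) > 0)
  # violating fraction over the cluster-size law
  n <- sample(seq(nk_range[1], nk_range[2]), nclust, replace = TRUE)
  n1 <- rbinom(nclust, n, pnorm(u))
  list(p = mean(t1), r0 = cor(t1, b0), r1 = cor(t1, b1),
       violation_frac = mean(n1 == 0L | n1 == n))
}
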