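test_that("weighted log-likelihood matches elementary closed forms", {
  # one unit, unit weight, no random effects, unit residual variance
  d <- clustered_dataset("a", 1, 0)
  w <- uniform_weights(d)
  vc <- variance_components(0, 0, 0, 1)
  ll <- weighted_loglik(d, w, model_spec("two_arm"), c(0, 0), vc)
  expect_equal(ll, -0.5 * log(2 * pi))

  # doubling every cluster weight doubles the log-likelihood exactly
  d2 <- toy_dataset(K = 4, seed = 2)
  w1 <- uniform_weights(d2)
  w2 <- w1; w2$v <- 2 * w2$v
  vc2 <- variance_components(2, 3, 0.4, 1.5)
  beta <- c(9, 11)
  expect_equal(weighted_loglik(d2, w2, model_spec("two_arm"), beta, vc2),
               2 * weighted_loglik(d2, w1, model_spec("two_arm"), beta, vc2))
})

test_that("log-likelihood and GLS match the dense-matrix oracle", {
  for (seed in 1:4) {
    d <- toy_dataset(K = 5, sizes = sample(1:4, 5, replace = TRUE),
                     seed = seed)
    set.seed(seed + 100)
    wvec <- runif(nrow(d), 0.3, 2.5)
    v <- runif(5, 0.5, 2)
    names(v) <- unique(d$cluster_id)
    w <- uniform_weights(d); w$w <- wvec; w$v <- v
    vc <- variance_components(1.7, 2.9, -0.45, 1.2)
    for (design in c("two_arm", "rsatc")) {
      spec <- model_spec(design)
      beta <- rnorm(ncol(spec$build(0, 0)))
      expect_equal(weighted_loglik(d, w, spec, beta, vc),
                   dense_loglik(d, wvec, unname(v), spec, beta, vc),
                   tolerance = 1e-8)
      g <- gls_fixed_effects(d, w, spec, vc)
      oracle <- dense_gls(d, wvec, unname(v), spec, vc)
      expect_equal(unname(g$beta), oracle$beta, tolerance = 1e-8)
      expect_equal(unname(g$cov), unname(oracle$cov), tolerance = 1e-8)
    }
  }
})

test_that("GLS reduces to OLS with one cluster, no random effects", {
  d <- toy_dataset(K = 1, sizes = 6, seed = 5)
  vc <- variance_components(0, 0, 0, 2)
  g <- gls_fixed_effects(d, uniform_weights(d), model_spec("two_arm"), vc)
  ols <- c(mean(d$y[d$t == 1]), mean(d$y[d$t == 0]))
  expect_equal(unname(g$beta), ols, tolerance = 1e-10)
})

test_that("GLS estimates are invariant to cluster permutation", {
  d <- toy_dataset(K = 6, seed = 6)
  vc <- variance_components(2, 2, 0.3, 1)
  g1 <- gls_fixed_effects(d, uniform_weights(d), model_spec("two_arm"), vc)
  ids <- unique(d$cluster_id)
  ord <- order(match(d$cluster_id, rev(ids)))
  dp <- validate_clustered_dataset(as.data.frame(d)[ord, ])
  g2 <- gls_fixed_effects(dp, uniform_weights(dp), model_spec("two_arm"), vc)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-10)
})

test_that("fit recovers arm means on pure-noise data and true effects on
           randomized data", {
  # pure noise: no cluster structure, so beta approaches the arm means
  set.seed(7)
  d <- clustered_dataset(rep(sprintf("k%02d", 1:40), each = 25),
                         rbinom(1000, 1, 0.5), rnorm(1000, 20, 4))
  f <- fit_weighted_hlm(d, uniform_weights(d), model_spec("two_arm"))
  expect_true(f$converged)
  expect_equal(unname(f$beta),
               c(mean(d$y[d$t == 1]), mean(d$y[d$t == 0])),
               tolerance = 0.01)

  # completely randomized assignment with real cluster structure
  set.seed(8)
  K <- 500; n <- 20
  b1 <- 4 * rnorm(K); b0 <- 3 * rnorm(K)
  cl <- rep(seq_len(K), each = n)
  t <- rbinom(K * n, 1, 0.4)
  y <- ifelse(t == 1, 40 + b1[cl], 35 + b0[cl]) + 6 * rnorm(K * n)
  d2 <- clustered_dataset(sprintf("k%03d", cl), t, y)
  f2 <- fit_weighted_hlm(d2, uniform_weights(d2), model_spec("two_arm"))
  se <- sqrt(diag(f2$cov_beta))
  expect_lt(abs(f2$beta[["beta1"]] - 40), 3 * se[["beta1"]])
  expect_lt(abs(f2$beta[["beta0"]] - 35), 3 * se[["beta0"]])
  expect_equal(sqrt(f2$vc$sigma1_sq), 4, tolerance = 0.2)
  expect_equal(sqrt(f2$vc$sigma_eps_sq), 6, tolerance = 0.05)
})

test_that("refitting from the returned estimates is idempotent", {
  d <- toy_dataset(K = 12, sizes = rep(6, 12), seed = 9)
  w <- uniform_weights(d)
  f1 <- fit_weighted_hlm(d, w, model_spec("two_arm"))
  f2 <- fit_weighted_hlm(d, w, model_spec("two_arm"),
                         options = list(start = f1$vc))
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-7)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
})

test_that("maximized log-likelihood ignores cluster labels and row order", {
  d <- toy_dataset(K = 8, sizes = rep(5, 8), seed = 10)
  w <- uniform_weights(d)
  f1 <- fit_weighted_hlm(d, w, model_spec("two_arm"))
  set.seed(11)
  perm <- sample(nrow(d))
  dp <- as.data.frame(d)[perm, ]
  dp$cluster_id <- paste0("relabel_", dp$cluster_id)
  dp <- validate_clustered_dataset(dp)
  f2 <- fit_weighted_hlm(dp, uniform_weights(dp), model_spec("two_arm"))
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
})

test_that("unweighted fit agrees with an independent mixed-model
           implementation", {
  skip_if_not_installed("lme4")
  set.seed(12)
  K <- 60; n <- 8
  b1 <- 3 * rnorm(K); b0 <- 2.4 * rnorm(K)
  cl <- rep(seq_len(K), each = n)
  t <- rbinom(K * n, 1, 0.5)
  y <- ifelse(t == 1, 12 + b1[cl], 10 + b0[cl]) + 2 * rnorm(K * n)
  d <- clustered_dataset(sprintf("k%03d", cl), t, y)
  f <- fit_weighted_hlm(d, uniform_weights(d), model_spec("two_arm"))
  df <- as.data.frame(d); df$t0 <- 1 - df$t
  lf <- lme4::lmer(y ~ 0 + t + t0 + (0 + t + t0 | cluster_id),
                   data = df, REML = FALSE)
  expect_equal(f$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(lme4::fixef(lf)[c("t", "t0")]),
               tolerance = 1e-4)

  # and with non-constant precision weights
  set.seed(13)
  wts <- uniform_weights(d); wts$w <- runif(nrow(d), 0.5, 2)
  fw <- fit_weighted_hlm(d, wts, model_spec("two_arm"))
  df$w <- wts$w
  lw <- lme4::lmer(y ~ 0 + t + t0 + (0 + t + t0 | cluster_id),
                   data = df, weights = w, REML = FALSE)
  expect_equal(fw$loglik, as.numeric(stats::logLik(lw)), tolerance = 1e-5)
  expect_equal(unname(fw$beta), unname(lme4::fixef(lw)[c("t", "t0")]),
               tolerance = 1e-4)
})

test_that("BLUPs shrink to zero for an arm with no observations when
           rho = 0", {
  d <- clustered_dataset(rep(c("a", "b"), each = 4),
                         c(1, 1, 0, 0, 0, 0, 0, 0),
                         c(5, 6, 1, 2, 8, 9, 7, 8))
  w <- uniform_weights(d)
  prep <- aiptw:::prepare_hlm(d, w, model_spec("two_arm"))
  vc0 <- variance_components(4, 4, 0, 1)
  res <- aiptw:::.core(prep, vc0, profile_beta = TRUE, want_blups = TRUE)
  # cluster b has no treated units: its b_k1 prediction is exactly zero
  expect_identical(res$blups[2, 1], 0)
  # with correlated effects, information flows across arms instead
  vc_r <- variance_components(4, 4, 0.8, 1)
  res_r <- aiptw:::.core(prep, vc_r, profile_beta = TRUE, want_blups = TRUE)
  expect_gt(abs(res_r$blups[2, 1]), 0)
})

test_that("a design column without support raises a clear error", {
  d <- clustered_dataset(c("a", "a", "b"), c(1, 1, 1), rnorm(3))
  expect_error(
    fit_weighted_hlm(d, uniform_weights(d), model_spec("two_arm")),
    "beta0")
})
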