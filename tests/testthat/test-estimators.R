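test_that("trimming keeps exactly the mixed clusters", {
  d <- clustered_dataset(rep(c("a", "b", "c"), each = 3),
                         c(1, 0, 0, 1, 1, 1, 0, 0, 0), rnorm(9))
  tr <- trim_clusters(d)
  expect_equal(unique(tr$cluster_id), "a")
  expect_equal(nrow(tr), 3L)

  d2 <- toy_dataset(K = 4, sizes = rep(4, 4), seed = 31)
  if (all(cluster_summaries(d2)$status == "mixed")) {
    expect_equal(as.data.frame(trim_clusters(d2)), as.data.frame(d2))
  }
  d3 <- clustered_dataset(c("a", "b"), c(1, 0), rnorm(2))
  expect_error(trim_clusters(d3), "empty")
})

test_that("under a high-violation design about 20% of clusters survive
           trimming", {
  cfg <- scenario_preset("setting1_80")
  co <- calibrate_assignment(cfg)
  frac <- vapply(1:20, function(i) {
    d <- generate_dataset(cfg, co, 500 + i)
    s <- cluster_summaries(d)
    mean(s$status == "mixed")
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.20), 0.04)
})

test_that("constant propensity makes the weighted fit equal the
           unweighted one", {
  set.seed(32)
  cl <- rep(sprintf("k%02d", 1:12), each = 10)
  t <- unlist(replicate(12, sample(rep(c(1L, 0L), c(3, 7)))))
  d <- clustered_dataset(cl, t, rnorm(120, 20, 5))
  e <- iptw_orig(d)
  expect_equal(e$weights$w, rep(1, 120))
  f0 <- fit_weighted_hlm(d, uniform_weights(d), model_spec("two_arm"))
  expect_equal(e$beta1_hat, unname(f0$beta[["beta1"]]), tolerance = 1e-8)
  expect_equal(e$beta0_hat, unname(f0$beta[["beta0"]]), tolerance = 1e-8)
})

test_that("augmentation reduces to the identity without violations and
           AIPTW equals IPTW-orig exactly", {
  set.seed(33)
  cl <- rep(sprintf("k%02d", 1:10), each = 6)
  t <- unlist(replicate(10, sample(c(1L, 1L, 0L, 0L, 0L, 0L))))
  d <- clustered_dataset(cl, t, rnorm(60, 15, 4))
  aug <- build_augmented_data(d, "satc")
  expect_identical(as.data.frame(aug), as.data.frame(d))
  ei <- iptw_orig(d)
  ea <- aiptw(d, "satc")
  expect_identical(ea$beta0_hat, ei$beta0_hat)
  expect_identical(ea$beta1_hat, ei$beta1_hat)
  expect_identical(ea$delta_hat, ei$delta_hat)
  expect_identical(unclass(ea$vc_hat), unclass(ei$vc_hat))
})

test_that("augmented weights follow the hand-derived algebra", {
  # clusters: one all-control of size 5, two mixed
  d <- clustered_dataset(
    rep(c("v", "m1", "m2"), c(5, 4, 4)),
    c(rep(0L, 5), 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
    rnorm(13, 10, 2))
  aug <- build_augmented_data(d, "satc")
  expect_equal(nrow(aug), nrow(d) + 1L)
  s <- cluster_summaries(aug)
  expect_equal(s$n_k[s$cluster_id == "v"], 6L)
  prop <- estimate_propensity(s)
  expect_equal(prop$pi_hat[prop$cluster_id == "v"], 1 / 6)
  w <- compute_unit_weights(aug, prop)
  cc <- w$c
  wv <- w$w[aug$cluster_id == "v"]
  tv <- aug$t[aug$cluster_id == "v"]
  expect_equal(wv[tv == 1], 6 * cc)
  expect_equal(wv[tv == 0], rep((1 - cc) * 6 / 5, 5))
  expect_equal(sum(wv), 6)
  # the pseudo-row carries the SATC prediction for the treated arm
  fit <- attr(aug, "correction_fit")
  expect_equal(aug$y[aug$is_pseudo],
               predict_missing_arm(fit, "all_control"))
})

test_that("pseudo-units never alter the estimand cluster weights", {
  d <- clustered_dataset(
    rep(c("v", "m1", "m2"), c(3, 6, 6)),
    c(rep(1L, 3), 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    rnorm(15, 8, 2))
  e <- aiptw(d, "rsatc", estimand = "school_population")
  s_obs <- cluster_summaries(d)
  expect_equal(e$weights$v, cluster_weights(s_obs, "school_population"))
})

test_that("a single surviving mixed cluster yields its arm-mean
           difference", {
  d <- clustered_dataset(
    rep(c("a", "b"), c(4, 3)),
    c(1L, 1L, 0L, 0L, 0L, 0L, 0L),
    c(12, 14, 7, 9, 5, 6, 4))
  e <- iptw_trim(d)
  expect_equal(e$n_clusters_used, 1L)
  expect_equal(e$delta_hat, mean(c(12, 14)) - mean(c(7, 9)),
               tolerance = 1e-6)
})

test_that("every estimator is location-equivariant", {
  cfg <- scenario_preset("setting1_80")
  co <- calibrate_assignment(cfg)
  d <- generate_dataset(cfg, co, 777)
  shifted <- as.data.frame(d); shifted$y <- shifted$y + 9
  ds <- validate_clustered_dataset(shifted)
  for (method in c("iptw_orig", "iptw_trim")) {
    f <- get(method)
    e1 <- f(d); e2 <- f(ds)
    expect_equal(e2$beta0_hat - e1$beta0_hat, 9, tolerance = 1e-4)
    expect_equal(e2$beta1_hat - e1$beta1_hat, 9, tolerance = 1e-4)
    expect_equal(e2$delta_hat, e1$delta_hat, tolerance = 1e-4)
  }
  for (model in c("satc", "rsatc")) {
    e1 <- aiptw(d, model); e2 <- aiptw(ds, model)
    expect_equal(e2$beta0_hat - e1$beta0_hat, 9, tolerance = 1e-4)
    expect_equal(e2$delta_hat, e1$delta_hat, tolerance = 1e-4)
  }
  e1 <- aiptw_nonparametric(d, "satc")
  e2 <- aiptw_nonparametric(ds, "satc")
  expect_equal(e2$delta_hat, e1$delta_hat, tolerance = 1e-6)
})

test_that("the nonparametric contrast reproduces the hand-computed toy", {
  # cluster A mixed: treated mean 10, control mean 6; cluster B
  # all-control with mean 6 and predicted treated outcome 8
  d <- clustered_dataset(
    c("A", "A", "A", "A", "B", "B"),
    c(1L, 1L, 0L, 0L, 0L, 0L),
    c(9, 11, 5, 7, 5.5, 6.5))
  expect_equal(nonparametric_delta(d, c(B = 8)), ((10 - 6) + (8 - 6)) / 2)
  # without violations it is the mean of within-cluster arm differences
  d2 <- clustered_dataset(rep(c("A", "B"), each = 4),
                          rep(c(1L, 1L, 0L, 0L), 2),
                          c(4, 6, 1, 3, 10, 12, 7, 9))
  expect_equal(nonparametric_delta(d2, numeric(0)), ((5 - 2) + (11 - 8)) / 2)
})

test_that("parametric and nonparametric AIPTW agree on a large sharp
           dataset", {
  cfg <- scenario_config(K = 800, nk_range = c(1, 9), beta = c(10, 15),
                         sigma0 = 3, sigma1 = 3, rho = 0.3, sigma_eps = 5,
                         r0 = 0.2, r1 = 0.2, p = 0.4,
                         violation_frac = 0.35)
  co <- calibrate_assignment(cfg)
  d <- generate_dataset(cfg, co, 41)
  ep <- aiptw(d, "satc")
  en <- aiptw_nonparametric(d, "satc")
  expect_lt(abs(en$delta_hat - ep$delta_hat), 0.6)
  expect_lt(abs(en$delta_hat - 5), 0.6)
})

test_that("all four estimators are nearly unbiased under 26% violations", {
  rp <- run_replications(
    scenario_preset("setting1_26"),
    methods = c("iptw_orig", "iptw_trim", "aiptw_satc", "aiptw_rsatc"),
    R = 300, master_seed = 26)
  m <- rp$metrics[rp$metrics$param %in% c("beta0", "beta1"), ]
  expect_true(all(abs(m$pb) < 0.05))
  pb0 <- rp$metrics$pb[rp$metrics$method == "iptw_orig" &
                         rp$metrics$param == "beta0"]
  expect_lt(abs(pb0 - (-0.004)), 0.02)
})
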