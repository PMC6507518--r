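test_that("analytic treatment moments handle the symmetric null and
           sign flips", {
  null <- list(c1 = 0, c2 = 0, c3 = 0, c4 = 0)
  expect_equal(analytic_treatment_moments(null, 8, 8, 0.5),
               c(p = 0.5, r0 = 0, r1 = 0))
  a <- list(c1 = -0.4, c2 = 0.15, c3 = 0, c4 = 1)
  b <- list(c1 = -0.4, c2 = -0.15, c3 = 0, c4 = 1)
  ma <- analytic_treatment_moments(a, 8, 8, 0)
  mb <- analytic_treatment_moments(b, 8, 8, 0)
  expect_equal(mb[["r0"]], -ma[["r0"]])
  expect_equal(mb[["p"]], ma[["p"]])
})

test_that("analytic moments match the Monte Carlo oracle", {
  cfg <- scenario_preset("setting1_80")
  co <- calibrate_assignment(cfg)
  mom <- analytic_treatment_moments(co, cfg$sigma0, cfg$sigma1, cfg$rho)
  mc <- mc_assignment_oracle(co, cfg$sigma0, cfg$sigma1, cfg$rho,
                             cfg$nk_range, nclust = 2e5, seed = 71)
  n <- 2e5
  expect_lt(abs(mom[["p"]] - mc$p), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(mom[["r0"]] - mc$r0), 3 / sqrt(n) + 0.005)
  expect_lt(abs(mom[["r1"]] - mc$r1), 3 / sqrt(n) + 0.005)
})

test_that("violation fraction: forced, closed-form and cross-checked
           cases", {
  # singleton clusters always violate
  one <- list(c1 = -0.5, c2 = 0.1, c3 = 0.1, c4 = 0.5)
  expect_equal(expected_violation_fraction(one, 8, 8, 0.5, c(1, 1)), 1,
               tolerance = 1e-8)
  # constant propensity: closed form over the size law
  const <- list(c1 = qnorm(0.3), c2 = 0, c3 = 0, c4 = 0)
  ns <- 1:19
  expect_equal(expected_violation_fraction(const, 8, 8, 0.5, c(1, 19)),
               mean(0.3^ns + 0.7^ns), tolerance = 1e-8)
  # quadrature and Monte Carlo agree
  cfg <- scenario_preset("setting1_80")
  co <- calibrate_assignment(cfg)
  vq <- expected_violation_fraction(co, 8, 8, 0.8, c(1, 19))
  vm <- expected_violation_fraction(co, 8, 8, 0.8, c(1, 19),
                                    method = "mc", ndraw = 2e5, seed = 72)
  expect_lt(abs(vq - vm), 3 * sqrt(0.8 * 0.2 / 2e5))
})

test_that("calibration round-trips all four targets against the MC
           oracle", {
  for (nm in c("setting1_80", "setting2_r04_rm04")) {
    cfg <- scenario_preset(nm)
    co <- calibrate_assignment(cfg)
    mc <- mc_assignment_oracle(co, cfg$sigma0, cfg$sigma1, cfg$rho,
                               cfg$nk_range, nclust = 2e5, seed = 73)
    slack <- 3 / sqrt(2e5)   # MC-oracle noise on top of the 0.01 budget
    expect_lt(abs(mc$p - cfg$p), 0.01 + slack)
    expect_lt(abs(mc$r0 - cfg$r0), 0.01 + slack)
    expect_lt(abs(mc$r1 - cfg$r1), 0.01 + slack)
    expect_lt(abs(mc$violation_frac - cfg$violation_frac), 0.01 + slack)
  }
})

test_that("null targets give a null mechanism", {
  cfg <- scenario_config(K = 50, nk_range = c(2, 10), beta = c(0, 1),
                         sigma0 = 8, sigma1 = 8, rho = 0.5, sigma_eps = 1,
                         r0 = 0, r1 = 0, p = 0.5, violation_frac = 0.3)
  co <- calibrate_assignment(cfg)
  expect_equal(co$c1, 0, tolerance = 1e-6)
  expect_equal(co$c2, 0, tolerance = 1e-6)
  expect_equal(co$c3, 0, tolerance = 1e-6)
})

test_that("infeasible targets are reported, not silently adjusted", {
  cfg <- scenario_config(K = 50, nk_range = c(2, 10), beta = c(0, 1),
                         sigma0 = 8, sigma1 = 8, rho = 0, sigma_eps = 1,
                         r0 = 0.8, r1 = 0.8, p = 0.5,
                         violation_frac = 0.5)
  expect_error(calibrate_assignment(cfg), "infeasible")
})

test_that("generated data obey the observed-outcome identity and are
           seed-reproducible", {
  cfg <- scenario_preset("setting1_26")
  co <- calibrate_assignment(cfg)
  d1 <- generate_dataset(cfg, co, 74)
  d2 <- generate_dataset(cfg, co, 74)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  tr <- attr(d1, "truth")
  expect_identical(d1$y, d1$t * tr$y1 + (1 - d1$t) * tr$y0)
  expect_equal(nrow(cluster_summaries(d1)), cfg$K)
  d3 <- generate_dataset(cfg, co, 75)
  expect_false(identical(d1$y, d3$y))
})

test_that("generated samples hit the calibrated targets on average", {
  cfg <- scenario_preset("setting1_26")
  co <- calibrate_assignment(cfg)
  viol <- r0 <- p <- gap <- numeric(30)
  for (i in 1:30) {
    d <- generate_dataset(cfg, co, 800 + i)
    s <- cluster_summaries(d)
    tr <- attr(d, "truth")
    viol[i] <- mean(s$status != "mixed")
    cl <- match(d$cluster_id, s$cluster_id)
    r0[i] <- cor(d$t, tr$b[cl, "b_k0"])
    p[i] <- mean(d$t)
    gap[i] <- mean(tr$y1 - tr$y0)
  }
  expect_lt(abs(mean(viol) - 0.26), 0.025)
  expect_lt(abs(mean(r0) - 0.4), 0.03)
  expect_lt(abs(mean(p) - 0.3), 0.03)
  expect_lt(abs(mean(gap) - 5), 3 * sd(gap) / sqrt(30))
})

test_that("YAML scenarios mirror the presets", {
  for (nm in c("setting1_80", "setting2_r04_rm04")) {
    path <- system.file("extdata", "scenarios", paste0(nm, ".yaml"),
                        package = "aiptw")
    expect_true(nzchar(path))
    expect_equal(unclass(read_scenario(path)),
                 unclass(scenario_preset(nm)))
  }
})
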