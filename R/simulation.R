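#' Simulation scenario configuration
#'
#' Full generative specification for the clustered potential-outcome model
#' with a latent-index treatment assignment.  Outcomes follow
#' `Y(1) = beta1 + b_k1 + eps(1)`, `Y(0) = beta0 + b_k0 + eps(0)` with
#' `(b_k1, b_k0) ~ N(0, Omega)` and `eps ~ N(0, sigma_eps^2)`; treatment is
#' `t = 1` iff `c1 + c2 b_k0 + c3 b_k1 + c4 zeta_k + xi_ik > 0` with
#' standard-normal `zeta_k` (cluster level) and `xi_ik` (unit level).  The
#' assignment coefficients are calibrated to hit the four targets: `r0 =
#' cor(t, b_k0)`, `r1 = cor(t, b_k1)`, the overall treatment probability
#' `p`, and the expected fraction of violating clusters.
#'
#' @param K number of clusters.
#' @param nk_range integer `c(lo, hi)` of the discrete-uniform cluster-size
#'   law.
#' @param beta numeric `c(beta0, beta1)` population arm means.
#' @param sigma0,sigma1 between-cluster standard deviations.
#' @param rho correlation of `(b_k1, b_k0)`.
#' @param sigma_eps residual standard deviation.
#' @param r0,r1 target correlations of treatment with `b_k0` and `b_k1`.
#' @param p target overall treatment probability in (0, 1).
#' @param violation_frac target expected fraction of clusters with
#'   `n_k1 = 0` or `n_k1 = n_k`, in `[0, 1)`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(K, nk_range, beta, sigma0, sigma1, rho,
                            sigma_eps, r0, r1, p, violation_frac) {
  stopifnot(K >= 1, length(nk_range) == 2, nk_range[1] >= 1,
            nk_range[2] >= nk_range[1], length(beta) == 2,
            sigma0 >= 0, sigma1 >= 0, abs(rho) < 1, sigma_eps > 0,
            p > 0, p < 1, violation_frac >= 0, violation_frac < 1)
  structure(list(K = as.integer(K), nk_range = as.integer(nk_range),
                 beta = as.numeric(beta), sigma0 = sigma0, sigma1 = sigma1,
                 rho = rho, sigma_eps = sigma_eps, r0 = r0, r1 = r1,
                 p = p, violation_frac = violation_frac),
            class = "scenario_config")
}

#' Shipped scenario presets
#'
#' Two study designs are shipped.  Setting 1: `K = 150`, cluster sizes
#' discrete-uniform on 1..19, `beta = (35, 40)`, `sigma0 = sigma1 = 8`,
#' `rho = 0.8`, `sigma_eps = 45`, `r0 = r1 = 0.4`, `p = 0.3`, with a 26%
#' or 80% violation-fraction variant.  Setting 2: `K = 200`, sizes 1..49,
#' `beta = (12, 15)`, `sigma0 = sigma1 = 8`, `sigma_eps = 35`, `p = 0.3`,
#' 80% violations, with `(r0, r1, rho)` grids covering equal, unequal and
#' opposite-signed treatment/random-effect correlations.
#'
#' @param name one of `"setting1_26"`, `"setting1_80"`,
#'   `"setting2_r04_r04"`, `"setting2_r02_r06"`, `"setting2_r04_rm04"`,
#'   `"setting2_r04_rm04_rhom03"`, `"setting2_r04_rm04_rhom08"`,
#'   `"setting2_r06_rm06_rhom08"`.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name) {
  s1 <- function(vf) scenario_config(K = 150, nk_range = c(1, 19),
                                     beta = c(35, 40), sigma0 = 8,
                                     sigma1 = 8, rho = 0.8, sigma_eps = 45,
                                     r0 = 0.4, r1 = 0.4, p = 0.3,
                                     violation_frac = vf)
  s2 <- function(r0, r1, rho) scenario_config(K = 200, nk_range = c(1, 49),
                                              beta = c(12, 15), sigma0 = 8,
                                              sigma1 = 8, rho = rho,
                                              sigma_eps = 35, r0 = r0,
                                              r1 = r1, p = 0.3,
                                              violation_frac = 0.80)
  switch(name,
    setting1_26 = s1(0.26),
    setting1_80 = s1(0.80),
    setting2_r04_r04 = s2(0.4, 0.4, 0.3),
    setting2_r02_r06 = s2(0.2, 0.6, 0.3),
    setting2_r04_rm04 = s2(0.4, -0.4, 0.3),
    setting2_r04_rm04_rhom03 = s2(0.4, -0.4, -0.3),
    setting2_r04_rm04_rhom08 = s2(0.4, -0.4, -0.8),
    setting2_r06_rm06_rhom08 = s2(0.6, -0.6, -0.8),
    stop("unknown preset: ", name))
}

#' Read a scenario configuration from YAML
#'
#' The YAML schema mirrors the [scenario_config()] fields.
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_config(K = y$K, nk_range = unlist(y$nk_range),
                  beta = unlist(y$beta), sigma0 = y$sigma0,
                  sigma1 = y$sigma1, rho = y$rho, sigma_eps = y$sigma_eps,
                  r0 = y$r0, r1 = y$r1, p = y$p,
                  violation_frac = y$violation_frac)
}

# Latent scale implied by assignment coefficients.
latent_scale <- function(coeffs, sigma0, sigma1, rho) {
  with(coeffs, sqrt(c2^2 * sigma0^2 + c3^2 * sigma1^2 +
                      2 * c2 * c3 * rho * sigma0 * sigma1 + c4^2 + 1))
}

#' Analytic moments of the latent-index assignment mechanism
#'
#' With total latent scale `s`, the overall treatment probability is
#' `p = Phi(c1 / s)`, and `cor(t, b_k0) = phi(c1 / s) (c2 sigma0^2 +
#' c3 rho sigma0 sigma1) / (s sigma0 sqrt(p (1 - p)))` (analogously for
#' `b_k1`), from the usual truncated-normal covariance identity.
#'
#' @param coeffs list with `c1`, `c2`, `c3`, `c4`.
#' @param sigma0,sigma1,rho cluster random-effect parameters.
#' @return Named numeric vector `c(p, r0, r1)`.
#' @export
analytic_treatment_moments <- function(coeffs, sigma0, sigma1, rho) {
  s <- latent_scale(coeffs, sigma0, sigma1, rho)
  p <- stats::pnorm(coeffs$c1 / s)
  dens <- stats::dnorm(coeffs$c1 / s)
  sdp <- sqrt(p * (1 - p))
  cov0 <- dens * (coeffs$c2 * sigma0^2 +
                    coeffs$c3 * rho * sigma0 * sigma1) / s
  cov1 <- dens * (coeffs$c3 * sigma1^2 +
                    coeffs$c2 * rho * sigma0 * sigma1) / s
  c(p = p,
    r0 = if (sigma0 > 0) cov0 / (sigma0 * sdp) else 0,
    r1 = if (sigma1 > 0) cov1 / (sigma1 * sdp) else 0)
}

#' Expected fraction of violating clusters
#'
#' The cluster-level latent `u = c1 + c2 b_k0 + c3 b_k1 + c4 zeta` is
#' normal with mean `c1` and variance `s^2 - 1`; given `u`, each unit is
#' treated independently with probability `pi = Phi(u)`, so a cluster of
#' size `n` violates with probability `pi^n + (1 - pi)^n`.  The expectation
#' over `u` (Gaussian quadrature via [stats::integrate()]) and over the
#' cluster-size law is returned; `method = "mc"` uses plain Monte Carlo
#' instead.
#'
#' @inheritParams analytic_treatment_moments
#' @param nk_range integer bounds of the discrete-uniform size law.
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param ndraw number of Monte Carlo draws for `method = "mc"`.
#' @param seed seed for `method = "mc"`.
#' @return Expected violating fraction in `[0, 1]`.
#' @export
expected_violation_fraction <- function(coeffs, sigma0, sigma1, rho,
                                        nk_range,
                                        method = c("quadrature", "mc"),
                                        ndraw = 1e5, seed = 1L) {
  method <- match.arg(method)
  s <- latent_scale(coeffs, sigma0, sigma1, rho)
  tau <- sqrt(max(s^2 - 1, 0))
  ns <- seq.int(nk_range[1], nk_range[2])
  viol_given_u <- function(u) {
    pi_k <- stats::pnorm(u)
    vapply(pi_k, function(pk) mean(pk^ns + (1 - pk)^ns), numeric(1))
  }
  if (method == "quadrature") {
    if (tau < 1e-12) return(viol_given_u(coeffs$c1))
    f <- function(z) viol_given_u(coeffs$c1 + tau * z) * stats::dnorm(z)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    u <- coeffs$c1 + tau * stats::rnorm(ndraw)
    n <- sample(ns, ndraw, replace = TRUE)
    pi_k <- stats::pnorm(u)
    mean(pi_k^n + (1 - pi_k)^n)
  }
}

#' Calibrate the assignment coefficients to the scenario targets
#'
#' Solves for `(c1, c2, c3, c4)` so that the analytic treatment moments
#' equal `(p, r0, r1)` and the expected violating fraction equals
#' `violation_frac`.  Given the targets, `c1 / s` is fixed by `p` and
#' `(c2, c3)` solve a 2x2 linear system in the random-effect covariance,
#' both proportional to the free latent scale `s`; `c4` absorbs the
#' remaining scale.  The violating fraction is monotone increasing in `s`,
#' so `s` is found by one-dimensional root finding.  Deterministic given
#' the configuration.
#'
#' @param config a [scenario_config()].
#' @param tol absolute tolerance on the violation-fraction target.
#' @return List of class `assignment_coefficients` with `c1`..`c4`, the
#'   implied scale `s`, and `achieved` (the four calibrated targets).
#' @export
calibrate_assignment <- function(config, tol = 1e-6) {
  sigma0 <- config$sigma0; sigma1 <- config$sigma1; rho <- config$rho
  z <- stats::qnorm(config$p)
  dens <- stats::dnorm(z)
  sdp <- sqrt(config$p * (1 - config$p))
  A <- config$r0 * sigma0 * sdp / dens
  B <- config$r1 * sigma1 * sdp / dens
  Sigma_b <- matrix(c(sigma0^2, rho * sigma0 * sigma1,
                      rho * sigma0 * sigma1, sigma1^2), 2, 2)
  ab <- c(A, B)
  sol <- solve(Sigma_b, ab)    # (c2, c3) / s
  q <- sum(ab * sol)
  if (q >= 1)
    stop("infeasible targets: implied latent correlation budget ",
         sprintf("%.3f", q), " >= 1 for (r0, r1, p) = (",
         config$r0, ", ", config$r1, ", ", config$p, ")")
  s_min <- sqrt(1 / (1 - q)) * (1 + 1e-10)
  coeffs_at <- function(s) {
    c2 <- s * sol[1]; c3 <- s * sol[2]
    c4sq <- s^2 * (1 - q) - 1
    list(c1 = z * s, c2 = c2, c3 = c3, c4 = sqrt(max(c4sq, 0)))
  }
  viol_at <- function(s) {
    expected_violation_fraction(coeffs_at(s), sigma0, sigma1, rho,
                                config$nk_range)
  }
  v_lo <- viol_at(s_min)
  if (config$violation_frac < v_lo - tol)
    stop("infeasible violation-fraction target ", config$violation_frac,
         ": the minimum attainable under these (r0, r1, p) targets is ",
         sprintf("%.4f", v_lo))
  if (config$violation_frac <= v_lo) {
    s_star <- s_min
  } else {
    s_hi <- s_min
    repeat {
      s_hi <- s_hi * 2
      if (viol_at(s_hi) >= config$violation_frac || s_hi > 1e4) break
    }
    if (viol_at(s_hi) < config$violation_frac)
      stop("infeasible violation-fraction target ", config$violation_frac,
           ": best attainable ", sprintf("%.4f", viol_at(s_hi)))
    s_star <- stats::uniroot(function(s) viol_at(s) - config$violation_frac,
                             c(s_min, s_hi), tol = tol)$root
  }
  coeffs <- coeffs_at(s_star)
  mom <- analytic_treatment_moments(coeffs, sigma0, sigma1, rho)
  structure(c(coeffs,
              list(s = latent_scale(coeffs, sigma0, sigma1, rho),
                   achieved = c(mom, violation_frac = viol_at(s_star)))),
            class = "assignment_coefficients")
}

#' Generate one clustered dataset from a calibrated scenario
#'
#' Draws cluster sizes, random effects, assignment latents and residuals;
#' assigns treatment by the latent-index sign; and records both potential
#' outcomes with the observed outcome `y = t Y(1) + (1 - t) Y(0)`.  Fully
#' reproducible from `seed`.
#'
#' @param config a [scenario_config()].
#' @param coeffs calibrated [calibrate_assignment()] coefficients.
#' @param seed integer seed.
#' @return A [clustered_dataset()] with attribute `truth`: list with
#'   per-cluster `b` (matrix of `(b_k1, b_k0)`), `pi_k`, `delta_k` and
#'   per-unit potential outcomes `y1`, `y0`.
#' @export
generate_dataset <- function(config, coeffs, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  K <- config$K
  nk <- sample(seq.int(config$nk_range[1], config$nk_range[2]), K,
               replace = TRUE)
  N <- sum(nk)
  # (b_k1, b_k0) ~ N(0, Omega)
  z1 <- stats::rnorm(K); z2 <- stats::rnorm(K)
  b1 <- config$sigma1 * z1
  b0 <- config$sigma0 * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
  zeta <- stats::rnorm(K)
  u <- coeffs$c1 + coeffs$c2 * b0 + coeffs$c3 * b1 + coeffs$c4 * zeta
  cl <- rep(seq_len(K), nk)
  xi <- stats::rnorm(N)
  t <- as.integer(u[cl] + xi > 0)
  y1 <- config$beta[2] + b1[cl] + config$sigma_eps * stats::rnorm(N)
  y0 <- config$beta[1] + b0[cl] + config$sigma_eps * stats::rnorm(N)
  y <- t * y1 + (1 - t) * y0
  d <- clustered_dataset(sprintf("c%04d", cl), t, y)
  attr(d, "truth") <- list(
    b = cbind(b_k1 = b1, b_k0 = b0),
    pi_k = stats::pnorm(u),
    delta_k = (config$beta[2] - config$beta[1]) + b1 - b0,
    y1 = y1, y0 = y0)
  d
}

#' @export
print.assignment_coefficients <- function(x, ...) {
  cat(sprintf("c1 = %.4f, c2 = %.4f, c3 = %.4f, c4 = %.4f (s = %.4f)\n",
              x$c1, x$c2, x$c3, x$c4, x$s))
  cat("achieved targets:\n")
  print(round(x$achieved, 4))
  invisible(x)
}
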