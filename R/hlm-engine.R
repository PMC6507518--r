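#' Variance components of the two-arm random coefficient model
#'
#' Holds `(sigma0^2, sigma1^2, rho, sigma_eps^2)`: the between-cluster
#' variances of the control-arm and treated-arm cluster means, their
#' correlation, and the residual variance.  The random-effect covariance is
#' `Omega = [[sigma1^2, rho*sigma1*sigma0], [rho*sigma1*sigma0, sigma0^2]]`
#' on `(b_k1, b_k0)`.
#'
#' @param sigma0_sq,sigma1_sq non-negative between-cluster variances.
#' @param rho correlation in (-1, 1).
#' @param sigma_eps_sq strictly positive residual variance.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(sigma0_sq, sigma1_sq, rho, sigma_eps_sq) {
  stopifnot(sigma0_sq >= 0, sigma1_sq >= 0, sigma_eps_sq > 0,
            rho > -1, rho < 1)
  structure(list(sigma0_sq = sigma0_sq, sigma1_sq = sigma1_sq,
                 rho = rho, sigma_eps_sq = sigma_eps_sq),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma0 = %.4f, sigma1 = %.4f, rho = %.4f, sigma_eps = %.4f\n",
              sqrt(x$sigma0_sq), sqrt(x$sigma1_sq), x$rho,
              sqrt(x$sigma_eps_sq)))
  invisible(x)
}

#' Fixed-effect design specification
#'
#' The random design is always `[t, 1 - t]` onto `(b_k1, b_k0)`.  The fixed
#' design is one of:
#' \describe{
#'   \item{two_arm}{`[t, 1 - t]` with coefficients `(beta1, beta0)`.}
#'   \item{satc}{`[t, 1 - t, Tbar_k * t, Tbar_k * (1 - t)]` with
#'     coefficients `(beta1, beta0, gamma1, gamma0)`; the cluster-average
#'     treatment `Tbar_k` enters each arm separately.}
#'   \item{rsatc}{`[t, 1 - t, Tbar_k]` with coefficients
#'     `(beta1, beta0, gamma)`; one shared cluster-average effect.}
#' }
#'
#' @param design one of `"two_arm"`, `"satc"`, `"rsatc"`.
#' @return An object of class `model_spec` with a `build(t, tbar)` closure
#'   returning the fixed-design matrix.
#' @export
model_spec <- function(design = c("two_arm", "satc", "rsatc")) {
  design <- match.arg(design)
  build <- switch(design,
    two_arm = function(t, tbar) {
      cbind(beta1 = t, beta0 = 1 - t)
    },
    satc = function(t, tbar) {
      cbind(beta1 = t, beta0 = 1 - t,
            gamma1 = tbar * t, gamma0 = tbar * (1 - t))
    },
    rsatc = function(t, tbar) {
      cbind(beta1 = t, beta0 = 1 - t, gamma = tbar)
    })
  structure(list(design = design, build = build), class = "model_spec")
}

# Internal: order rows by cluster (first-appearance order), build the fixed
# design and the 0-based cluster index vectors consumed by the C++ core.
prepare_hlm <- function(d, weights, spec) {
  d <- validate_clustered_dataset(d)
  stopifnot(inherits(weights, "weight_set"), inherits(spec, "model_spec"))
  if (length(weights$w) != nrow(d))
    stop("weight set does not match the dataset rows")
  ids <- unique(d$cluster_id)
  f <- factor(d$cluster_id, levels = ids)
  ord <- order(as.integer(f))
  t <- d$t[ord]
  y <- d$y[ord]
  w <- weights$w[ord]
  nk <- as.integer(tabulate(f, nbins = length(ids)))
  start <- cumsum(c(0L, nk[-length(nk)]))
  tbar_k <- as.numeric(rowsum(d$t, f, reorder = FALSE)) / nk
  tbar <- rep(tbar_k, nk)
  X <- spec$build(t, tbar)
  v <- weights$v
  if (!is.null(names(v))) {
    v <- v[ids]
    if (anyNA(v)) stop("cluster weights v_k missing for some clusters")
  } else if (length(v) != length(ids)) {
    stop("cluster weights v_k do not match the clusters")
  }
  ss <- .hlm_suffstats(y, t, w, X, start, nk)
  list(y = y, t = t, w = w, X = X, start = start, nk = nk,
       v = as.numeric(v), ids = ids, ord = ord, ss = ss)
}

.core <- function(prep, vc, profile_beta, beta = NULL,
                  want_blups = FALSE, want_scores = FALSE) {
  if (is.null(beta)) beta <- numeric(ncol(prep$X))
  .hlm_core(prep$ss, prep$v,
            vc$sigma1_sq, vc$sigma0_sq, vc$rho, vc$sigma_eps_sq,
            profile_beta, beta, want_blups, want_scores)
}

#' Weighted marginal log-likelihood
#'
#' Evaluates `sum_k v_k * (-1/2) [n_k log(2 pi) + log det V_k +
#' r_k' V_k^{-1} r_k]` with `V_k = Z_k Omega Z_k' + sigma_eps^2
#' diag(1 / w_ik)` and `r_k = y_k - X_k beta`.  Unit weights act as
#' residual precisions; cluster weights multiply each cluster's
#' contribution.
#'
#' @param d a [clustered_dataset()].
#' @param weights a `weight_set`.
#' @param spec a [model_spec()].
#' @param beta fixed-effect vector matching the design columns.
#' @param vc a [variance_components()].
#' @return Scalar log-likelihood.
#' @export
weighted_loglik <- function(d, weights, spec, beta, vc) {
  prep <- prepare_hlm(d, weights, spec)
  stopifnot(length(beta) == ncol(prep$X))
  .core(prep, vc, profile_beta = FALSE, beta = as.numeric(beta))$loglik
}

#' Generalized least squares fixed effects at fixed variance components
#'
#' `beta_hat = (sum_k v_k X_k' V_k^{-1} X_k)^{-1} sum_k v_k X_k' V_k^{-1}
#' y_k`, with model-based covariance `(sum_k v_k X_k' V_k^{-1} X_k)^{-1}`.
#'
#' @inheritParams weighted_loglik
#' @param vc a [variance_components()], held fixed.
#' @return List with `beta` (named), `cov` (model-based covariance) and
#'   `loglik` at the solution.
#' @export
gls_fixed_effects <- function(d, weights, spec, vc) {
  prep <- prepare_hlm(d, weights, spec)
  res <- .core(prep, vc, profile_beta = TRUE)
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(prep$X)
  cov <- solve(res$A)
  dimnames(cov) <- list(colnames(prep$X), colnames(prep$X))
  list(beta = beta, cov = cov, loglik = res$loglik)
}

# Internal: moment-based deterministic starting values.
start_vc <- function(d) {
  s <- cluster_summaries(d)
  f <- factor(d$cluster_id, levels = s$cluster_id)
  key <- interaction(f, d$t, drop = FALSE)
  m <- tapply(d$y, key, mean)
  counts <- tapply(d$y, key, length)
  resid <- d$y - m[key]
  df <- sum(!is.na(counts) & counts > 1)
  sesq <- if (sum(counts[!is.na(counts)] - 1) > 0) {
    sum(resid^2, na.rm = TRUE) / max(1, sum(counts - 1, na.rm = TRUE))
  } else {
    stats::var(d$y)
  }
  vy <- stats::var(d$y)
  floor_b <- max(1e-4, 0.01 * vy)
  m1 <- m[paste0(s$cluster_id, ".1")]
  m0 <- m[paste0(s$cluster_id, ".0")]
  v1 <- max(stats::var(m1, na.rm = TRUE) - sesq / max(1, mean(s$n_k1[s$n_k1 > 0])),
            floor_b, na.rm = TRUE)
  v0 <- max(stats::var(m0, na.rm = TRUE) -
              sesq / max(1, mean((s$n_k - s$n_k1)[s$n_k1 < s$n_k])),
            floor_b, na.rm = TRUE)
  variance_components(sigma0_sq = v0, sigma1_sq = v1, rho = 0,
                      sigma_eps_sq = max(sesq, floor_b))
}

vc_to_par <- function(vc) {
  c(log(sqrt(max(vc$sigma0_sq, 1e-12))),
    log(sqrt(max(vc$sigma1_sq, 1e-12))),
    atanh(min(max(vc$rho, -0.99), 0.99)),
    log(sqrt(vc$sigma_eps_sq)))
}

par_to_vc <- function(par) {
  variance_components(sigma0_sq = exp(2 * par[1]),
                      sigma1_sq = exp(2 * par[2]),
                      rho = tanh(par[3]),
                      sigma_eps_sq = exp(2 * par[4]))
}

#' Fit a weighted two-arm random coefficient model by maximum likelihood
#'
#' Maximizes the weighted marginal log-likelihood over the variance
#' components with the fixed effects profiled out by GLS at each step.
#' The variance parameters are optimized on the unconstrained scale
#' `(log sigma0, log sigma1, atanh rho, log sigma_eps)`; boundary fits
#' (a variance shrinking to zero or `|rho|` near 1) are reported as
#' converged with `boundary = TRUE`.
#'
#' @inheritParams weighted_loglik
#' @param options list: `start` (a [variance_components()] to start from;
#'   default is a deterministic moment fit), `reml` (logical, default
#'   `FALSE`: plain maximum likelihood), `max_iter` (default 500),
#'   `rel_tol` (default 1e-10).
#' @return An object of class `hlm_fit`: list with `beta` (named fixed
#'   effects), `vc`, `blups` (one `(b_k1, b_k0)` row per cluster),
#'   `loglik`, `cov_beta` (model-based), `converged`, `boundary`,
#'   `n_iter`, `design`.
#' @export
fit_weighted_hlm <- function(d, weights, spec, options = list()) {
  opts <- utils::modifyList(
    list(start = NULL, reml = FALSE, max_iter = 500L, rel_tol = 1e-10),
    options)
  prep <- prepare_hlm(d, weights, spec)
  zero <- which(colSums(abs(prep$X)) == 0)
  if (length(zero))
    stop("fixed-effect column '", colnames(prep$X)[zero[1L]],
         "' has no support in the data")
  start <- if (is.null(opts$start)) start_vc(d) else opts$start
  reml <- isTRUE(opts$reml)
  negll <- function(par) {
    vc <- par_to_vc(par)
    res <- tryCatch(.core(prep, vc, profile_beta = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik)) return(1e10)
    ll <- res$loglik
    if (reml && is.finite(res$logdet_vinfo)) ll <- ll - 0.5 * res$logdet_vinfo
    -ll
  }
  opt <- stats::nlminb(vc_to_par(start), negll,
                       control = list(iter.max = opts$max_iter,
                                      eval.max = 4L * opts$max_iter,
                                      rel.tol = opts$rel_tol))
  vc <- par_to_vc(opt$par)
  res <- .core(prep, vc, profile_beta = TRUE, want_blups = TRUE)
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(prep$X)
  blups <- res$blups
  dimnames(blups) <- list(prep$ids, c("b_k1", "b_k0"))
  sd_y <- stats::sd(prep$y)
  boundary <- sqrt(vc$sigma0_sq) < 1e-3 * sd_y ||
    sqrt(vc$sigma1_sq) < 1e-3 * sd_y || abs(vc$rho) > 0.999
  cov <- solve(res$A)
  dimnames(cov) <- list(colnames(prep$X), colnames(prep$X))
  structure(list(beta = beta, vc = vc, blups = blups,
                 loglik = res$loglik, cov_beta = cov,
                 converged = opt$convergence == 0L,
                 boundary = boundary, n_iter = opt$iterations,
                 design = spec$design, weights = weights,
                 cluster_ids = prep$ids),
            class = "hlm_fit")
}

#' @export
print.hlm_fit <- function(x, ...) {
  cat(sprintf("Weighted random-coefficient fit (%s design), logLik = %.3f%s\n",
              x$design, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$beta, 4))
  print(x$vc)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit an `hlm_fit`.
#' @return A JSON string with estimates, variance components and
#'   convergence information.
#' @export
hlm_fit_json <- function(fit) {
  jsonlite::toJSON(list(
    design = fit$design,
    beta = as.list(fit$beta),
    vc = unclass(fit$vc),
    loglik = fit$loglik,
    converged = fit$converged,
    boundary = fit$boundary,
    n_iter = fit$n_iter), auto_unbox = TRUE, digits = NA)
}
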