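covariance_estimate <- function(cov, method, B = NA_integer_) {
  dimnames(cov) <- list(c("beta0", "beta1"), c("beta0", "beta1"))
  se_delta_sq <- cov["beta0", "beta0"] + cov["beta1", "beta1"] -
    2 * cov["beta0", "beta1"]
  structure(list(cov = cov,
                 se_beta0 = sqrt(max(cov["beta0", "beta0"], 0)),
                 se_beta1 = sqrt(max(cov["beta1", "beta1"], 0)),
                 se_delta = sqrt(max(se_delta_sq, 0)),
                 method = method, B = B),
            class = "covariance_estimate")
}

#' Robust cluster sandwich covariance for the weighted fixed effects
#'
#' `bread^{-1} meat bread^{-1}` with `bread = sum_k X_k' W_k X_k`,
#' `W_k = V_k^{-1}` evaluated at the fitted variance components and unit
#' weights, and the cluster-blocked `meat = sum_k X_k' W_k r_k r_k' W_k
#' X_k` with residuals `r_k = y_k - X_k beta_hat`.
#'
#' @param d the [clustered_dataset()] the fit used.
#' @param weights the `weight_set` the fit used.
#' @param fit an `hlm_fit` with the `two_arm` design.
#' @return A `covariance_estimate` (method `"sandwich"`) for
#'   `(beta0_hat, beta1_hat)`, with `se_delta` from the quadratic form.
#' @export
robust_sandwich <- function(d, weights, fit) {
  stopifnot(inherits(fit, "hlm_fit"))
  if (fit$design != "two_arm")
    stop("the sandwich covariance is defined for the two_arm design")
  prep <- prepare_hlm(d, weights, model_spec("two_arm"))
  res <- .core(prep, fit$vc, profile_beta = FALSE,
               beta = as.numeric(fit$beta[colnames(prep$X)]),
               want_scores = TRUE)
  bread_inv <- solve(res$bread)
  meat <- crossprod(res$scores)
  cov <- bread_inv %*% meat %*% bread_inv
  # design order is (beta1, beta0); report as (beta0, beta1)
  dimnames(cov) <- list(colnames(prep$X), colnames(prep$X))
  cov <- cov[c("beta0", "beta1"), c("beta0", "beta1")]
  covariance_estimate(cov, "sandwich")
}

#' Cluster bootstrap covariance
#'
#' Resamples the clusters with replacement (resampled clusters get fresh
#' unique labels), reruns the full estimation pipeline on each resample,
#' and returns the element-wise sample covariance of the bootstrap
#' `(beta0_hat, beta1_hat)` pairs.  A resample without treatment variation
#' anywhere (or on which the estimator fails) is redrawn; more than 50
#' consecutive redraws is an error.
#'
#' @param d a [clustered_dataset()].
#' @param estimator a function mapping a [clustered_dataset()] to an
#'   object with elements `beta0_hat` and `beta1_hat` (e.g. a wrapper
#'   around [aiptw()]); it is responsible for refitting every stage of
#'   its pipeline on the resample.
#' @param B number of bootstrap replicates (default 30).
#' @param seed integer seed making the resampling fully reproducible.
#' @return A `covariance_estimate` (method `"cluster_bootstrap"`).
#' @export
cluster_bootstrap <- function(d, estimator, B = 30L, seed = 1L) {
  d <- validate_clustered_dataset(d)
  stopifnot(B >= 2L)
  ids <- unique(d$cluster_id)
  K <- length(ids)
  rows_of <- split(seq_len(nrow(d)), factor(d$cluster_id, levels = ids))
  est <- matrix(NA_real_, B, 2L)
  redraws <- 0L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  b <- 1L
  consec <- 0L
  while (b <= B) {
    pick <- sample.int(K, K, replace = TRUE)
    rows <- unlist(rows_of[pick], use.names = FALSE)
    reps <- rep(seq_len(K), lengths(rows_of)[pick])
    bs <- d[rows, , drop = FALSE]
    bs$cluster_id <- sprintf("bs%04d", reps)
    rownames(bs) <- NULL
    class(bs) <- c("clustered_dataset", "data.frame")
    n1 <- sum(bs$t)
    value <- NULL
    if (n1 > 0L && n1 < nrow(bs)) {
      value <- tryCatch(estimator(bs), error = function(e) NULL)
    }
    if (is.null(value)) {
      consec <- consec + 1L
      redraws <- redraws + 1L
      if (consec > 50L)
        stop("more than 50 consecutive degenerate bootstrap resamples")
      next
    }
    est[b, ] <- c(value$beta0_hat, value$beta1_hat)
    b <- b + 1L
    consec <- 0L
  }
  out <- covariance_estimate(stats::cov(est), "cluster_bootstrap", B = B)
  out$redraws <- redraws
  out$estimates <- est
  out
}

#' Normal-quantile confidence interval
#'
#' `estimate +/- z_{(1 + level)/2} * se`; at the default 95% level the
#' multiplier is 1.96 (no small-sample correction).
#'
#' @param estimate point estimate.
#' @param se standard error, non-negative.
#' @param level confidence level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(estimate, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("%s covariance%s: se(beta0) = %.4f, se(beta1) = %.4f, se(delta) = %.4f\n",
              x$method, if (is.na(x$B)) "" else sprintf(" (B = %d)", x$B),
              x$se_beta0, x$se_beta1, x$se_delta))
  invisible(x)
}
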