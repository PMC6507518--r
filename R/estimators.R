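#' Drop clusters without treatment variation
#'
#' Retains exactly the mixed clusters; downstream propensities, counts and
#' the normalization constant are recomputed on the trimmed sample.  Note
#' that trimming changes the target population to the clusters with
#' observed treatment variation.
#'
#' @param d a [clustered_dataset()].
#' @return A [clustered_dataset()] containing only mixed clusters.
#' @export
trim_clusters <- function(d) {
  d <- validate_clustered_dataset(d)
  s <- cluster_summaries(d)
  keep <- s$cluster_id[s$status == "mixed"]
  if (!length(keep))
    stop("no cluster has treatment variation; the trimmed sample is empty")
  out <- d[d$cluster_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clustered_dataset", "data.frame")
  out
}

# Internal: weighted two-arm fit + extraction shared by all IPTW/AIPTW
# parametric estimators.
weighted_two_arm_estimate <- function(d, estimand, options, method,
                                      n_violating) {
  s <- cluster_summaries(d)
  prop <- estimate_propensity(s)
  wts <- compute_unit_weights(d, prop, estimand)
  fit <- fit_weighted_hlm(d, wts, model_spec("two_arm"), options)
  structure(list(beta0_hat = unname(fit$beta["beta0"]),
                 beta1_hat = unname(fit$beta["beta1"]),
                 delta_hat = unname(fit$beta["beta1"] - fit$beta["beta0"]),
                 vc_hat = fit$vc, method = method,
                 n_clusters_used = nrow(s), n_violating = n_violating,
                 fit = fit, weights = wts, data = d),
            class = "causal_estimate")
}

#' IPTW estimator on the original sample
#'
#' Weighted maximum-likelihood fit of the two-arm random coefficient model
#' with inverse-probability-of-treatment weights computed from the
#' within-cluster propensities, using the full sample including violating
#' clusters (whose units carry the degenerate-propensity weights).
#'
#' @param d a [clustered_dataset()].
#' @param estimand `"student_population"` (default) or
#'   `"school_population"`; see [cluster_weights()].
#' @param options passed to [fit_weighted_hlm()].
#' @return An object of class `causal_estimate` with `beta0_hat`,
#'   `beta1_hat`, `delta_hat = beta1_hat - beta0_hat`, `vc_hat`, the
#'   method tag and cluster counts; the underlying `hlm_fit` is attached.
#' @export
iptw_orig <- function(d, estimand = "student_population", options = list()) {
  d <- validate_clustered_dataset(d)
  s <- cluster_summaries(d)
  weighted_two_arm_estimate(d, estimand, options, "iptw_orig",
                            sum(s$status != "mixed"))
}

#' IPTW estimator on the trimmed sample
#'
#' [trim_clusters()] followed by [iptw_orig()] on the surviving clusters;
#' propensities, `N1`, `N` and `c` are all recomputed on the trimmed
#' sample.
#'
#' @inheritParams iptw_orig
#' @return A `causal_estimate` with method tag `iptw_trim`.
#' @export
iptw_trim <- function(d, estimand = "student_population", options = list()) {
  d <- validate_clustered_dataset(d)
  s <- cluster_summaries(d)
  est <- weighted_two_arm_estimate(trim_clusters(d), estimand, options,
                                   "iptw_trim", sum(s$status != "mixed"))
  est$n_violating <- sum(s$status != "mixed")
  est
}

#' Build the augmented dataset
#'
#' Fits the chosen correction model (SATC or RSATC) on the original,
#' unweighted data and appends to every violating cluster exactly one
#' pseudo-unit carrying the predicted missing-arm potential outcome: a
#' treated pseudo-unit with `y = E_hat[Y(1) | k]` for an all-control
#' cluster, a control pseudo-unit with `y = E_hat[Y(0) | k]` for an
#' all-treated cluster.  Mixed clusters are unchanged; when no cluster
#' violates, the input is returned as is.
#'
#' @param d a [clustered_dataset()] of observed units.
#' @param model `"satc"` or `"rsatc"`.
#' @param options passed to the correction-model fit.
#' @return A [clustered_dataset()] with `n_k + 1` rows for each violating
#'   cluster (`is_pseudo = TRUE` on the added row) and `n_k` rows
#'   otherwise; the correction fit is attached as attribute
#'   `correction_fit`.
#' @export
build_augmented_data <- function(d, model = c("satc", "rsatc"),
                                 options = list()) {
  d <- validate_clustered_dataset(d)
  model <- match.arg(model)
  s <- cluster_summaries(d)
  viol <- s[s$status != "mixed", , drop = FALSE]
  if (nrow(viol) == 0L) return(d)
  fit <- if (model == "satc") fit_satc(d, options) else fit_rsatc(d, options)
  pseudo <- data.frame(
    cluster_id = viol$cluster_id,
    t = ifelse(viol$status == "all_control", 1L, 0L),
    y = vapply(viol$status, function(st) predict_missing_arm(fit, st),
               numeric(1)),
    is_pseudo = TRUE,
    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(d)[, c("cluster_id", "t", "y", "is_pseudo")],
               pseudo)
  rownames(out) <- NULL
  class(out) <- c("clustered_dataset", "data.frame")
  attr(out, "correction_fit") <- fit
  out
}

#' Augmented IPTW estimator
#'
#' Builds the augmented dataset, recomputes the propensities and the
#' normalization constant treating the pseudo-units as observed, and runs
#' the weighted two-arm fit on the augmented sample.  Cluster weights
#' `v_k` are computed from the observed cluster sizes (the augmentation
#' affects only the propensities and unit weights).  When no cluster
#' violates positivity the estimator reduces exactly to [iptw_orig()].
#'
#' @inheritParams iptw_orig
#' @param model correction model used for the missing-arm predictions:
#'   `"satc"` or `"rsatc"`.
#' @return A `causal_estimate` with method tag `aiptw_satc` or
#'   `aiptw_rsatc`.
#' @export
aiptw <- function(d, model = c("satc", "rsatc"),
                  estimand = "student_population", options = list()) {
  d <- validate_clustered_dataset(d)
  model <- match.arg(model)
  s <- cluster_summaries(d)
  n_viol <- sum(s$status != "mixed")
  aug <- build_augmented_data(d, model, options)
  est <- weighted_two_arm_estimate_aug(aug, d, estimand, options,
                                       paste0("aiptw_", model), n_viol)
  est
}

# Internal: like weighted_two_arm_estimate but v_k from observed sizes.
weighted_two_arm_estimate_aug <- function(aug, d_obs, estimand, options,
                                          method, n_violating) {
  s_aug <- cluster_summaries(aug)
  prop <- estimate_propensity(s_aug)
  wts <- compute_unit_weights(aug, prop, estimand)
  s_obs <- cluster_summaries(d_obs)
  v <- cluster_weights(s_obs, estimand)
  wts$v <- v
  fit <- fit_weighted_hlm(aug, wts, model_spec("two_arm"), options)
  structure(list(beta0_hat = unname(fit$beta["beta0"]),
                 beta1_hat = unname(fit$beta["beta1"]),
                 delta_hat = unname(fit$beta["beta1"] - fit$beta["beta0"]),
                 vc_hat = fit$vc, method = method,
                 n_clusters_used = nrow(s_aug), n_violating = n_violating,
                 fit = fit, weights = wts, data = aug),
            class = "causal_estimate")
}

#' Nonparametric augmented contrast from supplied predictions
#'
#' The cluster-average contrast `delta_hat = (1/K) sum_k v_k d_k` where
#' `d_k` is the within-cluster difference of treated and control means for
#' a mixed cluster, the treated mean minus the predicted control-arm
#' outcome for an all-treated cluster, and the predicted treated-arm
#' outcome minus the control mean for an all-control cluster.
#'
#' @param d a [clustered_dataset()].
#' @param predictions named numeric vector of predicted missing-arm
#'   outcomes for (at least) every violating cluster, named by cluster id.
#' @param v named per-cluster weights `v_k` (defaults to 1).
#' @return Scalar `delta_hat`.
#' @export
nonparametric_delta <- function(d, predictions, v = NULL) {
  d <- validate_clustered_dataset(d)
  s <- cluster_summaries(d)
  if (is.null(v)) v <- stats::setNames(rep(1, nrow(s)), s$cluster_id)
  f <- factor(d$cluster_id, levels = s$cluster_id)
  sum_y1 <- rowsum(d$y * d$t, f, reorder = FALSE)
  sum_y0 <- rowsum(d$y * (1 - d$t), f, reorder = FALSE)
  m1 <- ifelse(s$n_k1 > 0, sum_y1 / pmax(s$n_k1, 1L), NA_real_)
  m0 <- ifelse(s$n_k1 < s$n_k, sum_y0 / pmax(s$n_k - s$n_k1, 1L), NA_real_)
  dk <- numeric(nrow(s))
  for (k in seq_len(nrow(s))) {
    dk[k] <- switch(s$status[k],
      mixed = m1[k] - m0[k],
      all_treated = m1[k] - predictions[[s$cluster_id[k]]],
      all_control = predictions[[s$cluster_id[k]]] - m0[k])
  }
  sum(v[s$cluster_id] * dk) / nrow(s)
}

#' Nonparametric AIPTW estimator
#'
#' Fits the chosen correction model to obtain the missing-arm predictions
#' and evaluates [nonparametric_delta()].  Carries only the treatment
#' effect (no arm-specific intercepts or variance components).
#'
#' @inheritParams aiptw
#' @return A `causal_estimate` with `delta_hat` only (method tag
#'   `aiptw_nonparametric`).
#' @export
aiptw_nonparametric <- function(d, model = c("satc", "rsatc"),
                                estimand = "student_population",
                                options = list()) {
  d <- validate_clustered_dataset(d)
  model <- match.arg(model)
  s <- cluster_summaries(d)
  viol <- s[s$status != "mixed", , drop = FALSE]
  preds <- stats::setNames(numeric(0), character(0))
  if (nrow(viol) > 0L) {
    fit <- if (model == "satc") fit_satc(d, options) else fit_rsatc(d, options)
    preds <- stats::setNames(
      vapply(viol$status, function(st) predict_missing_arm(fit, st),
             numeric(1)),
      viol$cluster_id)
  }
  v <- cluster_weights(s, estimand)
  structure(list(beta0_hat = NA_real_, beta1_hat = NA_real_,
                 delta_hat = nonparametric_delta(d, preds, v),
                 vc_hat = NULL, method = "aiptw_nonparametric",
                 n_clusters_used = nrow(s),
                 n_violating = nrow(viol)),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d clusters, %d violating)\n",
              x$method, x$n_clusters_used, x$n_violating))
  if (is.finite(x$beta0_hat))
    cat(sprintf("  beta0 = %.4f, beta1 = %.4f, delta = %.4f\n",
                x$beta0_hat, x$beta1_hat, x$delta_hat))
  else
    cat(sprintf("  delta = %.4f\n", x$delta_hat))
  if (!is.null(x$vc_hat)) print(x$vc_hat)
  invisible(x)
}
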