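#' Cluster-average treatment and its grand mean
#'
#' `Tbar_k = sum_i t_ik / n_k` per cluster, and the unweighted grand mean
#' `Tbarbar = sum_k Tbar_k / K` (each cluster counted once).  `Tbar_k` is 0
#' or 1 exactly when the cluster violates practical positivity.
#'
#' @param d a [clustered_dataset()].
#' @return An object of class `cluster_means`: data frame with columns
#'   `cluster_id`, `tbar`; attribute `grand_mean`.
#' @export
cluster_treatment_means <- function(d) {
  s <- cluster_summaries(d)
  m <- data.frame(cluster_id = s$cluster_id, tbar = s$n_k1 / s$n_k,
                  stringsAsFactors = FALSE)
  attr(m, "grand_mean") <- mean(m$tbar)
  class(m) <- c("cluster_means", "data.frame")
  m
}

# Internal shared fitter for the correction models: unweighted ML via the
# HLM engine with the chosen design.
fit_correction <- function(d, design, options = list()) {
  d <- validate_clustered_dataset(d)
  m <- cluster_treatment_means(d)
  if (length(unique(m$tbar)) < 2L)
    stop("all clusters have the same average treatment; the cluster-mean ",
         "effect is not identified (collinear design)")
  fit <- fit_weighted_hlm(d, uniform_weights(d), model_spec(design), options)
  fit$cluster_means <- m
  class(fit) <- c(paste0(design, "_fit"), class(fit))
  fit
}

#' Fit the cluster-average-treatment corrected (SATC) model
#'
#' Unweighted maximum likelihood fit of
#' `y = (beta1 + b_k1 + gamma1 * Tbar_k) t + (beta0 + b_k0 + gamma0 *
#' Tbar_k)(1 - t) + e`.  Including the cluster-average treatment as an
#' arm-specific covariate breaks the dependence between the random effects
#' and the treatment (a Mundlak-type correction), so the fixed effects are
#' estimated consistently even when treatment is confounded with the
#' cluster effects.
#'
#' @param d a [clustered_dataset()].
#' @param options passed to [fit_weighted_hlm()].
#' @return An `satc_fit` (an [fit_weighted_hlm()] result with the `satc`
#'   design and the cluster means attached).
#' @export
fit_satc <- function(d, options = list()) {
  fit_correction(d, "satc", options)
}

#' Fit the reduced SATC (RSATC) model
#'
#' As [fit_satc()] but with a single shared cluster-average effect:
#' `y = (beta1 + b_k1) t + (beta0 + b_k0)(1 - t) + gamma * Tbar_k + e`.
#' One parameter fewer than SATC; correct and more efficient when the two
#' arms' random effects covary equally with treatment.  The implied
#' treatment effect `beta1 - beta0` is unchanged by the reparameterization.
#'
#' @inheritParams fit_satc
#' @return An `rsatc_fit`.
#' @export
fit_rsatc <- function(d, options = list()) {
  fit_correction(d, "rsatc", options)
}

#' Predicted missing-arm potential outcome for a violating cluster
#'
#' For a cluster observed in only one arm, predicts the expected outcome of
#' the missing arm from the fixed part of a fitted correction model; the
#' missing arm's random effect is set to its marginal expectation, zero
#' (the shrinkage limit for a cluster with no relevant observations).
#' Under SATC: an all-control cluster (`Tbar = 0`) gets `beta1_hat`; an
#' all-treated cluster (`Tbar = 1`) gets `beta0_hat + gamma0_hat`.  Under
#' RSATC: `beta1_hat` and `beta0_hat + gamma_hat` respectively.
#'
#' @param fit an `satc_fit` or `rsatc_fit`.
#' @param status `"all_control"` (predict the treated arm) or
#'   `"all_treated"` (predict the control arm); a mixed cluster is an
#'   error.
#' @return Scalar predicted potential outcome.
#' @export
predict_missing_arm <- function(fit, status) {
  if (identical(status, "mixed"))
    stop("predict_missing_arm is only defined for violating clusters")
  stopifnot(status %in% c("all_control", "all_treated"))
  b <- fit$beta
  if (inherits(fit, "satc_fit")) {
    if (status == "all_control") unname(b["beta1"])
    else unname(b["beta0"] + b["gamma0"])
  } else if (inherits(fit, "rsatc_fit")) {
    if (status == "all_control") unname(b["beta1"])
    else unname(b["beta0"] + b["gamma"])
  } else {
    stop("fit must come from fit_satc() or fit_rsatc()")
  }
}
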