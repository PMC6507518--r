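#' Within-cluster propensity estimation
#'
#' Under cluster-level ignorability the propensity in cluster `k` is
#' estimated by the empirical treated proportion `pi_hat = n_k1 / n_k`.
#' The global normalization constant is `c = N1 / N`, the overall treated
#' proportion of the dataset being analysed.
#'
#' @param s a `cluster_summary` from [cluster_summaries()].
#' @return An object of class `propensity_table`: a data frame with
#'   columns `cluster_id`, `pi_hat`, `violating`, plus attributes `c`,
#'   `N1`, `N`.
#' @export
estimate_propensity <- function(s) {
  stopifnot(inherits(s, "cluster_summary"), nrow(s) >= 1L)
  N1 <- sum(s$n_k1)
  N <- sum(s$n_k)
  if (N1 == 0L || N1 == N)
    stop("no treatment variation anywhere (N1 = ", N1, ", N = ", N,
         "); no weighted estimator is identified")
  p <- data.frame(cluster_id = s$cluster_id,
                  pi_hat = s$n_k1 / s$n_k,
                  violating = s$status != "mixed",
                  stringsAsFactors = FALSE)
  attr(p, "c") <- N1 / N
  attr(p, "N1") <- N1
  attr(p, "N") <- N
  class(p) <- c("propensity_table", "data.frame")
  p
}

#' Unit-level inverse-probability-of-treatment weights
#'
#' Computes `w_ik = t * c / pi_hat_k + (1 - t) * (1 - c) / (1 - pi_hat_k)`
#' for every unit.  In a violating cluster the formula is evaluated at the
#' degenerate propensity for the arm actually observed, so all-control
#' units receive `1 - c` and all-treated units receive `c`.  Within any
#' mixed cluster the weights sum to `n_k` for every `c` in (0, 1).
#'
#' @param d a [clustered_dataset()].
#' @param prop a `propensity_table` for the clusters of `d`.
#' @param estimand `"student_population"` (cluster weights `v_k = 1`,
#'   the default) or `"school_population"` (`v_k = N / (n_k K)`).
#' @return An object of class `weight_set`: list with `w` (per-unit, in
#'   row order of `d`), `v` (named per-cluster weights), `c`, `estimand`.
#' @export
compute_unit_weights <- function(d, prop,
                                 estimand = c("student_population",
                                              "school_population")) {
  d <- validate_clustered_dataset(d)
  estimand <- match.arg(estimand)
  cc <- attr(prop, "c")
  pi_k <- prop$pi_hat[match(d$cluster_id, prop$cluster_id)]
  if (anyNA(pi_k)) stop("propensity table lacks some clusters of the data")
  w <- ifelse(d$t == 1L, cc / pi_k, (1 - cc) / (1 - pi_k))
  s <- cluster_summaries(d)
  v <- cluster_weights(s, estimand)
  structure(list(w = w, v = v, c = cc, estimand = estimand),
            class = "weight_set")
}

#' Cluster-level estimand weights
#'
#' The causal estimand is a weighted average of cluster effects with
#' weights `omega_k`; in estimation each cluster enters with
#' `v_k = omega_k * N / (n_k * K)`.  Generalizing to a population of
#' students gives `omega_k = n_k K / N`, i.e. `v_k = 1`; generalizing to a
#' population of schools gives `omega_k = 1`, i.e. `v_k = N / (n_k K)`.
#'
#' @param s a `cluster_summary`.
#' @param estimand `"student_population"` or `"school_population"`.
#' @return Named numeric vector of `v_k`, one per cluster.
#' @export
cluster_weights <- function(s, estimand = c("student_population",
                                            "school_population")) {
  stopifnot(inherits(s, "cluster_summary"), nrow(s) >= 1L)
  estimand <- match.arg(estimand)
  v <- if (estimand == "student_population") {
    rep(1, nrow(s))
  } else {
    sum(s$n_k) / (s$n_k * nrow(s))
  }
  names(v) <- s$cluster_id
  v
}

#' Uniform (unweighted) weight set
#'
#' All unit weights and cluster weights equal to 1; used for the ordinary
#' maximum-likelihood fits of the correction models.
#'
#' @param d a [clustered_dataset()].
#' @return A `weight_set` with `w = 1`, `v = 1` and `c = NA`.
#' @export
uniform_weights <- function(d) {
  d <- validate_clustered_dataset(d)
  s <- cluster_summaries(d)
  v <- rep(1, nrow(s))
  names(v) <- s$cluster_id
  structure(list(w = rep(1, nrow(d)), v = v, c = NA_real_,
                 estimand = "student_population"),
            class = "weight_set")
}

#' @export
print.propensity_table <- function(x, ...) {
  cat(sprintf(
    "Propensity table: %d clusters, %d violating; c = N1/N = %d/%d = %.4f\n",
    nrow(x), sum(x$violating), attr(x, "N1"), attr(x, "N"), attr(x, "c")))
  invisible(x)
}
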