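#' Monte Carlo performance metrics for one estimator and parameter
#'
#' Percentage bias (on the fraction scale) `pb = mean(est - truth) /
#' truth`, the mean estimated standard error `t_se`, the empirical
#' standard deviation of the estimates `s_se` (denominator R - 1), and
#' the fraction of normal 95% confidence intervals covering the truth.
#'
#' @param estimates numeric vector of replicate estimates (length >= 2).
#' @param ses numeric vector of estimated SEs (same length), or `NULL`
#'   when no SE was computed (then `t_se` and `cp95` are `NA`).
#' @param truth true parameter value; must be nonzero for `pb`.
#' @return Named numeric vector `c(pb, t_se, s_se, cp95)`.
#' @export
compute_metrics <- function(estimates, ses, truth) {
  ok <- is.finite(estimates)
  estimates <- estimates[ok]
  stopifnot(length(estimates) >= 2)
  if (truth == 0) stop("percentage bias is undefined for truth = 0")
  if (!is.null(ses)) ses <- ses[ok]
  pb <- mean(estimates - truth) / truth
  s_se <- stats::sd(estimates)
  t_se <- if (is.null(ses)) NA_real_ else mean(ses, na.rm = TRUE)
  cp95 <- if (is.null(ses)) NA_real_ else {
    z <- stats::qnorm(0.975)
    mean(abs(estimates - truth) <= z * ses, na.rm = TRUE)
  }
  c(pb = pb, t_se = t_se, s_se = s_se, cp95 = cp95)
}

.mc_methods <- c("iptw_orig", "iptw_trim", "aiptw_satc", "aiptw_rsatc",
                 "aiptw_np")

# Internal: one method applied to one dataset, returning estimates and
# (optionally) standard errors.
run_one_method <- function(d, method, se_kind, B, boot_seed, estimand) {
  est <- switch(method,
    iptw_orig = iptw_orig(d, estimand),
    iptw_trim = iptw_trim(d, estimand),
    aiptw_satc = aiptw(d, "satc", estimand),
    aiptw_rsatc = aiptw(d, "rsatc", estimand),
    aiptw_np = aiptw_nonparametric(d, "satc", estimand),
    stop("unknown method: ", method))
  out <- list(beta0 = est$beta0_hat, beta1 = est$beta1_hat,
              delta = est$delta_hat,
              sigma0 = if (is.null(est$vc_hat)) NA_real_ else
                sqrt(est$vc_hat$sigma0_sq),
              sigma1 = if (is.null(est$vc_hat)) NA_real_ else
                sqrt(est$vc_hat$sigma1_sq),
              rho = if (is.null(est$vc_hat)) NA_real_ else est$vc_hat$rho,
              se_beta0 = NA_real_, se_beta1 = NA_real_,
              se_delta = NA_real_)
  if (identical(se_kind, "sandwich")) {
    cv <- robust_sandwich(est$data, est$weights, est$fit)
    out[c("se_beta0", "se_beta1", "se_delta")] <-
      list(cv$se_beta0, cv$se_beta1, cv$se_delta)
  } else if (identical(se_kind, "bootstrap")) {
    # warm-start each resample fit from the full-data variance components
    bo <- list(start = est$vc_hat, rel_tol = 1e-8)
    refit <- switch(method,
      iptw_orig = function(b) iptw_orig(b, estimand, options = bo),
      iptw_trim = function(b) iptw_trim(b, estimand, options = bo),
      aiptw_satc = function(b) aiptw(b, "satc", estimand, options = bo),
      aiptw_rsatc = function(b) aiptw(b, "rsatc", estimand, options = bo))
    cv <- cluster_bootstrap(d, refit, B = B, seed = boot_seed)
    out[c("se_beta0", "se_beta1", "se_delta")] <-
      list(cv$se_beta0, cv$se_beta1, cv$se_delta)
  }
  out
}

#' Run a Monte Carlo replication study
#'
#' Calibrates the scenario once, then for each replicate generates a
#' dataset, applies every requested estimator (with its standard-error
#' method, if any), and summarizes bias, SEs and coverage against the
#' scenario truth.  Replicates are seeded individually from the master
#' seed, so the study is deterministic and each replicate is individually
#' reproducible.  Failed replicates are dropped; a failure rate above 2%
#' for any method flags the report invalid.
#'
#' @param config a [scenario_config()].
#' @param methods subset of `c("iptw_orig", "iptw_trim", "aiptw_satc",
#'   "aiptw_rsatc", "aiptw_np")`.
#' @param R number of replicates.
#' @param master_seed integer master seed.
#' @param se named character vector mapping method names to `"sandwich"`,
#'   `"bootstrap"` or `"none"` (default: none for all).
#' @param B bootstrap replicates for methods with `se = "bootstrap"`.
#' @param estimand passed to the estimators.
#' @return An object of class `mc_report`: list with `metrics` (data
#'   frame: method, param, pb, t_se, s_se, cp95 for beta0/beta1/delta),
#'   `vc_summary` (method, param, avg_est, s_se for sigma0/sigma1/rho),
#'   `estimates` (array method x quantity x replicate), `failures`,
#'   `valid`, `config`, `R`, `master_seed`, `B`.
#' @export
run_replications <- function(config, methods = c("iptw_orig", "aiptw_satc"),
                             R = 100L, master_seed = 1L, se = NULL, B = 30L,
                             estimand = "student_population") {
  stopifnot(all(methods %in% .mc_methods), R >= 2L)
  coeffs <- calibrate_assignment(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * R), R, 2L)
  qty <- c("beta0", "beta1", "delta", "sigma0", "sigma1", "rho",
           "se_beta0", "se_beta1", "se_delta")
  est <- array(NA_real_, c(length(methods), length(qty), R),
               dimnames = list(methods, qty, NULL))
  failures <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(R)) {
    d <- generate_dataset(config, coeffs, seeds[r, 1L])
    for (m in methods) {
      se_kind <- if (!is.null(se) && m %in% names(se)) se[[m]] else "none"
      res <- tryCatch(
        run_one_method(d, m, se_kind, B, seeds[r, 2L], estimand),
        error = function(e) NULL)
      if (is.null(res)) {
        failures[m] <- failures[m] + 1L
      } else {
        est[m, , r] <- unlist(res)[qty]
      }
    }
  }
  truth <- c(beta0 = config$beta[1], beta1 = config$beta[2],
             delta = config$beta[2] - config$beta[1])
  metrics <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(names(truth), function(pq) {
      es <- est[m, pq, ]
      if (sum(is.finite(es)) < 2L) return(NULL)
      ses <- est[m, paste0("se_", pq), ]
      mm <- compute_metrics(es, if (all(is.na(ses))) NULL else ses,
                            truth[[pq]])
      data.frame(method = m, param = pq, t(mm), stringsAsFactors = FALSE)
    }))
  }))
  vc_summary <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(c("sigma0", "sigma1", "rho"), function(pq) {
      es <- est[m, pq, ]
      if (sum(is.finite(es)) < 2L) return(NULL)
      data.frame(method = m, param = pq,
                 avg_est = mean(es, na.rm = TRUE),
                 s_se = stats::sd(es[is.finite(es)]),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(metrics = metrics, vc_summary = vc_summary,
                 estimates = est, failures = failures,
                 valid = all(failures <= 0.02 * R),
                 config = config, R = R, master_seed = master_seed, B = B),
            class = "mc_report")
}

#' Recompute a reference results grid
#'
#' Runs the scenario presets belonging to one of the three reference
#' tables at the requested replication count and emits the recomputed
#' metrics side by side with the published reference values and their
#' absolute differences.
#'
#' @param table_id 1, 2 or 3.
#' @param R replicates per scenario.
#' @param master_seed integer master seed.
#' @param se `"auto"` (sandwich for IPTW, bootstrap for AIPTW, as used
#'   for the reference coverage results; only meaningful for table 1) or
#'   `"none"` for point estimates only.
#' @param B bootstrap replicates when `se = "auto"`.
#' @return A data frame with columns `scenario`, `method`, `metric`,
#'   `param`, `value`, `reference`, `abs_diff`; the per-scenario
#'   `mc_report`s are attached as attribute `reports`.
#' @export
reproduce_table <- function(table_id, R = 300L, master_seed = 1L,
                            se = c("auto", "none"), B = 30L) {
  se <- match.arg(se)
  scenarios <- .table_scenarios[[as.character(table_id)]]
  if (is.null(scenarios)) stop("table_id must be 1, 2 or 3")
  methods <- c("iptw_orig", "iptw_trim", "aiptw_satc", "aiptw_rsatc")
  se_map <- if (se == "auto") {
    c(iptw_orig = "sandwich", iptw_trim = "sandwich",
      aiptw_satc = "bootstrap", aiptw_rsatc = "bootstrap")
  } else NULL
  reports <- lapply(scenarios, function(sc) {
    run_replications(scenario_preset(sc), methods, R = R,
                     master_seed = master_seed, se = se_map, B = B)
  })
  names(reports) <- scenarios
  got <- do.call(rbind, lapply(scenarios, function(sc) {
    rp <- reports[[sc]]
    long_beta <- do.call(rbind, lapply(c("pb", "t_se", "s_se", "cp95"),
      function(met) {
        data.frame(scenario = sc, method = rp$metrics$method,
                   metric = met, param = rp$metrics$param,
                   value = rp$metrics[[met]], stringsAsFactors = FALSE)
      }))
    long_vc <- rbind(
      data.frame(scenario = sc, method = rp$vc_summary$method,
                 metric = "avg_est", param = rp$vc_summary$param,
                 value = rp$vc_summary$avg_est, stringsAsFactors = FALSE),
      data.frame(scenario = sc, method = rp$vc_summary$method,
                 metric = "s_se", param = rp$vc_summary$param,
                 value = rp$vc_summary$s_se, stringsAsFactors = FALSE))
    rbind(long_beta, long_vc)
  }))
  ref <- reference_results(table_id)
  out <- merge(ref, got,
               by = c("scenario", "method", "metric", "param"),
               all.x = TRUE, sort = FALSE)
  out$abs_diff <- abs(out$value - out$reference)
  out <- out[, c("scenario", "method", "metric", "param",
                 "value", "reference", "abs_diff")]
  attr(out, "reports") <- reports
  out
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("Monte Carlo report: %d replicates, seed %d%s\n",
              x$R, x$master_seed,
              if (x$valid) "" else " [INVALID: >2% failures]"))
  if (any(x$failures > 0)) {
    cat("failures: ")
    print(x$failures[x$failures > 0])
  }
  print(transform(x$metrics, pb = round(pb, 4), t_se = round(t_se, 3),
                  s_se = round(s_se, 3), cp95 = round(cp95, 3)))
  invisible(x)
}
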