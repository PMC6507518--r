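#' Construct a clustered dataset
#'
#' A `clustered_dataset` is a data frame with one row per unit holding the
#' cluster label, the binary treatment indicator and the continuous outcome
#' (e.g. a test-score gain).  Rows added later by the augmentation step are
#' marked with `is_pseudo = TRUE`; freshly constructed data are all observed.
#'
#' @param cluster_id vector of cluster labels (coerced to character; labels
#'   are opaque, no ordering is assumed).
#' @param t binary treatment indicator, coded 0/1.
#' @param y numeric outcome, finite for every unit.
#' @param is_pseudo logical flag per unit; `FALSE` for observed rows.
#' @param unit_weight optional positive unit-level weight column.
#' @return A data frame of class `clustered_dataset` with columns
#'   `cluster_id`, `t`, `y`, `is_pseudo` and optionally `unit_weight`.
#' @examples
#' d <- clustered_dataset(rep(c("a", "b"), each = 3),
#'                        c(1, 0, 0, 1, 1, 1), rnorm(6))
#' cluster_summaries(d)
#' @export
clustered_dataset <- function(cluster_id, t, y, is_pseudo = FALSE,
                              unit_weight = NULL) {
  n <- length(y)
  d <- data.frame(cluster_id = as.character(cluster_id),
                  t = as.integer(t),
                  y = as.numeric(y),
                  is_pseudo = rep_len(as.logical(is_pseudo), n),
                  stringsAsFactors = FALSE)
  if (!is.null(unit_weight)) d$unit_weight <- as.numeric(unit_weight)
  class(d) <- c("clustered_dataset", "data.frame")
  validate_clustered_dataset(d)
}

#' Validate a clustered dataset
#'
#' Checks the invariants: every unit has a cluster label, `t` is 0/1, `y` is
#' finite, and any `unit_weight` present is strictly positive.
#'
#' @param d object to validate.
#' @return `d`, invisibly unchanged, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_clustered_dataset <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("cluster_id", "t", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("dataset has no rows")
  bad <- which(is.na(d$cluster_id) | !nzchar(d$cluster_id))
  if (length(bad)) stop("missing cluster_id at row ", bad[1L])
  bad <- which(!(d$t %in% c(0L, 1L)))
  if (length(bad)) stop("non-binary treatment at row ", bad[1L])
  bad <- which(!is.finite(d$y))
  if (length(bad)) stop("missing or non-finite outcome at row ", bad[1L])
  if (!is.null(d$unit_weight)) {
    bad <- which(!is.finite(d$unit_weight) | d$unit_weight <= 0)
    if (length(bad)) stop("non-positive unit_weight at row ", bad[1L])
  }
  if (is.null(d$is_pseudo)) d$is_pseudo <- FALSE
  if (!inherits(d, "clustered_dataset"))
    class(d) <- c("clustered_dataset", "data.frame")
  d
}

#' Read a clustered dataset from a delimited text file
#'
#' Expects a header row; columns are mapped through `cols`.  A two-level
#' non-numeric treatment coding can be declared via `treated_level`, which is
#' recoded to 1 (all other values to 0).
#'
#' @param path path to an existing delimited file.
#' @param cols named character vector mapping the canonical names
#'   (`cluster_id`, `t`, `y`, and optionally `is_pseudo`, `unit_weight`)
#'   to the column names in the file.
#' @param treated_level optional value of the treatment column to recode
#'   to 1; required when the column is not already 0/1.
#' @param sep field delimiter (default comma).
#' @return A validated [clustered_dataset()] with file row order preserved
#'   and cluster labels kept verbatim.
#' @export
read_clustered_data <- function(path,
                                cols = c(cluster_id = "cluster_id",
                                         t = "t", y = "y"),
                                treated_level = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty file: ", path)
  for (nm in c("cluster_id", "t", "y")) {
    if (is.na(cols[nm]) || !(cols[nm] %in% names(raw)))
      stop("column for '", nm, "' (", cols[nm], ") not found in ", path)
  }
  tcol <- raw[[cols["t"]]]
  if (!is.null(treated_level)) {
    t <- as.integer(tcol == treated_level)
  } else {
    t <- suppressWarnings(as.numeric(tcol))
    if (anyNA(t) || !all(t %in% c(0, 1)))
      stop("treatment column is not coded 0/1; declare treated_level")
  }
  y <- suppressWarnings(as.numeric(raw[[cols["y"]]]))
  bad <- which(is.na(y))
  if (length(bad)) stop("missing or non-numeric outcome at row ", bad[1L])
  is_pseudo <- FALSE
  if (!is.na(cols["is_pseudo"]) && cols["is_pseudo"] %in% names(raw))
    is_pseudo <- as.logical(raw[[cols["is_pseudo"]]])
  unit_weight <- NULL
  if (!is.na(cols["unit_weight"]) && cols["unit_weight"] %in% names(raw))
    unit_weight <- as.numeric(raw[[cols["unit_weight"]]])
  clustered_dataset(raw[[cols["cluster_id"]]], t, y,
                    is_pseudo = is_pseudo, unit_weight = unit_weight)
}

#' Write a clustered dataset to a delimited text file
#'
#' Writes `cluster_id`, `t`, `y` and, when informative, `is_pseudo` and
#' `unit_weight` (at full precision) with a header row.  Round-trips
#' through [read_clustered_data()] bit-identically on labels and treatment
#' and within print precision on the outcome.
#'
#' @param d a [clustered_dataset()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_clustered_data <- function(d, path, sep = ",") {
  d <- validate_clustered_dataset(d)
  out <- data.frame(cluster_id = d$cluster_id, t = d$t,
                    y = format(d$y, digits = 17, trim = TRUE),
                    stringsAsFactors = FALSE)
  if (any(d$is_pseudo)) out$is_pseudo <- d$is_pseudo
  if (!is.null(d$unit_weight))
    out$unit_weight <- format(d$unit_weight, digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-cluster treatment counts and positivity status
#'
#' Summarizes each cluster as its size `n_k`, treated count `n_k1`, and
#' status: `mixed` when `0 < n_k1 < n_k`, otherwise `all_treated` or
#' `all_control`.  Clusters with status other than `mixed` are the
#' practical positivity violations.
#'
#' @param d a [clustered_dataset()].
#' @return A data frame of class `cluster_summary` with one row per
#'   distinct cluster (in order of first appearance) and columns
#'   `cluster_id`, `n_k`, `n_k1`, `status`.
#' @export
cluster_summaries <- function(d) {
  d <- validate_clustered_dataset(d)
  ids <- unique(d$cluster_id)
  f <- factor(d$cluster_id, levels = ids)
  n_k <- as.integer(tabulate(f, nbins = length(ids)))
  n_k1 <- as.integer(rowsum(d$t, f, reorder = FALSE))
  status <- ifelse(n_k1 == 0L, "all_control",
                   ifelse(n_k1 == n_k, "all_treated", "mixed"))
  s <- data.frame(cluster_id = ids, n_k = n_k, n_k1 = n_k1,
                  status = status, stringsAsFactors = FALSE)
  class(s) <- c("cluster_summary", "data.frame")
  s
}

#' @export
print.clustered_dataset <- function(x, ...) {
  s <- cluster_summaries(x)
  nviol <- sum(s$status != "mixed")
  cat(sprintf(paste0("Clustered dataset: %d units in %d clusters ",
                     "(%d treated; %d violating cluster%s)\n"),
              nrow(x), nrow(s), sum(x$t), nviol,
              if (nviol == 1L) "" else "s"))
  if (any(x$is_pseudo))
    cat(sprintf("  including %d pseudo-unit(s) from augmentation\n",
                sum(x$is_pseudo)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
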