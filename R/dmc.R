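#' Per-probe group means and delta beta
#'
#' Arithmetic mean beta-value per probe within each group, with missing
#' entries excluded per probe (pairwise deletion); the number of missing
#' entries dropped is recorded in column `n_missing`.
#'
#' @param study A [beta_study()].
#' @return `data.frame` with `probe_id`, `mean_case`, `mean_ref`,
#'   `delta_beta` (case minus reference, in `[-1, 1]`) and `n_missing`.
#' @export
group_means <- function(study) {
  ref <- group_columns(study, study$ref_group)
  cas <- group_columns(study, study$case_group)
  if (!length(ref) || !length(cas)) stop("both groups must be non-empty")
  b <- study$beta
  mean_ref <- rowMeans(b[, ref, drop = FALSE], na.rm = TRUE)
  mean_case <- rowMeans(b[, cas, drop = FALSE], na.rm = TRUE)
  data.frame(
    probe_id = rownames(b),
    mean_case = mean_case, mean_ref = mean_ref,
    delta_beta = mean_case - mean_ref,
    n_missing = rowSums(is.na(b)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Row-wise mean/variance/n with NA handling, shared by the Welch test.
.row_moments <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = m, var = v)
}

#' Welch's unequal-variance t-test, vectorised over probes
#'
#' Two-sided Welch t-test of the case-vs-reference beta-value difference at
#' every probe, with Welch-Satterthwaite degrees of freedom and per-probe
#' pairwise deletion of missing values. Degenerate probes with zero
#' within-group variance in both groups yield p = 1 when the group means are
#' equal and the smallest representable positive p otherwise.
#'
#' @param study A [beta_study()].
#' @return `data.frame` with `probe_id`, `statistic`, `df` and `p_value`
#'   (two-sided, in `(0, 1]`, invariant under swapping the group labels).
#' @export
probe_welch_t <- function(study) {
  ref <- group_columns(study, study$ref_group)
  cas <- group_columns(study, study$case_group)
  if (length(ref) < 2L || length(cas) < 2L) {
    stop("each group needs at least 2 samples for a variance estimate")
  }
  a <- .row_moments(study$beta[, cas, drop = FALSE])
  b <- .row_moments(study$beta[, ref, drop = FALSE])
  se2 <- a$var / a$n + b$var / b$n
  tstat <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- !is.na(se2) & se2 == 0
  tstat[zero_se] <- 0
  p[zero_se & (a$mean == b$mean)] <- 1
  p[zero_se & (a$mean != b$mean)] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  data.frame(
    probe_id = rownames(study$beta),
    statistic = tstat, df = df, p_value = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]): sort ascending,
#' scale by m/rank, enforce monotonicity by a running minimum from the
#' largest rank, cap at 1 and restore the input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1] at positions: ",
      paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated CpGs
#'
#' A probe is a DMC when its adjusted p-value is strictly below
#' `p_threshold` *and* its absolute delta beta strictly exceeds
#' `delta_threshold`. DMCs are classified `hyper` when the case-group mean
#' exceeds the reference mean (positive delta) and `hypo` otherwise;
#' non-DMCs are `none`.
#'
#' @param res `data.frame` with columns `adjusted_p` and `delta_beta`.
#' @param p_threshold Adjusted-p ceiling (strict; default 0.01).
#' @param delta_threshold Absolute delta-beta floor (strict; default 0.15).
#' @return The input with `is_dmc` and `direction` columns set; summary
#'   counts are attached as attribute `"dmc_summary"`.
#' @export
call_dmcs <- function(res, p_threshold = 0.01, delta_threshold = 0.15) {
  stopifnot(all(c("adjusted_p", "delta_beta") %in% names(res)))
  is_dmc <- !is.na(res$adjusted_p) & !is.na(res$delta_beta) &
    res$adjusted_p < p_threshold & abs(res$delta_beta) > delta_threshold
  direction <- rep("none", nrow(res))
  direction[is_dmc & res$delta_beta > 0] <- "hyper"
  direction[is_dmc & res$delta_beta < 0] <- "hypo"
  res$is_dmc <- is_dmc
  res$direction <- direction
  n_hyper <- sum(direction == "hyper")
  n_hypo <- sum(direction == "hypo")
  attr(res, "dmc_summary") <- c(
    total = n_hyper + n_hypo, hyper = n_hyper, hypo = n_hypo,
    pct_hyper = if (n_hyper + n_hypo > 0) 100 * n_hyper / (n_hyper + n_hypo) else NA_real_,
    pct_hypo = if (n_hyper + n_hypo > 0) 100 * n_hypo / (n_hyper + n_hypo) else NA_real_
  )
  res
}

#' Full differential-methylation analysis of a study
#'
#' Runs [group_means()], the per-probe test (Welch's t by default; any
#' function with the same signature can be plugged in), [bh_adjust()] and
#' [call_dmcs()], and assembles the per-probe result table.
#'
#' @param study A [beta_study()] (typically the retained set from
#'   [filter_probes()]).
#' @param p_threshold,delta_threshold DMC thresholds, see [call_dmcs()].
#' @param test_fun Per-probe test; a function of `study` returning a
#'   `data.frame` with `probe_id` and `p_value`.
#' @return A `DmcResult` data.frame: `probe_id`, `mean_case`, `mean_ref`,
#'   `delta_beta`, `raw_p`, `adjusted_p`, `is_dmc`, `direction`.
#' @export
dmc_analysis <- function(study, p_threshold = 0.01, delta_threshold = 0.15,
                         test_fun = probe_welch_t) {
  means <- group_means(study)
  test <- test_fun(study)
  stopifnot(identical(means$probe_id, test$probe_id))
  res <- data.frame(
    probe_id = means$probe_id,
    mean_case = means$mean_case, mean_ref = means$mean_ref,
    delta_beta = means$delta_beta,
    raw_p = test$p_value,
    adjusted_p = bh_adjust(test$p_value),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- call_dmcs(res, p_threshold = p_threshold, delta_threshold = delta_threshold)
  class(res) <- c("DmcResult", "data.frame")
  res
}

#' Summary counts of a DMC result
#' @param object A `DmcResult` from [dmc_analysis()] or [call_dmcs()].
#' @param ... Unused.
#' @return Named vector: total, hyper, hypo, pct_hyper, pct_hypo.
#' @export
summary.DmcResult <- function(object, ...) {
  attr(object, "dmc_summary")
}
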