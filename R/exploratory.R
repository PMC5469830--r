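#' Classical multidimensional scaling of sample beta-profiles
#'
#' Torgerson scaling ([stats::cmdscale()]) on pairwise Euclidean distances
#' between sample columns of a beta matrix. Coordinates are centred by
#' construction; configurations that are exactly embeddable in `n_dims`
#' dimensions reproduce their distance matrix exactly. A constant matrix
#' (all pairwise distances zero) yields an all-zero embedding with a
#' warning.
#'
#' @param beta Numeric matrix, probes x samples.
#' @param n_dims Number of output dimensions (default 2).
#' @return List with `points` (samples x `n_dims`, rownames = sample ids)
#'   and `eig` (eigenvalue spectrum of the scaling solution).
#' @export
mds_embed <- function(beta, n_dims = 2L) {
  n_samp <- ncol(beta)
  if (n_samp < 3L) stop("MDS needs at least 3 samples")
  d <- stats::dist(t(beta))
  if (all(d == 0)) {
    warning("constant beta matrix: all pairwise distances are zero")
    pts <- matrix(0, n_samp, n_dims, dimnames = list(colnames(beta), NULL))
    return(list(points = pts, eig = rep(0, n_samp)))
  }
  sol <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  pts <- sol$points
  if (ncol(pts) < n_dims) { # degenerate geometry: pad trailing zero axes
    pts <- cbind(pts, matrix(0, n_samp, n_dims - ncol(pts)))
  }
  rownames(pts) <- colnames(beta)
  list(points = pts, eig = sol$eig)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Euclidean distance between sample beta-profiles with average linkage by
#' default (both configurable). Typically run on the beta matrix restricted
#' to the DMCs.
#'
#' @param beta Numeric matrix, probes x samples (>= 2 samples).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An [stats::hclust] object (merge history, heights, leaf order).
#' @export
hier_cluster <- function(beta, method = "average") {
  if (ncol(beta) < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(stats::dist(t(beta)), method = method)
}

#' Per-group coefficient of variation of per-sample median beta
#'
#' For each sample the median beta-value across probes; for each group the
#' coefficient of variation (sd / mean x 100) of those medians. A group
#' whose mean median is zero has an undefined CV (`NA` with status
#' `"undefined"`).
#'
#' @param beta Numeric matrix, probes x samples.
#' @param groups Group label per sample (length = `ncol(beta)`), each group
#'   with >= 2 samples.
#' @return `data.frame` with `group`, `n`, `mean_median`, `sd_median`,
#'   `cv_pct`, `status`.
#' @export
median_beta_cv <- function(beta, groups) {
  stopifnot(length(groups) == ncol(beta))
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  med <- apply(beta, 2L, stats::median, na.rm = TRUE)
  out <- lapply(split(med, groups), function(m) {
    mu <- mean(m)
    s <- stats::sd(m)
    data.frame(
      n = length(m), mean_median = mu, sd_median = s,
      cv_pct = if (mu == 0) NA_real_ else 100 * s / mu,
      status = if (mu == 0) "undefined" else "ok",
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(group = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Median-centred Levene (Brown-Forsythe) test of equal group variances
#'
#' One-way ANOVA F-test on the absolute deviations of each observation from
#' its group median (via [car::leveneTest()] with `center = median`),
#' testing whether the spread differs between groups. Location shifts of a
#' whole group do not affect the statistic. When every deviation is zero
#' the test is degenerate and p = 1 is returned.
#'
#' @param values Numeric vector (e.g. per-sample median beta-values).
#' @param groups Group label per value; >= 2 values per group.
#' @return List with `statistic` (F), `df` (numerator, denominator) and
#'   `p_value`.
#' @export
levene_median_test <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  dev <- abs(values - stats::ave(values, groups, FUN = stats::median))
  if (all(dev == 0)) {
    return(list(statistic = 0, df = c(nlevels(groups) - 1L, length(values) - nlevels(groups)), p_value = 1))
  }
  lt <- car::leveneTest(values ~ groups, center = stats::median)
  list(
    statistic = lt[1, "F value"],
    df = c(lt[1, "Df"], lt[2, "Df"]),
    p_value = lt[1, "Pr(>F)"]
  )
}
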