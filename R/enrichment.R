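#' A 2x2 contingency table
#'
#' Cell layout: rows are {in-category, not-in-category}, columns are the
#' two groups being compared, so `a`/`c` are the in/out counts of group 1
#' and `b`/`d` would be... concretely the stored fields are the four cells
#' `a` (group-1 in-category), `b` (group-1 out or group-2 in, depending on
#' the builder -- see [dmc_vs_background_table()] and
#' [direction_table()] for the two layouts used by the reports). The
#' statistics ([odds_ratio()], [katz_ci()], [yates_chisq()]) only assume
#' the cross-product convention OR = (a*d)/(b*c).
#'
#' @param a,b,c,d Non-negative integer cell counts; grand total must be
#'   positive.
#' @return Object of class `ContingencyTable`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative")
  }
  if (sum(cells) <= 0) stop("contingency table grand total must be positive")
  structure(as.list(cells), class = "ContingencyTable")
}

#' @export
print.ContingencyTable <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
    dimnames = list(c("in", "out"), c("grp1", "grp2"))
  )
  print(m)
  invisible(x)
}

#' Build the DMC-vs-background 2x2 for one annotation category
#'
#' The "all CpGs analysed" column of a Table-1-style report includes the
#' DMCs, so the proper background for an enrichment odds ratio is the
#' *non-DMC* probes: `a = dmc_in_cat`, `b = dmc_total - dmc_in_cat`,
#' `c = analysed_in_cat - dmc_in_cat`,
#' `d = (analysed_total - dmc_total) - c`. Using the raw analysed counts as
#' the second column (without subtracting the DMCs) double-counts every DMC
#' and yields different odds ratios; this function always subtracts.
#'
#' @param dmc_in_cat,dmc_total DMC counts in the category and overall.
#' @param analysed_in_cat,analysed_total Analysed counts (DMCs included).
#' @return A [contingency_table()] of DMC vs non-DMC by category status.
#' @export
dmc_vs_background_table <- function(dmc_in_cat, dmc_total,
                                    analysed_in_cat, analysed_total) {
  if (dmc_in_cat > dmc_total || analysed_in_cat > analysed_total ||
    dmc_in_cat > analysed_in_cat || dmc_total > analysed_total) {
    stop("inconsistent counts: category/total or DMC/analysed ordering violated")
  }
  a <- dmc_in_cat
  b <- dmc_total - dmc_in_cat
  cc <- analysed_in_cat - dmc_in_cat
  d <- (analysed_total - dmc_total) - cc
  if (d < 0) stop("inconsistent counts: derived background cell is negative")
  contingency_table(a, b, cc, d)
}

#' Build the hyper-vs-hypo 2x2 for one annotation category
#'
#' Compares the direction composition of DMCs inside a category with those
#' outside it: `a = hyper_in`, `b = hypo_in`, `c = hyper_total - hyper_in`,
#' `d = hypo_total - hypo_in`. With this layout the odds ratio is the odds
#' of hypermethylation inside the category over the odds outside it.
#'
#' @param hyper_in,hypo_in Direction counts within the category.
#' @param hyper_total,hypo_total Direction counts over all DMCs.
#' @return A [contingency_table()].
#' @export
direction_table <- function(hyper_in, hypo_in, hyper_total, hypo_total) {
  if (hyper_in > hyper_total || hypo_in > hypo_total) {
    stop("inconsistent counts: in-category exceeds total")
  }
  contingency_table(hyper_in, hypo_in, hyper_total - hyper_in, hypo_total - hypo_in)
}

#' Odds ratio of a 2x2 table
#'
#' Plain cross-product `(a*d)/(b*c)`. A zero in `b` or `c` makes the ratio
#' infinite (`Inf`) or undefined (`NaN` when `a*d` is also zero); these are
#' returned as-is rather than raising, so callers can attach an explicit
#' status.
#'
#' @param t A [contingency_table()].
#' @return Numeric odds ratio (possibly `Inf`/`NaN`).
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "ContingencyTable"))
  num <- as.numeric(t$a) * as.numeric(t$d)
  den <- as.numeric(t$b) * as.numeric(t$c)
  if (den == 0) {
    return(if (num == 0) NaN else Inf)
  }
  num / den
}

#' Katz log-scale confidence interval for an odds ratio
#'
#' Normal approximation on the log odds ratio with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`:
#' `exp(log(OR) +/- z * SE)` with `z = 1.959964` at the default 95\% level.
#' Undefined when any cell is zero; then `c(NA, NA)` is returned with
#' attribute `status = "undefined"`.
#'
#' @param t A [contingency_table()].
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `c(low, high)`; attribute `status` is `"ok"` or
#'   `"undefined"`.
#' @export
katz_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "ContingencyTable"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    return(structure(c(NA_real_, NA_real_), status = "undefined"))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  lor <- log(odds_ratio(t))
  structure(exp(lor + c(-1, 1) * z * se), status = "ok")
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Statistic `N * (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' continuity correction floored at zero when `|ad - bc| < N/2`; p-value
#' from the upper tail of the chi-square distribution with 1 degree of
#' freedom. A zero margin makes the test degenerate; by convention p = 1 is
#' returned with a warning.
#'
#' @param t A [contingency_table()].
#' @return List with `statistic`, `df` (1) and `p_value`.
#' @export
yates_chisq <- function(t) {
  stopifnot(inherits(t, "ContingencyTable"))
  a <- as.numeric(t$a)
  b <- as.numeric(t$b)
  cc <- as.numeric(t$c)
  d <- as.numeric(t$d)
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    warning("zero margin in 2x2 table; returning p = 1 by convention")
    return(list(statistic = 0, df = 1L, p_value = 1))
  }
  num <- max(abs(a * d - b * cc) - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, df = 1L, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Multi-category goodness-of-fit test of a count distribution
#'
#' Chi-square comparison of observed category counts (e.g. DMCs per gene
#' region) against expectations proportional to a reference distribution
#' (e.g. all analysed probes per region), with `categories - 1` degrees of
#' freedom. Categories with zero expected count cannot contribute and are
#' dropped with a warning.
#'
#' @param observed Integer vector of observed counts per category.
#' @param expected_counts Reference counts per category (same length/order).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
goodness_of_fit_distribution <- function(observed, expected_counts) {
  stopifnot(length(observed) == length(expected_counts))
  keep <- expected_counts > 0
  if (!all(keep)) {
    warning(sum(!keep), " categorie(s) with zero expectation dropped")
    observed <- observed[keep]
    expected_counts <- expected_counts[keep]
  }
  if (length(observed) < 2L) stop("need at least 2 categories with positive expectation")
  e <- sum(observed) * expected_counts / sum(expected_counts)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Assemble OR/CI/p/status for one 2x2; shared by the table builders.
.enrich_stats <- function(t) {
  or <- odds_ratio(t)
  ci <- katz_ci(t)
  p <- suppressWarnings(yates_chisq(t)$p_value)
  status <- if (!is.finite(or)) {
    "undefined_or"
  } else if (attr(ci, "status") == "undefined") {
    "undefined_ci"
  } else {
    "ok"
  }
  list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2], p_value = p, status = status)
}

#' Build a Table-1-style enrichment report (DMC vs background)
#'
#' One row per annotation category. Percentages are category count over
#' column total x 100 (full precision; rounding is presentation-only).
#' Gene-region rows are computed against the *annotation* totals (a probe
#' annotated to two regions counts twice, so the gene-region column totals
#' may exceed the probe totals), island and enhancer rows against the probe
#' totals. Odds ratios, Katz 95\% CIs and Yates chi-square p-values come
#' from [dmc_vs_background_table()].
#'
#' @param counts Output of [count_by_region()] (columns `block`,
#'   `category`, `dmc_count`, `analysed_count`).
#' @param dmc_totals,analysed_totals Optional named (by block) column
#'   totals overriding the per-block sums; useful when reproducing a
#'   published table whose printed totals differ from its row sums.
#' @return `data.frame` with `block`, `category`, `count_dmc`, `pct_dmc`,
#'   `count_background`, `pct_background`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `status`.
#' @export
build_table1 <- function(counts, dmc_totals = NULL, analysed_totals = NULL) {
  out <- lapply(split(counts, counts$block), function(blk) {
    b <- blk$block[1]
    dmc_tot <- if (!is.null(dmc_totals) && b %in% names(dmc_totals)) {
      dmc_totals[[b]]
    } else {
      sum(blk$dmc_count)
    }
    ana_tot <- if (!is.null(analysed_totals) && b %in% names(analysed_totals)) {
      analysed_totals[[b]]
    } else {
      sum(blk$analysed_count)
    }
    rows <- lapply(seq_len(nrow(blk)), function(i) {
      t <- dmc_vs_background_table(
        blk$dmc_count[i], dmc_tot, blk$analysed_count[i], ana_tot
      )
      s <- .enrich_stats(t)
      data.frame(
        block = b, category = blk$category[i],
        count_dmc = blk$dmc_count[i],
        pct_dmc = 100 * blk$dmc_count[i] / dmc_tot,
        count_background = blk$analysed_count[i],
        pct_background = 100 * blk$analysed_count[i] / ana_tot,
        odds_ratio = s$odds_ratio, ci_low = s$ci_low, ci_high = s$ci_high,
        p_value = s$p_value, status = s$status,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out[unique(counts$block)])
  rownames(res) <- NULL
  res
}

#' Build a Table-2-style direction report (hyper vs hypo per category)
#'
#' For each annotation category, compares the hyper/hypo composition of
#' DMCs inside the category against DMCs outside it via
#' [direction_table()]. Per-category percentages are the hyper and hypo
#' shares of that category's DMCs (they sum to 100). When there are no
#' DMCs at all, an empty report is returned with a warning.
#'
#' @param dmc A `DmcResult` with `is_dmc` and `direction` set.
#' @param context A `ContextAssignment` covering the DMC probes.
#' @return `data.frame` with `block`, `category`, `count_hyper`,
#'   `pct_hyper`, `count_hypo`, `pct_hypo`, `total`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `status`.
#' @export
build_table2 <- function(dmc, context) {
  dmcs <- dmc[dmc$is_dmc, , drop = FALSE]
  if (nrow(dmcs) == 0L) {
    warning("no DMCs; direction report is empty")
    return(data.frame(
      block = character(), category = character(), count_hyper = integer(),
      pct_hyper = numeric(), count_hypo = integer(), pct_hypo = numeric(),
      total = integer(), odds_ratio = numeric(), ci_low = numeric(),
      ci_high = numeric(), p_value = numeric(), status = character(),
      stringsAsFactors = FALSE
    ))
  }
  counts_h <- count_by_region(context, transform_calls(dmcs, "hyper"))
  counts_l <- count_by_region(context, transform_calls(dmcs, "hypo"))
  hyper_total <- sum(dmcs$direction == "hyper")
  hypo_total <- sum(dmcs$direction == "hypo")
  rows <- lapply(seq_len(nrow(counts_h)), function(i) {
    hi <- counts_h$dmc_count[i]
    lo <- counts_l$dmc_count[i]
    tot <- hi + lo
    t <- direction_table(hi, lo, hyper_total, hypo_total)
    s <- .enrich_stats(t)
    data.frame(
      block = counts_h$block[i], category = counts_h$category[i],
      count_hyper = hi, pct_hyper = if (tot > 0) 100 * hi / tot else NA_real_,
      count_hypo = lo, pct_hypo = if (tot > 0) 100 * lo / tot else NA_real_,
      total = tot,
      odds_ratio = s$odds_ratio, ci_low = s$ci_low, ci_high = s$ci_high,
      p_value = s$p_value, status = s$status,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Re-call a DmcResult so that "is_dmc" marks only one direction; lets
# count_by_region tally hyper- and hypo-methylated probes separately.
transform_calls <- function(dmcs, direction) {
  out <- dmcs
  out$is_dmc <- dmcs$direction == direction
  out
}
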