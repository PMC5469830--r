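# Bundled reference counts from a published two-group oesophageal
# fibroblast 450K methylation comparison (12 normal vs 10 tumour-derived
# fibroblast lines; 4,856 DMCs over 408,329 analysed probes). The raw
# array data of that study were never deposited, but its printed
# per-category contingency counts fully determine the enrichment
# statistics, so they serve as exact regression fixtures for the odds
# ratio / CI / chi-square machinery.

#' Reference enrichment counts (DMC vs all analysed, per category)
#'
#' Per-category DMC and analysed-probe counts of the bundled reference
#' study, in the shape produced by [count_by_region()]. Note the printed
#' gene-region column totals (5,302 DMC annotations / 479,691 analysed
#' annotations) are carried separately because they differ slightly from
#' the row sums of the published table.
#'
#' @return List with `counts` (`block`, `category`, `dmc_count`,
#'   `analysed_count`), `dmc_totals` and `analysed_totals` (named by
#'   block).
#' @export
reference_table1_counts <- function() {
  counts <- utils::read.csv(
    system.file("extdata", "table1_counts.csv", package = "dmc450"),
    stringsAsFactors = FALSE
  )
  totals <- utils::read.csv(
    system.file("extdata", "table1_totals.csv", package = "dmc450"),
    stringsAsFactors = FALSE
  )
  list(
    counts = counts,
    dmc_totals = stats::setNames(totals$dmc_total, totals$block),
    analysed_totals = stats::setNames(totals$analysed_total, totals$block)
  )
}

#' Reference direction counts (hyper vs hypo DMCs, per category)
#'
#' Per-category hypermethylated/hypomethylated DMC counts of the bundled
#' reference study (1,613 hyper / 3,243 hypo overall).
#'
#' @return List with `counts` (`block`, `category`, `hyper_count`,
#'   `hypo_count`) and `totals` (`hyper_total`, `hypo_total` named by
#'   block).
#' @export
reference_table2_counts <- function() {
  counts <- utils::read.csv(
    system.file("extdata", "table2_counts.csv", package = "dmc450"),
    stringsAsFactors = FALSE
  )
  totals <- utils::read.csv(
    system.file("extdata", "table2_totals.csv", package = "dmc450"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, totals = totals)
}

#' Enrichment report from the bundled reference counts
#'
#' Rebuilds the DMC-vs-background enrichment table (odds ratio, Katz 95\%
#' CI, Yates chi-square p) from the bundled per-category counts using
#' exactly the same code path as a synthetic run ([build_table1()]).
#'
#' @return The [build_table1()] report for the reference counts.
#' @export
reference_table1 <- function() {
  ref <- reference_table1_counts()
  build_table1(ref$counts,
    dmc_totals = ref$dmc_totals,
    analysed_totals = ref$analysed_totals
  )
}
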