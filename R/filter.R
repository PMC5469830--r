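# Exclusion rules in audit order. A probe excluded by several rules is
# charged to the first one in this order, which makes the ledger a partition
# of the excluded set; the retained set itself never depends on the order.
filter_rule_names <- function() {
  c(
    "non_cpg", "snp_aligned", "multi_mapping", "snp_proximal",
    "detection_p", "bead_count", "sex_chromosome"
  )
}

normalize_chromosome <- function(chr) {
  toupper(sub("^chr", "", as.character(chr), ignore.case = TRUE))
}

#' Apply probe exclusion rules to a study
#'
#' Removes probes that (1) do not target a cytosine within a CpG, (2) align
#' to a known SNP, (3) align to multiple genomic locations, (4) have their
#' target cytosine two or fewer nucleotides from a SNP with minor allele
#' frequency above `maf_threshold`, (5) have a detection p-value greater
#' than `detection_threshold` in any sample, (6) have a bead count below
#' `min_beads` in any sample, or (7) sit on the X or Y chromosome. The
#' detection and MAF comparisons are strict (`p > 0.01` fails, `p = 0.01`
#' is retained; MAF must *exceed* the threshold).
#'
#' @param study A [beta_study()].
#' @param manifest Manifest `data.frame` covering every probe in the study
#'   (columns as produced by [generate_manifest()]).
#' @param maf_threshold SNP minor-allele-frequency threshold (default 0.05).
#' @param snp_window Maximum SNP distance, in nucleotides, for the proximity
#'   rule (default 2; `distance <= snp_window` fails when MAF exceeds the
#'   threshold).
#' @param detection_threshold Detection p-value ceiling (default 0.01).
#' @param min_beads Minimum bead count (default 3).
#' @return List with `retained` (probe ids), `ledger` (a `FilterLedger`:
#'   input/retained counts plus per-rule exclusion counts attributed to the
#'   first failing rule), `study` (the study restricted to retained probes)
#'   and `manifest` (likewise restricted).
#' @export
filter_probes <- function(study, manifest,
                          maf_threshold = 0.05, snp_window = 2,
                          detection_threshold = 0.01, min_beads = 3) {
  ids <- probe_ids(study)
  missing <- setdiff(ids, manifest$IlmnID)
  extra <- setdiff(manifest$IlmnID, ids)
  if (length(missing) || length(extra)) {
    stop(
      "probe id mismatch between manifest and matrices; missing from manifest: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      "; absent from matrices: ",
      paste(utils::head(extra, 5L), collapse = ", ")
    )
  }
  man <- manifest[match(ids, manifest$IlmnID), , drop = FALSE]

  snp_prox <- !is.na(man$snp_distance) & !is.na(man$snp_maf) &
    man$snp_distance <= snp_window & man$snp_maf > maf_threshold
  rules <- list(
    non_cpg = !man$target_is_cpg,
    snp_aligned = man$snp_at_target,
    multi_mapping = man$multi_mapping,
    snp_proximal = snp_prox,
    detection_p = rowSums(study$detection_p > detection_threshold, na.rm = TRUE) > 0,
    bead_count = rowSums(study$beads < min_beads, na.rm = TRUE) > 0,
    sex_chromosome = normalize_chromosome(man$CHR) %in% c("X", "Y")
  )

  excluded <- rep(FALSE, length(ids))
  counts <- integer(length(rules))
  names(counts) <- names(rules)
  for (nm in names(rules)) {
    newly <- rules[[nm]] & !excluded
    counts[nm] <- sum(newly)
    excluded <- excluded | rules[[nm]]
  }
  keep <- ids[!excluded]
  ledger <- structure(
    list(
      input_count = length(ids),
      retained_count = length(keep),
      excluded = counts
    ),
    class = "FilterLedger"
  )
  list(
    retained = keep,
    ledger = ledger,
    study = subset_study(study, keep),
    manifest = man[!excluded, , drop = FALSE]
  )
}

#' @export
print.FilterLedger <- function(x, ...) {
  cat("Probe filter ledger\n")
  cat("  input:   ", x$input_count, "\n")
  cat("  retained:", x$retained_count, "\n")
  for (nm in names(x$excluded)) {
    cat(sprintf("  - %-15s %d\n", nm, x$excluded[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.FilterLedger <- function(x, ...) {
  data.frame(
    rule = c("input", names(x$excluded), "retained"),
    count = c(x$input_count, unname(x$excluded), x$retained_count),
    stringsAsFactors = FALSE
  )
}
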