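# Readers and writers for the plain-text interchange formats of the
# pipeline: CSV manifest and matrices, TSV results, BED islands/DMCs, GMT
# gene sets. TSV output is tab-separated UTF-8 with Unix newlines so runs
# can be compared byte-for-byte.

#' Write a results table as TSV
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, eol = "\n", na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write a probe manifest as CSV
#'
#' Uses 450K-manifest conventions: logical `Enhancer` becomes `TRUE`/empty,
#' missing SNP fields become empty strings.
#'
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$Enhancer <- ifelse(isTRUE_vec(out$Enhancer), "TRUE", "")
  data.table::fwrite(out, path, sep = ",", quote = FALSE, eol = "\n", na = "")
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a probe manifest CSV
#' @param path Path to a manifest written by [write_manifest()] (or any CSV
#'   with the same columns).
#' @return Manifest data.frame with logical flag columns restored.
#' @export
read_manifest <- function(path) {
  man <- as.data.frame(data.table::fread(path, sep = ",", na.strings = "", colClasses = list(character = "CHR")))
  for (col in c("target_is_cpg", "multi_mapping", "snp_at_target")) {
    if (col %in% names(man)) man[[col]] <- isTRUE_vec(man[[col]])
  }
  man$Enhancer <- isTRUE_vec(man$Enhancer)
  for (col in c("UCSC_RefGene_Name", "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")) {
    if (col %in% names(man)) man[[col]][is.na(man[[col]])] <- ""
  }
  man
}

#' Write a probes-x-samples matrix as CSV
#' @param m Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = ",", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a probes-x-samples matrix CSV
#' @param path Path written by [write_matrix_csv()].
#' @return Numeric matrix with probe rownames.
#' @export
read_matrix_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = ","))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read CpG-island intervals from a BED3 file
#' @param path BED file (chrom, start, end; 0-based half-open, no header).
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
read_islands_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t"))
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' Write island intervals as BED3
#' @param islands `data.frame` with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_islands_bed <- function(islands, path) {
  data.table::fwrite(islands[, c("chrom", "start", "end")], path,
    sep = "\t", col.names = FALSE, quote = FALSE, eol = "\n"
  )
  invisible(path)
}

#' Export DMCs as single-base BED intervals
#'
#' Each DMC becomes a 0-based half-open single-base interval
#' `[pos - 1, pos)`; the name column is the probe id and the score column
#' encodes direction (1000 = hyper, 500 = hypo). Records with a missing
#' chromosome are skipped with a warning.
#'
#' @param dmc A `DmcResult` (only rows with `is_dmc` are exported).
#' @param context A `ContextAssignment` providing `chrom` and `pos`.
#' @param path Output path; a BED file with no header.
#' @return The path, invisibly.
#' @export
export_bed <- function(dmc, context, path) {
  rows <- dmc[dmc$is_dmc, , drop = FALSE]
  ctx <- context[match(rows$probe_id, context$probe_id), , drop = FALSE]
  bad <- is.na(ctx$chrom) | !nzchar(ctx$chrom)
  if (any(bad)) {
    warning(sum(bad), " DMC(s) with unknown chromosome skipped")
    rows <- rows[!bad, , drop = FALSE]
    ctx <- ctx[!bad, , drop = FALSE]
  }
  bed <- data.frame(
    chrom = ctx$chrom,
    start = ctx$pos - 1L,
    end = ctx$pos,
    name = rows$probe_id,
    score = ifelse(rows$direction == "hyper", 1000L, 500L),
    strand = rep(".", nrow(rows)),
    stringsAsFactors = FALSE
  )
  bed <- bed[order(match(bed$chrom, unique(bed$chrom)), bed$start), , drop = FALSE]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file exported by [export_bed()]
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`; empty files give an empty frame.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0L) {
    return(stats::setNames(
      data.frame(character(), integer(), integer(), character(), integer(), character(), stringsAsFactors = FALSE),
      cols
    ))
  }
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1)))
  stats::setNames(df[, seq_along(cols)], cols)
}

#' Write a simulated study to a directory of CSV files
#'
#' Emits `manifest.csv`, `betas.csv`, `detection_p.csv`, `bead_counts.csv`,
#' `sample_sheet.csv`, `truth.csv` and `islands.bed`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(sim$manifest, file.path(dir, "manifest.csv"))
  write_matrix_csv(sim$study$beta, file.path(dir, "betas.csv"))
  write_matrix_csv(sim$study$detection_p, file.path(dir, "detection_p.csv"))
  write_matrix_csv(sim$study$beads, file.path(dir, "bead_counts.csv"))
  data.table::fwrite(sim$study$samples, file.path(dir, "sample_sheet.csv"),
    sep = ",", quote = FALSE, eol = "\n"
  )
  data.table::fwrite(sim$study$truth[, c("probe_id", "direction")],
    file.path(dir, "truth.csv"),
    sep = ",", quote = FALSE, eol = "\n"
  )
  write_islands_bed(sim$islands, file.path(dir, "islands.bed"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing the CSV/BED files.
#' @param ref_group,case_group Group labels (defaults match the simulator).
#' @return List with `manifest`, `islands`, `study` (a [beta_study()]).
#' @export
read_study <- function(dir, ref_group = "NDF", case_group = "TDF") {
  samples <- as.data.frame(data.table::fread(file.path(dir, "sample_sheet.csv")))
  study <- beta_study(
    beta = read_matrix_csv(file.path(dir, "betas.csv")),
    detection_p = read_matrix_csv(file.path(dir, "detection_p.csv")),
    beads = read_matrix_csv(file.path(dir, "bead_counts.csv")),
    samples = samples,
    ref_group = ref_group, case_group = case_group
  )
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    tr <- as.data.frame(data.table::fread(truth_path))
    tr$is_dmc <- tr$direction != "none"
    study$truth <- tr[, c("probe_id", "is_dmc", "direction")]
  }
  isl_path <- file.path(dir, "islands.bed")
  list(
    manifest = read_manifest(file.path(dir, "manifest.csv")),
    islands = if (file.exists(isl_path)) read_islands_bed(isl_path) else NULL,
    study = study
  )
}

#' Read a transcript table (TSV)
#' @param path TSV with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss`.
#' @return A data.frame.
#' @export
read_transcripts <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = list(character = c("chrom", "strand"))))
}
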