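# Island layout used by the generator: each chromosome is tiled with a
# 20 kb period; within tile k the CpG island occupies the 0-based half-open
# interval [k*20000 + 8000, k*20000 + 9000). Shores (<= 2 kb from an island
# edge), shelves (2-4 kb) and open-sea zones (> 4 kb from every island) are
# then disjoint by construction, so a probe's island relation is decided by
# its position alone.
.TILE <- 20000L
.ISL_OFF <- 8000L
.ISL_LEN <- 1000L

manifest_columns <- function() {
  c(
    "IlmnID", "CHR", "MAPINFO", "target_is_cpg", "multi_mapping",
    "snp_at_target", "snp_distance", "snp_maf", "UCSC_RefGene_Name",
    "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island", "Enhancer"
  )
}

# Draw a 0-based position inside tile `k` consistent with the requested
# island relation. Distances are measured in nucleotides from the nearest
# island edge, with the base adjacent to the island at distance 1.
.position_in_tile <- function(relation, k) {
  n <- length(k)
  base <- k * .TILE
  s <- .ISL_OFF
  e <- .ISL_OFF + .ISL_LEN
  off <- integer(n)
  isl <- relation == "Island"
  off[isl] <- s + sample.int(.ISL_LEN, sum(isl), replace = TRUE) - 1L
  for (rel in c("Shore", "Shelf")) {
    idx <- which(relation == rel)
    if (!length(idx)) next
    rng <- if (rel == "Shore") 1:2000 else 2001:4000
    d <- sample(rng, length(idx), replace = TRUE)
    side <- sample(c(-1L, 1L), length(idx), replace = TRUE)
    off[idx] <- ifelse(side < 0L, s - d, e + d - 1L)
  }
  open <- which(relation == "OpenSea")
  if (length(open)) {
    # zone [tile + 13000, tile + 23999]: > 4000 nt from the flanking islands
    off[open] <- (e + 4000L) + sample.int(11000L, length(open), replace = TRUE) - 1L
  }
  base + off
}

#' Generate a synthetic 450K-style probe manifest
#'
#' Lays out probes over chromosomes 1-22 (plus X/Y artifact probes at the
#' configured rate), assigns each probe a CpG-island relation, gene-region
#' annotation and enhancer flag at the configured category frequencies, and
#' places it at a genomic position consistent with its island relation
#' relative to an explicit set of island intervals. QC artifacts (non-CpG
#' targets, SNP-overlapping, multi-mapping and SNP-proximal probes) are
#' planted at the configured rates so every downstream exclusion rule is
#' exercised.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with 450K-manifest-style columns (`IlmnID`, `CHR`,
#'   `MAPINFO`, `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#'   `Relation_to_UCSC_CpG_Island`, `Enhancer`) plus QC flag columns.
#'   Positions are strictly increasing within each chromosome. The CpG-island
#'   intervals used for placement are attached as attribute `"islands"`
#'   (`chrom`, `start`, `end`; 0-based half-open) and retrievable with
#'   [island_intervals()].
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  empty <- data.frame(
    IlmnID = character(), CHR = character(), MAPINFO = integer(),
    target_is_cpg = logical(), multi_mapping = logical(),
    snp_at_target = logical(), snp_distance = integer(), snp_maf = numeric(),
    UCSC_RefGene_Name = character(), UCSC_RefGene_Group = character(),
    Relation_to_UCSC_CpG_Island = character(), Enhancer = logical(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    attr(empty, "islands") <- data.frame(
      chrom = character(), start = integer(), end = integer()
    )
    return(empty)
  }
  set.seed(stage_seed(config$seed, "manifest"))
  rates <- config$artifact_rates
  freqs <- config$region_freqs

  sex <- stats::runif(n) < rates[["sex_chromosome"]]
  chrom <- character(n)
  chrom[!sex] <- sample(as.character(1:22), sum(!sex), replace = TRUE)
  chrom[sex] <- sample(c("X", "Y"), sum(sex), replace = TRUE, prob = c(2, 1))

  relation <- sample(names(freqs$island_relation), n,
    replace = TRUE, prob = freqs$island_relation
  )

  pos0 <- integer(n)
  n_tiles <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    k_max <- max(4L, ceiling(length(idx) / 8))
    n_tiles[ch] <- k_max
    k <- sample.int(k_max, length(idx), replace = TRUE) - 1L
    p <- .position_in_tile(relation[idx], k)
    for (it in 1:100) {
      dup <- duplicated(p)
      if (!any(dup)) break
      p[dup] <- .position_in_tile(relation[idx][dup], k[dup])
    }
    if (anyDuplicated(p)) stop("could not place probes at unique positions")
    pos0[idx] <- p
  }

  region <- sample(names(freqs$gene_region), n,
    replace = TRUE, prob = freqs$gene_region
  )
  genic <- region != "Intergenic"
  gene <- character(n)
  gene[genic] <- paste0("G", chrom[genic], "_", pos0[genic] %/% .TILE)
  group <- ifelse(genic, region, "")

  enhancer <- stats::runif(n) < freqs$enhancer[["Enhancer"]]

  non_cpg <- stats::runif(n) < rates[["non_cpg"]]
  snp_at_target <- stats::runif(n) < rates[["snp_aligned"]]
  multi_mapping <- stats::runif(n) < rates[["multi_mapping"]]
  snp_proximal <- stats::runif(n) < rates[["snp_proximal"]]

  # SNP distance/MAF fields: proximal artifacts get a close common SNP;
  # some clean probes get decoy SNPs that the filter must retain
  # (close-but-rare, or common-but-distant).
  snp_distance <- rep(NA_integer_, n)
  snp_maf <- rep(NA_real_, n)
  snp_distance[snp_proximal] <- sample(0:2, sum(snp_proximal), replace = TRUE)
  snp_maf[snp_proximal] <- stats::runif(sum(snp_proximal), 0.051, 0.5)
  decoy <- !snp_proximal & stats::runif(n) < 0.25
  near_rare <- decoy & stats::runif(n) < 0.4
  snp_distance[near_rare] <- sample(0:2, sum(near_rare), replace = TRUE)
  snp_maf[near_rare] <- stats::runif(sum(near_rare), 0, 0.05)
  far <- decoy & !near_rare
  snp_distance[far] <- sample(3:500, sum(far), replace = TRUE)
  snp_maf[far] <- stats::runif(sum(far), 0, 0.5)

  ids <- ifelse(non_cpg,
    sprintf("ch.%s.%07d", chrom, seq_len(n)),
    sprintf("cg%07d", seq_len(n))
  )

  # 450K-style island-relation strings: upstream flank annotated N_*,
  # downstream S_*, open sea left blank; normalised on the way back in.
  in_tile <- pos0 %% .TILE
  upstream <- in_tile < .ISL_OFF
  rel_str <- relation
  rel_str[relation == "Shore"] <- ifelse(upstream[relation == "Shore"], "N_Shore", "S_Shore")
  rel_str[relation == "Shelf"] <- ifelse(upstream[relation == "Shelf"], "N_Shelf", "S_Shelf")
  rel_str[relation == "OpenSea"] <- ""

  man <- data.frame(
    IlmnID = ids, CHR = chrom, MAPINFO = pos0 + 1L,
    target_is_cpg = !non_cpg, multi_mapping = multi_mapping,
    snp_at_target = snp_at_target, snp_distance = snp_distance,
    snp_maf = snp_maf, UCSC_RefGene_Name = gene, UCSC_RefGene_Group = group,
    Relation_to_UCSC_CpG_Island = rel_str, Enhancer = enhancer,
    stringsAsFactors = FALSE
  )
  ord <- order(match(man$CHR, c(as.character(1:22), "X", "Y")), man$MAPINFO)
  man <- man[ord, , drop = FALSE]
  rownames(man) <- NULL

  isl <- do.call(rbind, lapply(names(n_tiles), function(ch) {
    k <- seq_len(n_tiles[[ch]]) - 1L
    data.frame(
      chrom = ch, start = k * .TILE + .ISL_OFF,
      end = k * .TILE + .ISL_OFF + .ISL_LEN, stringsAsFactors = FALSE
    )
  }))
  attr(man, "islands") <- isl[order(match(isl$chrom, c(as.character(1:22), "X", "Y")), isl$start), ]
  rownames(attr(man, "islands")) <- NULL
  man
}

#' CpG-island intervals attached to a simulated manifest
#'
#' @param manifest A manifest from [generate_manifest()].
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
island_intervals <- function(manifest) {
  isl <- attr(manifest, "islands")
  if (is.null(isl)) stop("manifest carries no island intervals")
  isl
}

#' Simulate beta-value, detection p-value and bead-count matrices
#'
#' Given a manifest, draws a two-group study. A configured fraction of
#' probes is truly differential: their case-group latent mean is shifted by
#' exactly `true_delta` (up for "hyper", down for "hypo" probes), with the
#' reference mean drawn so the shifted mean stays inside `[0.05, 0.95]`.
#' Non-differential probes get an island-context-dependent baseline (islands
#' mostly unmethylated, open sea mostly methylated), clipped to
#' `[0.01, 0.99]`. Observed beta-values are Beta(mean, precision) draws, so
#' every entry lies in `[0, 1]` and the expected group-mean difference at a
#' differential probe equals `true_delta`. Detection-p and bead-count
#' artifacts are planted at the configured rates for the filter to find.
#'
#' @param manifest Manifest from [generate_manifest()] (or any data.frame
#'   with the same columns).
#' @param config A [sim_config()] object.
#' @return A [beta_study()] with elements `beta`, `detection_p`, `beads`,
#'   `samples`, and a `truth` data.frame (`probe_id`, `is_dmc`, `direction`)
#'   recording which probes are truly differential, for parameter-recovery
#'   tests.
#' @export
simulate_betas <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(manifest) == 0L) stop("manifest is empty")
  if (config$n_ref < 2L || config$n_case < 2L) {
    stop("design error: each group needs at least 2 samples")
  }
  set.seed(stage_seed(config$seed, "betas"))
  n <- nrow(manifest)
  n_ref <- config$n_ref
  n_case <- config$n_case
  delta <- config$true_delta
  phi <- config$beta_precision

  is_dmc <- stats::runif(n) < config$dmc_fraction
  hyper <- is_dmc & stats::runif(n) < config$hyper_fraction
  direction <- rep("none", n)
  direction[is_dmc] <- ifelse(hyper[is_dmc], "hyper", "hypo")

  rel <- normalize_island_relation(manifest$Relation_to_UCSC_CpG_Island)
  mu_ref <- numeric(n)
  base_lo <- rel == "Island"
  base_mid <- rel == "Shore"
  base_hi <- !(base_lo | base_mid)
  mu_ref[base_lo] <- stats::runif(sum(base_lo), 0.03, 0.25)
  mu_ref[base_mid] <- stats::runif(sum(base_mid), 0.10, 0.60)
  mu_ref[base_hi] <- stats::runif(sum(base_hi), 0.40, 0.95)
  mu_ref <- pmin(pmax(mu_ref, 0.01), 0.99)

  up <- which(direction == "hyper")
  dn <- which(direction == "hypo")
  mu_ref[up] <- stats::runif(length(up), 0.05, 0.95 - delta)
  mu_ref[dn] <- stats::runif(length(dn), 0.05 + delta, 0.95)
  mu_case <- mu_ref
  mu_case[up] <- mu_ref[up] + delta
  mu_case[dn] <- mu_ref[dn] - delta

  draw_block <- function(mu, k) {
    matrix(stats::rbeta(n * k, rep(mu, k) * phi, (1 - rep(mu, k)) * phi),
      nrow = n, ncol = k
    )
  }
  beta <- cbind(draw_block(mu_ref, n_ref), draw_block(mu_case, n_case))
  n_samp <- n_ref + n_case
  sample_id <- c(sprintf("N.%02d", seq_len(n_ref)), sprintf("T.%02d", seq_len(n_case)))
  group <- c(rep("NDF", n_ref), rep("TDF", n_case))
  dimnames(beta) <- list(manifest$IlmnID, sample_id)

  detp <- matrix(stats::runif(n * n_samp, 0, 0.002),
    nrow = n, dimnames = dimnames(beta)
  )
  fail <- which(stats::runif(n) < config$artifact_rates[["detection_fail"]])
  if (length(fail)) {
    j <- sample.int(n_samp, length(fail), replace = TRUE)
    detp[cbind(fail, j)] <- stats::runif(length(fail), 0.0101, 0.2)
  }

  beads <- matrix(3L + stats::rpois(n * n_samp, 11),
    nrow = n, dimnames = dimnames(beta)
  )
  low <- which(stats::runif(n) < config$artifact_rates[["low_bead"]])
  if (length(low)) {
    j <- sample.int(n_samp, length(low), replace = TRUE)
    beads[cbind(low, j)] <- sample(0:2, length(low), replace = TRUE)
  }

  study <- beta_study(
    beta = beta, detection_p = detp, beads = beads,
    samples = data.frame(
      sample_id = sample_id, group = group,
      stringsAsFactors = FALSE
    ),
    ref_group = "NDF", case_group = "TDF"
  )
  study$truth <- data.frame(
    probe_id = manifest$IlmnID, is_dmc = is_dmc,
    direction = direction, stringsAsFactors = FALSE
  )
  study
}

#' Simulate a complete study (manifest + matrices) in one call
#'
#' @param config A [sim_config()] object.
#' @return List with `manifest`, `islands` and `study`.
#' @export
simulate_study <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  list(
    manifest = manifest,
    islands = island_intervals(manifest),
    study = simulate_betas(manifest, config)
  )
}
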