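# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# A minimal BetaStudy from explicit case/ref beta matrices (probes x
# samples); detection p and bead counts are clean unless supplied.
make_study <- function(beta_ref, beta_case, detp = NULL, beads = NULL) {
  stopifnot(nrow(beta_ref) == nrow(beta_case))
  n <- nrow(beta_ref)
  beta <- cbind(beta_ref, beta_case)
  ids <- rownames(beta_ref)
  if (is.null(ids)) ids <- sprintf("cg%07d", seq_len(n))
  samp <- c(
    sprintf("N.%02d", seq_len(ncol(beta_ref))),
    sprintf("T.%02d", seq_len(ncol(beta_case)))
  )
  dimnames(beta) <- list(ids, samp)
  if (is.null(detp)) detp <- matrix(0.001, n, ncol(beta))
  if (is.null(beads)) beads <- matrix(10L, n, ncol(beta))
  dimnames(detp) <- dimnames(beads) <- dimnames(beta)
  beta_study(
    beta = beta, detection_p = detp, beads = beads,
    samples = data.frame(
      sample_id = samp,
      group = c(rep("NDF", ncol(beta_ref)), rep("TDF", ncol(beta_case))),
      stringsAsFactors = FALSE
    ),
    ref_group = "NDF", case_group = "TDF"
  )
}

# A clean manifest row; override fields as needed.
manifest_row <- function(probe_id, chrom = "1", pos = 1000L,
                         target_is_cpg = TRUE, multi_mapping = FALSE,
                         snp_at_target = FALSE, snp_distance = NA_integer_,
                         snp_maf = NA_real_, gene = "", region = "",
                         island = "", enhancer = FALSE) {
  data.frame(
    IlmnID = probe_id, CHR = chrom, MAPINFO = as.integer(pos),
    target_is_cpg = target_is_cpg, multi_mapping = multi_mapping,
    snp_at_target = snp_at_target, snp_distance = snp_distance,
    snp_maf = snp_maf, UCSC_RefGene_Name = gene, UCSC_RefGene_Group = region,
    Relation_to_UCSC_CpG_Island = island, Enhancer = enhancer,
    stringsAsFactors = FALSE
  )
}

# Memoised medium-size synthetic run at the reference study conditions
# (12 vs 10 samples, 50k probes, 5% truly differential probes at
# |delta beta| = 0.3), shared by the recovery and invariant tests.
.fixture_env <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.fixture_env$run)) {
    return(.fixture_env$run)
  }
  cfg <- sim_config(
    n_probes = 50000L, n_ref = 12L, n_case = 10L,
    dmc_fraction = 0.05, true_delta = 0.3, beta_precision = 100,
    seed = 20170613L
  )
  sim <- simulate_study(cfg)
  filt <- filter_probes(sim$study, sim$manifest)
  dmc <- dmc_analysis(filt$study)
  .fixture_env$run <- list(cfg = cfg, sim = sim, filt = filt, dmc = dmc)
  .fixture_env$run
}
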