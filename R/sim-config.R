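#' Default annotation-category frequencies for simulated manifests
#'
#' Category probabilities for gene regions, CpG-island relation and enhancer
#' status, chosen to mirror the marginal annotation composition of an
#' autosomal, QC-passing 450K probe set (roughly 408k probes, of which about
#' a third sit in CpG islands and 22\% carry an enhancer annotation; gene
#' region probabilities are expressed per probe, treating unannotated probes
#' as intergenic).
#'
#' @return A named list with elements `gene_region`, `island_relation` and
#'   `enhancer`, each a named probability vector summing to 1.
#' @export
default_region_freqs <- function() {
  gene <- c(
    TSS1500 = 73530, TSS200 = 55640, `5UTR` = 57408, FirstExon = 34391,
    Body = 148809, `3UTR` = 16571, Intergenic = 93342
  )
  island <- c(Island = 133415, Shore = 97243, Shelf = 37691, OpenSea = 139980)
  enh <- c(Enhancer = 90996, NonEnhancer = 317333)
  list(
    gene_region = gene / sum(gene),
    island_relation = island / sum(island),
    enhancer = enh / sum(enh)
  )
}

#' Default artifact rates for simulated studies
#'
#' Per-probe rates at which quality artifacts are planted so that every
#' probe-exclusion rule has work to do. Magnitudes follow the published 450K
#' annotation lists: about 0.7\% of probes target non-CpG cytosines, ~6\%
#' are cross-reactive (multi-mapping), a few percent overlap or sit within
#' 2 nt of a common SNP, ~2.4\% are on the sex chromosomes, and a small
#' fraction of probe measurements fail detection or have low bead counts.
#'
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
default_artifact_rates <- function() {
  c(
    non_cpg = 0.007,
    snp_aligned = 0.02,
    multi_mapping = 0.06,
    snp_proximal = 0.05,
    detection_fail = 0.005,
    low_bead = 0.002,
    sex_chromosome = 0.024
  )
}

#' Configuration for the synthetic 450K-style study generator
#'
#' Collects every knob of the simulator: problem size, the two-group design,
#' the fraction and effect size of truly differential probes, the beta-value
#' noise model, annotation-category frequencies and artifact rates.
#'
#' The beta-value noise model is a Beta distribution parameterised by
#' (mean, precision): a probe with latent group mean `mu` is observed as
#' `Beta(mu * phi, (1 - mu) * phi)` with `phi = beta_precision`, so the
#' observed mean is exactly `mu` and the within-group standard deviation is
#' `sqrt(mu * (1 - mu) / (1 + phi))` (about 0.05 at `mu = 0.5` for the
#' default `phi = 100`).
#'
#' @param n_probes Number of probes to simulate.
#' @param n_ref,n_case Sample sizes of the reference and case group.
#' @param dmc_fraction Fraction of probes that are truly differential.
#' @param true_delta Target absolute group-mean difference for differential
#'   probes, on the beta-value scale.
#' @param beta_precision Precision parameter `phi` of the Beta noise model.
#' @param hyper_fraction Fraction of truly differential probes shifted
#'   upwards in the case group (the remainder are shifted down).
#' @param region_freqs Annotation-category frequencies, as returned by
#'   [default_region_freqs()].
#' @param artifact_rates Artifact rates, as returned by
#'   [default_artifact_rates()].
#' @param seed Integer seed; one global seed drives a named sub-stream per
#'   generation stage, so a manifest generated alone is identical to one
#'   generated before a beta matrix.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_probes = 50000L,
                       n_ref = 12L,
                       n_case = 10L,
                       dmc_fraction = 0.05,
                       true_delta = 0.3,
                       beta_precision = 100,
                       hyper_fraction = 0.5,
                       region_freqs = default_region_freqs(),
                       artifact_rates = default_artifact_rates(),
                       seed = 1L) {
  chk_prop <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid configuration: '", field, "' must be a proportion in [0, 1]",
        call. = FALSE
      )
    }
  }
  chk_prop(dmc_fraction, "dmc_fraction")
  chk_prop(hyper_fraction, "hyper_fraction")
  if (!is.numeric(true_delta) || true_delta < 0 || true_delta > 0.9) {
    stop("invalid configuration: 'true_delta' must be in [0, 0.9]", call. = FALSE)
  }
  if (!is.numeric(beta_precision) || beta_precision <= 0) {
    stop("invalid configuration: 'beta_precision' must be positive", call. = FALSE)
  }
  if (n_probes < 0) {
    stop("invalid configuration: 'n_probes' must be non-negative", call. = FALSE)
  }
  for (nm in names(region_freqs)) {
    p <- region_freqs[[nm]]
    if (any(p < 0) || any(p > 1)) {
      stop("invalid configuration: 'region_freqs$", nm,
        "' has entries outside [0, 1]",
        call. = FALSE
      )
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("invalid configuration: 'region_freqs$", nm,
        "' must sum to 1 (got ", format(sum(p), digits = 12), ")",
        call. = FALSE
      )
    }
  }
  for (nm in names(artifact_rates)) chk_prop(artifact_rates[[nm]], paste0("artifact_rates[", nm, "]"))
  structure(
    list(
      n_probes = as.integer(n_probes), n_ref = as.integer(n_ref),
      n_case = as.integer(n_case), dmc_fraction = dmc_fraction,
      true_delta = true_delta, beta_precision = beta_precision,
      hyper_fraction = hyper_fraction, region_freqs = region_freqs,
      artifact_rates = artifact_rates, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic per-stage sub-seed derived from the global seed, kept below
# 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483629)
}
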