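# Eight probes: one violating each exclusion rule plus one clean probe.
toy_filter_fixture <- function() {
  man <- rbind(
    manifest_row("cg0000001"), # clean
    manifest_row("ch.1.0000002", target_is_cpg = FALSE),
    manifest_row("cg0000003", snp_at_target = TRUE),
    manifest_row("cg0000004", multi_mapping = TRUE),
    manifest_row("cg0000005", snp_distance = 2L, snp_maf = 0.2),
    manifest_row("cg0000006"), # detection failure planted in matrix
    manifest_row("cg0000007"), # low bead count planted in matrix
    manifest_row("cg0000008", chrom = "X")
  )
  n <- nrow(man)
  beta <- matrix(0.5, n, 4, dimnames = list(man$IlmnID, c("N.01", "N.02", "T.01", "T.02")))
  detp <- matrix(0.001, n, 4, dimnames = dimnames(beta))
  beads <- matrix(10L, n, 4, dimnames = dimnames(beta))
  detp["cg0000006", 2] <- 0.02
  beads["cg0000007", 3] <- 2L
  study <- beta_study(beta, detp, beads,
    samples = data.frame(
      sample_id = colnames(beta),
      group = c("NDF", "NDF", "TDF", "TDF"), stringsAsFactors = FALSE
    ),
    ref_group = "NDF", case_group = "TDF"
  )
  list(study = study, manifest = man)
}

test_that("each exclusion rule removes exactly its offender", {
  fx <- toy_filter_fixture()
  res <- filter_probes(fx$study, fx$manifest)
  expect_identical(res$retained, "cg0000001")
  expect_equal(res$ledger$input_count, 8L)
  expect_equal(res$ledger$retained_count, 1L)
  expect_true(all(res$ledger$excluded == 1L))
  # ledger invariant: retained + excluded = input
  expect_equal(res$ledger$retained_count + sum(res$ledger$excluded), res$ledger$input_count)
})

test_that("threshold boundaries are strict", {
  # MAF exactly at the threshold is retained (must exceed 0.05)
  man <- rbind(
    manifest_row("cg0000001", snp_distance = 2L, snp_maf = 0.05),
    manifest_row("cg0000002", snp_distance = 2L, snp_maf = 0.0500001),
    manifest_row("cg0000003", snp_distance = 3L, snp_maf = 0.4)
  )
  st <- make_study(
    matrix(0.5, 3, 2, dimnames = list(man$IlmnID, NULL)),
    matrix(0.5, 3, 2)
  )
  res <- filter_probes(st, man)
  expect_setequal(res$retained, c("cg0000001", "cg0000003"))

  # detection p exactly 0.01 in every sample is retained (rule is strict >)
  man2 <- rbind(manifest_row("cg0000001"), manifest_row("cg0000002"))
  detp <- matrix(0.01, 2, 4)
  detp[2, 4] <- 0.0100001
  st2 <- make_study(
    matrix(0.5, 2, 2, dimnames = list(man2$IlmnID, NULL)),
    matrix(0.5, 2, 2),
    detp = detp
  )
  res2 <- filter_probes(st2, man2)
  expect_identical(res2$retained, "cg0000001")

  # bead count exactly 3 passes, 2 fails
  beads <- matrix(3L, 2, 4)
  beads[2, 1] <- 2L
  st3 <- make_study(
    matrix(0.5, 2, 2, dimnames = list(man2$IlmnID, NULL)),
    matrix(0.5, 2, 2),
    beads = beads
  )
  expect_identical(filter_probes(st3, man2)$retained, "cg0000001")
})

test_that("filtering is idempotent and chromosome labels are normalised", {
  cfg <- sim_config(n_probes = 3000L, seed = 21L)
  sim <- simulate_study(cfg)
  res <- filter_probes(sim$study, sim$manifest)
  res2 <- filter_probes(res$study, res$manifest)
  expect_identical(res2$retained, res$retained)
  expect_true(all(res2$ledger$excluded == 0L))

  man <- rbind(
    manifest_row("cg0000001", chrom = "chrX"),
    manifest_row("cg0000002", chrom = "y"),
    manifest_row("cg0000003", chrom = "chr1")
  )
  st <- make_study(
    matrix(0.5, 3, 2, dimnames = list(man$IlmnID, NULL)),
    matrix(0.5, 3, 2)
  )
  expect_identical(filter_probes(st, man)$retained, "cg0000003")
})

test_that("per-rule exclusion counts match planted artifact rates", {
  cfg <- sim_config(n_probes = 20000L, seed = 31L)
  sim <- simulate_study(cfg)
  res <- filter_probes(sim$study, sim$manifest)
  rates <- cfg$artifact_rates
  n <- cfg$n_probes
  # first-match attribution: rule r catches ~ n * rate_r * prod(1 - earlier)
  survive <- 1
  for (rule in c(
    "non_cpg", "snp_aligned", "multi_mapping", "snp_proximal",
    "detection_fail", "low_bead", "sex_chromosome"
  )) {
    ledger_key <- switch(rule,
      detection_fail = "detection_p", low_bead = "bead_count", rule
    )
    expected <- n * rates[[rule]] * survive
    se <- sqrt(expected)
    expect_lt(
      abs(res$ledger$excluded[[ledger_key]] - expected), 4 * se + 3
    )
    survive <- survive * (1 - rates[[rule]])
  }
})

test_that("probe id mismatches are reported", {
  fx <- toy_filter_fixture()
  man <- fx$manifest[-1, ]
  expect_error(filter_probes(fx$study, man), "cg0000001")
})
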