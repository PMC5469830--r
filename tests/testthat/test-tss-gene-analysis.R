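tx_fixture <- function() {
  data.frame(
    transcript_id = c("tx1", "tx2", "tx3", "tx4"),
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("1", "1", "1", "2"),
    strand = c("+", "-", "+", "+"),
    tss = c(10000L, 10400L, 50000L, 10000L),
    stringsAsFactors = FALSE
  )
}

test_that("TSS window mapping is boundary-inclusive and strand-aware", {
  tx <- tx_fixture()
  dmcs <- data.frame(
    probe_id = c("cg1", "cg2", "cg3"),
    chrom = c("1", "1", "1"),
    pos = c(11500L, 11501L, 10248L), # 1500 / 1501 nt from tx1 TSS
    stringsAsFactors = FALSE
  )
  m <- map_dmcs_to_tss(dmcs, tx)
  expect_true("cg1" %in% m$probe_id[m$transcript_id == "tx1"])
  expect_false("cg2" %in% m$probe_id[m$transcript_id == "tx1"])
  expect_equal(m$distance[m$probe_id == "cg1" & m$transcript_id == "tx1"], 1500L)

  # minus-strand transcript with TSS 152 nt above the probe: probe sits in
  # the transcribed direction, so the strand-aware signed distance is +152
  m3 <- m[m$probe_id == "cg3" & m$transcript_id == "tx2", ]
  expect_equal(m3$distance, 152L)
  # same probe is downstream-of-TSS (positive) for tx1 on the plus strand
  expect_equal(m$distance[m$probe_id == "cg3" & m$transcript_id == "tx1"], 248L)
  # nearest flag marks the closer transcript
  expect_true(m3$is_nearest)

  # upstream on the plus strand is negative
  dmcs_up <- data.frame(probe_id = "cg4", chrom = "1", pos = 9900L, stringsAsFactors = FALSE)
  m4 <- map_dmcs_to_tss(dmcs_up, tx)
  expect_equal(m4$distance[m4$transcript_id == "tx1"], -100L)

  expect_equal(nrow(map_dmcs_to_tss(dmcs[0, ], tx)), 0L)
  tx_bad <- tx
  tx_bad$strand[4] <- "*"
  expect_warning(map_dmcs_to_tss(dmcs, tx_bad), "unknown strand")
})

test_that("mapping agrees with a brute-force all-pairs scan", {
  set.seed(404)
  tx <- data.frame(
    transcript_id = sprintf("tx%03d", 1:300),
    gene_id = sprintf("g%03d", sample(1:100, 300, replace = TRUE)),
    chrom = sample(c("1", "2"), 300, replace = TRUE),
    strand = sample(c("+", "-"), 300, replace = TRUE),
    tss = sample(1:200000, 300),
    stringsAsFactors = FALSE
  )
  dmcs <- data.frame(
    probe_id = sprintf("cg%04d", 1:500),
    chrom = sample(c("1", "2"), 500, replace = TRUE),
    pos = sample(1:200000, 500),
    stringsAsFactors = FALSE
  )
  m <- map_dmcs_to_tss(dmcs, tx, window = 1500L)
  brute <- do.call(rbind, lapply(seq_len(nrow(dmcs)), function(i) {
    hits <- which(tx$chrom == dmcs$chrom[i] & abs(tx$tss - dmcs$pos[i]) <= 1500L)
    if (!length(hits)) {
      return(NULL)
    }
    data.frame(probe_id = dmcs$probe_id[i], transcript_id = tx$transcript_id[hits])
  }))
  got <- paste(m$probe_id, m$transcript_id)
  want <- paste(brute$probe_id, brute$transcript_id)
  expect_setequal(got, want)
})

test_that("gene collapse keeps both directions and counts consistently", {
  mapping <- data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    gene_id = c("gA", "gA", "gB", "gC", "gC"),
    distance = 0L, is_nearest = TRUE,
    stringsAsFactors = FALSE
  )
  dirs <- c(cg1 = "hyper", cg2 = "hypo", cg3 = "hyper", cg4 = "hypo", cg5 = "hypo")
  g <- collapse_to_genes(mapping, dirs)
  expect_setequal(g$all, c("gA", "gB", "gC"))
  expect_setequal(g$hyper, c("gA", "gB"))
  expect_setequal(g$hypo, c("gA", "gC"))
  # hyper + hypo >= all, equality iff no gene carries both directions
  expect_gte(length(g$hyper) + length(g$hypo), length(g$all))

  g0 <- collapse_to_genes(mapping[0, ], dirs)
  expect_equal(attr(g0, "counts"), c(all = 0L, hyper = 0L, hypo = 0L))
})

test_that("hypergeometric tail matches exact combinatorics", {
  uni <- sprintf("g%02d", 1:10)
  res <- overrepresentation_test(uni[1:4], uni[1:5], uni)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  # zero overlap with a tiny set can never beat chance: p = 1 only when
  # the observed overlap cannot be below its minimum
  res0 <- overrepresentation_test(uni[6:10], uni[1:2], uni)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p_value, 1)

  expect_equal(overrepresentation_test(character(), uni[1:3], uni)$p_value, 1)
  expect_error(overrepresentation_test("gX", uni[1:3], uni), "subset")
})

test_that("hypergeometric tail equals exhaustive enumeration (universe <= 15)", {
  set.seed(505)
  for (rep in 1:10) {
    N <- sample(8:15, 1)
    uni <- sprintf("g%02d", seq_len(N))
    set <- sample(uni, sample(2:(N - 2), 1))
    n_sel <- sample(2:min(7, N - 1), 1)
    sel <- sample(uni, n_sel)
    k <- length(intersect(sel, set))
    combos <- utils::combn(N, n_sel)
    in_set <- seq_len(N) %in% match(set, uni)
    tail_p <- mean(colSums(matrix(in_set[combos], nrow = n_sel)) >= k)
    got <- overrepresentation_test(sel, set, uni)$p_value
    expect_equal(got, tail_p, tolerance = 1e-12)
  }
})

test_that("over-representation analysis adjusts across sets", {
  uni <- sprintf("g%02d", 1:20)
  sets <- list(S1 = uni[1:5], S2 = uni[6:10], S3 = uni[1:10])
  res <- overrepresentation_analysis(uni[1:5], sets, uni)
  expect_equal(res$adjusted_p, bh_adjust(res$p_value))
  expect_equal(res$overlap[res$set_id == "S1"], 5L)
})

test_that("GMT round trip preserves sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c(
    "S1\tfirst set\tgA\tgB\tgC",
    "S2\tsecond set\tgB\tgD"
  ), path)
  sets <- read_gmt(path)
  expect_setequal(sets$S1, c("gA", "gB", "gC"))
  expect_setequal(sets$S2, c("gB", "gD"))
})
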