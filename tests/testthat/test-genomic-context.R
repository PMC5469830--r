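# One island on chromosome 1 covering 0-based [10000, 10500), i.e. 1-based
# positions 10001..10500.
one_island <- data.frame(chrom = "1", start = 10000L, end = 10500L)

test_that("island/shore/shelf boundaries follow the distance definition", {
  # positions below are 0-based genomic offsets; MAPINFO is 1-based
  pos0 <- c(10250, 9000, 6000, 5999, 10500, 9999, 14499, 14500)
  expected <- c(
    "Island", # inside
    "Shore", # 1000 nt upstream of start
    "Shelf", # exactly 4000 nt away: closed shelf edge
    "OpenSea", # 4001 nt away
    "Shore", # first base after the island: distance 1
    "Shore", # base before the island: distance 1
    "Shelf", # 4000 nt downstream of end
    "OpenSea" # 4001 nt downstream
  )
  ctx <- assign_island_context(rep("1", length(pos0)), pos0 + 1L, one_island)
  expect_equal(ctx$island_relation, expected)
  expect_equal(ctx$island_distance[1], 0L)
  expect_equal(ctx$island_distance[2], 1000L)
  expect_equal(ctx$island_distance[3], 4000L)
  expect_equal(ctx$island_distance[4], 4001L)
})

test_that("island context matches a brute-force all-islands scan", {
  set.seed(202)
  islands <- data.frame(
    chrom = sample(c("1", "2"), 40, replace = TRUE),
    start = sort(sample(seq(0, 500000, by = 1000), 40))
  )
  islands$end <- islands$start + sample(200:900, 40, replace = TRUE)
  probes <- data.frame(
    chrom = sample(c("1", "2", "3"), 1000, replace = TRUE),
    pos = sample(1:510000, 1000)
  )
  brute <- vapply(seq_len(nrow(probes)), function(i) {
    isl <- islands[islands$chrom == probes$chrom[i], , drop = FALSE]
    if (nrow(isl) == 0L) {
      return("OpenSea")
    }
    q <- probes$pos[i] - 1L # 0-based
    inside <- any(q >= isl$start & q < isl$end)
    if (inside) {
      return("Island")
    }
    d <- pmin(
      ifelse(q < isl$start, isl$start - q, Inf),
      ifelse(q >= isl$end, q - isl$end + 1L, Inf)
    )
    d <- min(d)
    if (d <= 2000) "Shore" else if (d <= 4000) "Shelf" else "OpenSea"
  }, character(1))
  ctx <- assign_island_context(probes$chrom, probes$pos, islands)
  expect_equal(ctx$island_relation, brute)
})

test_that("islands inherit intragenic status from any annotated member probe", {
  islands <- data.frame(
    chrom = c("1", "1", "2"),
    start = c(1000L, 20000L, 1000L),
    end = c(2000L, 21000L, 2000L)
  )
  man <- rbind(
    # island 1: five unannotated probes -> intergenic
    do.call(rbind, lapply(1:5, function(i) {
      manifest_row(sprintf("cg000000%d", i), chrom = "1", pos = 1000L + i * 10L)
    })),
    # island 2: four unannotated + one Body-annotated probe -> intragenic
    do.call(rbind, lapply(6:9, function(i) {
      manifest_row(sprintf("cg000000%d", i), chrom = "1", pos = 20000L + i * 10L)
    })),
    manifest_row("cg0000010", chrom = "1", pos = 20500L, gene = "GX", region = "Body")
  )
  expect_warning(res <- classify_island_genic(islands, man), "no probe")
  expect_equal(res$island_genic[1], "intergenic")
  expect_equal(res$island_genic[2], "intragenic")
  expect_true(is.na(res$island_genic[3])) # probe-less island

  empty <- classify_island_genic(islands[0, ], man)
  expect_equal(nrow(empty), 0L)
})

test_that("context assignment propagates island genic status to probes", {
  islands <- data.frame(chrom = "1", start = c(1000L, 20000L), end = c(2000L, 21000L))
  man <- rbind(
    manifest_row("cg0000001", chrom = "1", pos = 1500L), # intergenic island
    manifest_row("cg0000002", chrom = "1", pos = 20500L, gene = "GX", region = "Body"),
    manifest_row("cg0000003", chrom = "1", pos = 50000L) # open sea
  )
  ctx <- assign_context(man, islands = islands)
  expect_equal(ctx$island_genic, c("intergenic", "intragenic", "not_in_island"))
  expect_equal(
    ctx$island_genic != "not_in_island",
    ctx$island_relation == "Island"
  )
})

test_that("count_by_region tallies multi-annotations and partitions", {
  man <- rbind(
    manifest_row("cg0000001", region = "TSS200;FirstExon", island = "Island"),
    manifest_row("cg0000002", region = "Body", island = "N_Shore", enhancer = TRUE),
    manifest_row("cg0000003", region = "", island = ""),
    manifest_row("cg0000004", region = "Body;Body", island = "S_Shelf")
  )
  ctx <- assign_context(man)
  dmc <- data.frame(
    probe_id = man$IlmnID,
    is_dmc = c(TRUE, TRUE, FALSE, FALSE),
    direction = c("hyper", "hypo", "none", "none"),
    stringsAsFactors = FALSE
  )
  counts <- count_by_region(ctx, dmc)
  gene <- counts[counts$block == "gene_region", ]
  # cg1 contributes to TSS200 and FirstExon; totals exceed probe count
  expect_equal(gene$dmc_count[gene$category == "TSS200"], 1L)
  expect_equal(gene$dmc_count[gene$category == "FirstExon"], 1L)
  expect_equal(sum(gene$analysed_count), 6L) # 2 + 1 + 1(intergenic) + 2
  expect_equal(gene$analysed_count[gene$category == "Intergenic"], 1L)

  isl <- counts[counts$block == "island", ]
  expect_equal(sum(isl$analysed_count), 4L) # partition of probes
  expect_equal(sum(isl$dmc_count), 2L)

  enh <- counts[counts$block == "enhancer", ]
  expect_equal(sum(enh$analysed_count), 4L)
  expect_equal(enh$analysed_count[enh$category == "Enhancer"], 1L)

  expect_error(
    count_by_region(ctx[-1, ], dmc),
    "lack context"
  )
})

test_that("manifest island-relation strings normalise across dialects", {
  expect_equal(
    normalize_island_relation(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "", "open sea", NA)),
    c("Island", "Shore", "Shore", "Shelf", "Shelf", "OpenSea", "OpenSea", "OpenSea")
  )
  expect_error(normalize_island_relation("promontory"), "unrecognised")
})
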