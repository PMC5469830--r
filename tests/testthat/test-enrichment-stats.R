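test_that("DMC-vs-background table subtracts DMCs from the analysed column", {
  t <- dmc_vs_background_table(192, 5302, 55640, 479691)
  expect_equal(unlist(t[c("a", "b", "c", "d")], use.names = FALSE),
    c(192, 5110, 55448, 418941))
  expect_equal(signif(odds_ratio(t), 4), 0.2839)

  t2 <- dmc_vs_background_table(682, 5302, 73530, 479691)
  expect_equal(signif(odds_ratio(t2), 4), 0.8137)

  t0 <- dmc_vs_background_table(0, 100, 500, 10000)
  expect_equal(odds_ratio(t0), 0)
  expect_true(attr(katz_ci(t0), "status") == "undefined")

  expect_error(dmc_vs_background_table(10, 5, 50, 100), "inconsistent")
  expect_error(dmc_vs_background_table(10, 20, 5, 100), "inconsistent")
})

test_that("odds ratio is the plain cross-product with explicit edge status", {
  expect_equal(odds_ratio(contingency_table(2, 3, 4, 5)), 10 / 12)
  expect_equal(odds_ratio(contingency_table(1, 1, 7, 7)), 1)
  expect_equal(signif(odds_ratio(contingency_table(637, 1611, 976, 1632)), 4), 0.6612)
  expect_true(is.infinite(odds_ratio(contingency_table(2, 0, 4, 5))))
  expect_true(is.nan(odds_ratio(contingency_table(0, 0, 4, 5))))
  # column swap inverts the ratio
  set.seed(33)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    tsw <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t) * odds_ratio(tsw), 1, tolerance = 1e-12)
  }
})

test_that("Katz interval brackets the OR and shrinks under scaling", {
  t <- contingency_table(192, 5110, 55448, 418941)
  ci <- katz_ci(t)
  expect_equal(signif(ci, 4), c(0.2457, 0.3280), ignore_attr = TRUE)

  ci2 <- katz_ci(contingency_table(637, 1611, 976, 1632))
  expect_equal(signif(ci2, 4), c(0.5857, 0.7464), ignore_attr = TRUE)

  sym <- katz_ci(contingency_table(10, 10, 10, 10))
  expect_lt(sym[1], 1)
  expect_gt(sym[2], 1)
  expect_equal(log(sym[2]), -log(sym[1]), tolerance = 1e-12)

  set.seed(44)
  for (i in 1:20) {
    cells <- sample(2:30, 4, replace = TRUE)
    t <- do.call(contingency_table, as.list(cells))
    or <- odds_ratio(t)
    ci <- katz_ci(t)
    expect_lt(ci[1], or)
    expect_gt(ci[2], or)
    # scaling every cell by k narrows the interval
    tk <- do.call(contingency_table, as.list(cells * 4))
    cik <- katz_ci(tk)
    expect_lt(diff(log(cik)), diff(log(ci)))
  }
})

test_that("Yates chi-square matches its closed form and stats::chisq.test", {
  t <- contingency_table(173, 5129, 16398, 457991)
  expect_equal(round(yates_chisq(t)$p_value, 4), 0.4652)

  # independence: ad = bc gives p = 1
  expect_equal(yates_chisq(contingency_table(2, 4, 3, 6))$p_value, 1)

  set.seed(99)
  for (i in 1:250) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    t <- do.call(contingency_table, as.list(cells))
    ours <- yates_chisq(t)
    oracle <- suppressWarnings(
      stats::chisq.test(matrix(c(cells[1], cells[3], cells[2], cells[4]), 2), correct = TRUE)
    )
    expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-10)
    # the correction never increases the statistic
    uncorr <- suppressWarnings(
      stats::chisq.test(matrix(c(cells[1], cells[3], cells[2], cells[4]), 2), correct = FALSE)
    )
    expect_lte(ours$statistic, unname(uncorr$statistic) + 1e-12)
  }

  expect_warning(p0 <- yates_chisq(contingency_table(0, 0, 5, 5)), "zero margin")
  expect_equal(p0$p_value, 1)
})

test_that("goodness-of-fit test behaves across its cases", {
  # observed proportional to expected: p = 1
  gof <- goodness_of_fit_distribution(c(10, 20, 30), c(100, 200, 300))
  expect_equal(gof$p_value, 1)
  expect_equal(gof$df, 2L)

  # two categories: equals the 2x2 chi-square without continuity correction
  obs <- c(40, 60)
  exp_counts <- c(500, 500)
  gof2 <- goodness_of_fit_distribution(obs, exp_counts)
  oracle <- stats::chisq.test(obs, p = exp_counts / sum(exp_counts), correct = FALSE)
  expect_equal(gof2$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(gof2$p_value, oracle$p.value, tolerance = 1e-12)

  expect_warning(
    gof3 <- goodness_of_fit_distribution(c(5, 5, 0), c(10, 10, 0)),
    "zero expectation"
  )
  expect_equal(gof3$df, 1L)
})

test_that("table builders produce coherent reports on synthetic fixtures", {
  # planted enrichment: DMCs concentrated in the enhancer category
  ctx <- assign_context(rbind(
    do.call(rbind, lapply(1:40, function(i) {
      manifest_row(sprintf("cgE%04d", i), enhancer = i <= 20, island = "Island", region = "Body")
    }))
  ))
  dmc <- data.frame(
    probe_id = ctx$probe_id,
    is_dmc = c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 3), rep(FALSE, 17)),
    direction = c(rep("hyper", 10), rep("hypo", 5), rep("none", 5),
                  rep("hypo", 3), rep("none", 17)),
    stringsAsFactors = FALSE
  )
  t1 <- build_table1(count_by_region(ctx, dmc))
  enh_row <- t1[t1$block == "enhancer" & t1$category == "Enhancer", ]
  expect_gt(enh_row$odds_ratio, 1)
  # island/enhancer percent columns sum to 100 within a partitioning block
  for (blk in c("island", "enhancer")) {
    rows <- t1[t1$block == blk, ]
    expect_equal(sum(rows$pct_dmc), 100)
    expect_equal(sum(rows$pct_background), 100)
  }

  t2 <- build_table2(dmc, ctx)
  with_dmcs <- t2[t2$total > 0, ]
  expect_equal(with_dmcs$pct_hyper + with_dmcs$pct_hypo, rep(100, nrow(with_dmcs)))
  # a category holding every hypo DMC but sharing hyper DMCs: finite checks
  expect_true(all(t2$status %in% c("ok", "undefined_or", "undefined_ci")))

  # all DMCs in one direction: ORs undefined, flagged not raised
  dmc_h <- dmc
  dmc_h$direction[dmc_h$is_dmc] <- "hyper"
  t2h <- build_table2(dmc_h, ctx)
  expect_true(all(t2h$status != "ok"))

  # no DMCs at all: empty report with warning
  dmc_none <- dmc
  dmc_none$is_dmc <- FALSE
  dmc_none$direction <- "none"
  expect_warning(t2e <- build_table2(dmc_none, ctx), "no DMCs")
  expect_equal(nrow(t2e), 0L)
})
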