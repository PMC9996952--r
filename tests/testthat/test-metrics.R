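toy_table <- function(counts, genes = NULL, samples = NULL) {
  m <- matrix(as.integer(counts), nrow = length(counts))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  count_table(m, genes, samples)
}

test_that("cpm scales columns to one million", {
  expect_equal(unname(cpm(toy_table(7L))[1, 1]), 1e6)
  two <- cpm(toy_table(c(25L, 75L)))
  expect_equal(unname(two[, 1]), c(250000, 750000))
  set.seed(61)
  m <- matrix(rpois(600, 40), 100, 6,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  expect_equal(unname(colSums(cpm(count_table(m)))), rep(1e6, 6),
               tolerance = 1e-9)
  bad <- count_table(matrix(c(1L, 0L), 1, 2,
                            dimnames = list("g", c("ok", "empty"))))
  err <- expect_error(cpm(bad), class = "ob_input_error")
  expect_match(conditionMessage(err), "empty")
})

test_that("subsampling is exact hypergeometric and conserves totals", {
  set.seed(62)
  m <- matrix(rpois(300, 200), 100, 3,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:3)))
  ct <- count_table(m)
  # full depth is the identity when depth equals each column total
  eq <- count_table(matrix(m[, 1], 100, 1, dimnames = list(rownames(m), "s1")))
  expect_identical(unclass(subsample_counts(eq, sum(m[, 1]), seed = 1)),
                   unclass(eq))
  zero <- subsample_counts(ct, 0, seed = 1)
  expect_true(all(unclass(zero) == 0L))
  sub <- subsample_counts(ct, 500, seed = 2)
  expect_equal(unname(colSums(unclass(sub))), rep(500, 3))
  err <- expect_error(subsample_counts(ct, 1e9), class = "ob_input_error")
  expect_match(conditionMessage(err), "s1")

  # expectation: gene at fraction 0.3, depth 1e4 from a 1e5 population
  pop <- toy_table(c(30000L, 70000L))
  draws <- vapply(1:100, function(s)
    unclass(subsample_counts(pop, 1e4, seed = s))[1, 1], integer(1))
  se <- sqrt(1e4 * 0.3 * 0.7 * (1e5 - 1e4) / (1e5 - 1)) / sqrt(100)
  expect_lt(abs(mean(draws) - 3000), 3 * se)
})

test_that("fold_reduction is a CPM ratio with continuity correction", {
  ct <- toy_table(c(100L, 900L))
  expect_equal(as.numeric(fold_reduction(ct, ct, "g1")), 1)
  ctrl <- toy_table(c(1000L, 999000L))
  trt <- toy_table(c(10L, 999990L))
  expect_equal(as.numeric(fold_reduction(ctrl, trt, "g1")), 100,
               tolerance = 1e-6)
  trt0 <- toy_table(c(0L, 1000L))
  fr <- fold_reduction(ctrl, trt0, "g1")
  expect_true(isTRUE(attr(fr, "corrected")))
  expect_gt(as.numeric(fr), 1)
  expect_error(fold_reduction(ctrl, trt, "nope"), class = "ob_input_error")
})

test_that("biotype fractions recover a planted composition", {
  ct <- toy_table(c(5L, 7L))
  expect_equal(unname(biotype_fractions(ct, c(g1 = "x", g2 = "x"))[1, 1]), 1)
  # planted composition at depth 5e6 (multinomial; mirrors a platelet-rich
  # plasma library where YRNA takes ~73% of reads)
  set.seed(63)
  p <- c(0.7316, 0.1724, 0.096)
  counts <- stats::rmultinom(1, 5e6, c(p[1], p[2] / 2, p[2] / 2, p[3]))
  ct2 <- count_table(matrix(counts, 4, 1,
                            dimnames = list(c("y1", "m1", "m2", "o1"), "S1")))
  bf <- biotype_fractions(ct2, c(y1 = "YRNA", m1 = "miRNA", m2 = "miRNA"))
  se <- sqrt(p * (1 - p) / 5e6)
  expect_lt(abs(bf["YRNA", 1] - 0.7316), 3 * se[1])
  expect_lt(abs(bf["miRNA", 1] - 0.1724), 3 * se[2])
  expect_equal(unname(colSums(bf)), 1, tolerance = 1e-12)
  expect_true("other" %in% rownames(bf))
  empty <- count_table(matrix(c(3L, 0L), 1, 2,
                              dimnames = list("y1", c("a", "b"))))
  expect_error(biotype_fractions(empty, c(y1 = "YRNA")),
               class = "ob_input_error")
})

test_that("detection thresholds follow the stated rules", {
  ct <- toy_table(c(10L, 9L, 0L))
  expect_identical(unname(detected_genes(ct, 10L)), 1L)  # >= is inclusive
  expect_identical(unname(detected_genes(toy_table(c(0L, 0L)))), 0L)
  set.seed(64)
  m <- matrix(rpois(500, 8), 100, 5,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:5)))
  ct2 <- count_table(m)
  got <- detected_genes(ct2, 10L)
  for (j in 1:5) {                                # brute-force filter oracle
    n <- 0L
    for (i in 1:100) if (m[i, j] >= 10L) n <- n + 1L
    expect_identical(unname(got[j]), n)
  }
  # CPM > 0.5, strict: a gene sitting exactly at CPM 0.5 is not detected
  big <- count_table(matrix(c(1L, 1999999L), 2, 1,
                            dimnames = list(c("half", "rest"), "S1")))
  det <- detect_features(big, 0.5)               # gene "half" sits at CPM 0.5
  expect_identical(det$S1, "rest")
})

test_that("de_test filters on summed RPM and is null-calibrated on self-comparison", {
  set.seed(65)
  m <- matrix(rpois(400, 60), 100, 4,
              dimnames = list(sprintf("g%d", 1:100), sprintf("r%d", 1:4)))
  a <- count_table(m[, 1:2] + 0L)
  res <- de_test(a, count_table(m[, 1:2] + 0L))   # identical groups
  expect_identical(sum(res$significant), 0L)

  # RPM filter boundary: total RPM ~9 is filtered, ~12 is kept
  base <- matrix(1000000L, 3, 4,
                 dimnames = list(c("bulk", "low", "keep"), sprintf("r%d", 1:4)))
  base["low", ] <- c(2L, 2L, 2L, 3L)     # summed RPM ~ 9 (colsums ~1e6)
  base["keep", ] <- c(3L, 3L, 3L, 3L)    # summed RPM ~ 12
  ga <- count_table(base[, 1:2]); gb <- count_table(base[, 3:4])
  res2 <- de_test(ga, gb, min_rpm = 10)
  expect_true(res2$filtered[res2$gene == "low"])
  expect_true(is.na(res2$p[res2$gene == "low"]))
  expect_false(res2$filtered[res2$gene == "keep"])
  expect_error(de_test(count_table(m[, 1, drop = FALSE]), a),
               class = "ob_input_error")
})

test_that("de_test recovers planted fold changes with controlled FDR", {
  stats <- vapply(1:20, function(s) {
    tg <- synth_two_group_counts(n_genes = 400, n_per_group = 4,
                                 frac_de = 0.1, log2fc = 2, depth = 1e6,
                                 seed = s)
    de <- de_test(tg$groupA, tg$groupB)
    sig <- de$gene[de$significant]
    truth <- tg$manifest$de_genes$gene
    c(tp = length(intersect(sig, truth)), fp = length(setdiff(sig, truth)),
      n_truth = length(truth))
  }, numeric(3))
  sensitivity <- sum(stats["tp", ]) / sum(stats["n_truth", ])
  fdr <- sum(stats["fp", ]) / max(1, sum(stats["tp", ] + stats["fp", ]))
  expect_gt(sensitivity, 0.5)
  expect_lte(fdr, 0.10)
})

test_that("concordance is 100% at full depth and degrades with subsampling", {
  tg <- synth_two_group_counts(n_genes = 300, n_per_group = 4, frac_de = 0.1,
                               log2fc = 2, depth = 2e5, seed = 8)
  full_depth <- min(colSums(unclass(tg$groupA)), colSums(unclass(tg$groupB)))
  cc_full <- de_concordance(tg$groupA, tg$groupB, depth = full_depth, seed = 1)
  expect_true(all(lengths(cc_full$sets) > 0))
  expect_equal(cc_full$concordance, 100)
  # subsampling at full depth is deterministic, so two subsamples agree too
  cc2 <- de_concordance(tg$groupA, tg$groupB, depth = full_depth,
                        n_subsamples = 2, seed = 99)
  expect_equal(cc2$concordance, 100)
  # shallow subsampling cannot beat full depth (mean over 10 seeds)
  shallow <- mean(vapply(1:10, function(s)
    de_concordance(tg$groupA, tg$groupB, depth = round(full_depth / 10),
                   seed = s)$concordance, numeric(1)))
  expect_lte(shallow, 100)
  expect_lt(shallow, 99.999)   # genuinely degraded, not the trivial bound
})

test_that("standardized-residual flagging requires consistency across all pairs", {
  dp <- synth_depletion_pair(list(n_genes = 300, depth = 2e6), efficiency = 0,
                             seed = 71)
  expect_identical(nrow(flag_offtarget_outliers(dp$control, dp$control)), 0L)

  sup <- synth_depletion_pair(list(n_genes = 300, depth = 2e6),
                              efficiency = 0.9, seed = 72,
                              offtarget_gene = "gene_0042",
                              offtarget_suppression = 8)
  fl <- flag_offtarget_outliers(sup$control, sup$treated)
  expect_true("gene_0042" %in% fl$gene)
  expect_identical(fl$direction[fl$gene == "gene_0042"], "lower")

  # suppression in a single replicate pair only must not flag
  ctrl <- dp$control
  trt <- unclass(dp$control)
  trt["gene_0042", 1] <- trt["gene_0042", 1] %/% 8L
  fl2 <- flag_offtarget_outliers(ctrl, count_table(trt))
  expect_false("gene_0042" %in% fl2$gene)
})
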