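kbCs <- function(lengthsKb) {
  bp <- round(lengthsKb * 1000)
  InversionCallset("s", rep("chr1", length(bp)),
                   seq(0, by = 1e7, length.out = length(bp)),
                   seq(0, by = 1e7, length.out = length(bp)) + bp)
}

test_that("length summary uses type-7 interpolated quartiles in kb", {
  s <- lengthSummary(kbCs(c(1, 2, 3, 4)))
  expect_equal(s$median_kb, 2.5)
  expect_equal(s$q1_kb, 1.75)
  expect_equal(s$q3_kb, 3.25)
  expect_equal(s$n, 4L)

  one <- lengthSummary(kbCs(7.5))
  expect_true(all(unlist(one[c("min_kb", "q1_kb", "median_kb", "mean_kb",
                               "q3_kb", "max_kb")]) == 7.5))

  const <- lengthSummary(kbCs(c(5, 5, 5)))
  expect_equal(const$mean_kb, 5); expect_equal(const$q1_kb, 5)
  expect_equal(const$q3_kb, 5)

  # alternative interpolation differs on this fixture
  s6 <- lengthSummary(kbCs(c(1, 2, 3, 4)), quantileType = 6)
  expect_equal(s6$q1_kb, 1.25)
  expect_error(lengthSummary(InversionCallset("e", character(), numeric(),
                                              numeric())), "empty")
})

test_that("exact Wilcoxon matches full enumeration and the normal mode tracks it", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact")$p_value, 1 / 3)

  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- runif(n); y <- runif(m) + runif(1, -0.5, 0.5)
    pexact <- wilcoxonRankSum(x, y, mode = "exact")$p_value
    expect_equal(pexact, enumWilcoxonP(x, y), tolerance = 1e-12)
    # independent cross-check against the stock implementation
    expect_equal(pexact, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # exact and normal approximations agree to ~0.02 at n = m = 7
  set.seed(6)
  for (rep in 1:10) {
    x <- runif(7); y <- runif(7)
    pe <- wilcoxonRankSum(x, y, mode = "exact")$p_value
    pn <- wilcoxonRankSum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  # identical samples: degenerate, p = 1 with a warning
  expect_warning(r <- wilcoxonRankSum(c(2, 2), c(2, 2)), "identical")
  expect_equal(r$p_value, 1)
  # same values, both samples: ties force normal mode, p near 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 0.05)
})

test_that("exact Wilcoxon null distribution conserves total probability", {
  counts <- inversionscape:::.uCounts(4, 5)
  expect_equal(sum(counts), choose(9, 4))
  counts2 <- inversionscape:::.uCounts(2, 2)
  expect_equal(counts2, c(1, 1, 2, 1, 1))
})

test_that("two-sided binomial test uses the small-P method", {
  expect_equal(binomialTest(2, 2, 0.5)$p_value, 0.5)
  expect_equal(binomialTest(0, 10, 0.5)$p_value, 2 / 1024)
  expect_equal(binomialTest(5, 10, 0.5)$p_value, 1)  # observed at the mode
  # cross-check against the stock implementation on a grid
  for (k in c(0, 3, 7, 12, 20)) {
    expect_equal(binomialTest(k, 20, 0.3)$p_value,
                 stats::binom.test(k, 20, 0.3)$p.value, tolerance = 1e-12)
  }
  expect_equal(binomialTest(1, 10, 0.5, alternative = "less")$p_value,
               sum(dbinom(0:1, 10, 0.5)))
  expect_error(binomialTest(11, 10, 0.5), "0..n")
})

test_that("Fisher exact matches hypergeometric enumeration and fisher.test", {
  expect_equal(fisherExact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  set.seed(9)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisherExact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisherExact(tab, "greater")$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up closed form and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(10)
  p <- runif(50)^2
  q <- bhAdjust(p)
  expect_equal(q, stats::p.adjust(p, "BH"))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
})

test_that("over-representation analysis ranks enriched sets and adjusts across sets", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(enriched = universe[1:10], cold = universe[51:60])
  hits <- universe[c(1:8, 90:95)]
  res <- overrepresentation(hits, sets, universe)
  expect_equal(res$overlap[res$gene_set == "enriched"], 8L)
  expect_equal(res$overlap[res$gene_set == "cold"], 0L)
  expect_lt(res$p_value[res$gene_set == "enriched"], 1e-4)
  # deficit direction: one-sided enrichment p is large
  expect_gte(res$p_value[res$gene_set == "cold"], 0.5)
  # against the closed form: upper hypergeometric tail
  expect_equal(res$p_value[res$gene_set == "enriched"],
               sum(dhyper(8:10, 10, 90, length(hits))), tolerance = 1e-12)
  expect_equal(res$q_value, bhAdjust(res$p_value)[order(res$p_value)])
  expect_error(overrepresentation(hits, sets, character()), "universe")
})

test_that("GMT reader returns named member lists", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), p)
  sets <- readGmt(p)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})

test_that("inheritance distribution counts distinct genes and tests AR vs background", {
  lv <- c("phenotype_linked", "cataloged_no_phenotype", "not_in_omim")
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:40), symbol = "s",
    omim_status = factor(rep("phenotype_linked", 40), levels = lv),
    inheritance_modes = rep(c("AR", "AD"), each = 20),
    orphanet_linked = FALSE, stringsAsFactors = FALSE)
  # 10 genes hit, 5 AR and 5 AD -> AR 50% vs background 50%: p close to 1
  rec <- data.frame(dataset = "d", inversion_id = paste0("i", 1:10),
                    gene_id = ann$gene_id[c(1:5, 21:25)],
                    category = factor("intragenic",
                                      levels = inversionscape:::INV_CATEGORIES),
                    stringsAsFactors = FALSE)
  d <- inheritanceDistribution(rec, ann, "intragenic")
  expect_equal(d$table$percent[d$table$mode == "AR"], 50)
  expect_equal(d$n_genes, 10L)
  expect_gt(d$ar_test$p_value, 0.5)
  expect_error(inheritanceDistribution(rec[0, ], ann), "phenotype-linked")
})

test_that("planted AR enrichment is detected in nearly all replicates", {
  # background AR proportion 0.25; hits over-sample AR genes twofold
  lv <- c("phenotype_linked", "cataloged_no_phenotype", "not_in_omim")
  nG <- 2000
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:nG), symbol = "s",
    omim_status = factor(rep("phenotype_linked", nG), levels = lv),
    inheritance_modes = rep(c("AR", "AD", "other", "XLR"), nG / 4),
    orphanet_linked = FALSE, stringsAsFactors = FALSE)
  isAR <- ann$inheritance_modes == "AR"
  set.seed(123)
  hitsSignif <- vapply(1:100, function(r) {
    w <- ifelse(isAR, 2, 1)
    hit <- sample(ann$gene_id, 300, prob = w)
    rec <- data.frame(dataset = "d", inversion_id = paste0("i", seq_along(hit)),
                      gene_id = hit,
                      category = factor("intragenic",
                                        levels = inversionscape:::INV_CATEGORIES),
                      stringsAsFactors = FALSE)
    inheritanceDistribution(rec, ann, "intragenic")$ar_test$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hitsSignif), 0.95)
})
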