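## toyGenes() geometry (1-based): gA chr1 [1001,2000] with introns
## [1201,1500] and [1701,1900]; gB chr1 [5001,5400] minus strand with intron
## [5101,5300]; gC chr1 [8001,8200] single exon; gD chr2 [1001,1600].

toyInvCallset <- function(...) {
  df <- rbind(...)
  InversionCallset("toy", df[, 1], as.numeric(df[, 2]), as.numeric(df[, 3]),
                   id = df[, 4])
}

test_that("the three categories follow breakpoint containment", {
  gm <- toyGenes()
  cs <- toyInvCallset(
    c("chr1", 900, 2100, "span"),       # covers gA, both breakpoints outside
    c("chr1", 1599, 2500, "disrupt"),   # first base 1600 inside gA, last outside
    c("chr1", 1250, 1400, "intra"))     # wholly inside intron 1 of gA
  rec <- classifyCallset(cs, gm)
  rec <- rec[rec$gene_id == "gA", ]
  expect_equal(rec$category[rec$inversion_id == "span"], factor("gene_spanning", levels = levels(rec$category)))
  expect_equal(as.character(rec$category[rec$inversion_id == "disrupt"]), "gene_disrupting")
  expect_equal(as.character(rec$category[rec$inversion_id == "intra"]), "intragenic")
  expect_equal(rec$breakpoints_in_gene[rec$inversion_id == "span"], 0L)
  expect_equal(rec$breakpoints_in_gene[rec$inversion_id == "disrupt"], 1L)
  expect_equal(rec$breakpoints_in_gene[rec$inversion_id == "intra"], 2L)
  expect_true(rec$single_intron[rec$inversion_id == "intra"])
  expect_equal(rec$disrupted_introns[rec$inversion_id == "intra"], "1")
})

test_that("boundary bases count as within the gene", {
  gm <- toyGenes()
  # first inverted base == gene's last base (1-based 2000)
  cs <- toyInvCallset(c("chr1", 1999, 2500, "edge"))
  rec <- classifyCallset(cs, gm)
  expect_equal(as.character(rec$category), "gene_disrupting")
  # first inverted base == gene's first base, last base beyond: one bp in
  cs2 <- toyInvCallset(c("chr1", 1000, 2500, "lead"))
  rec2 <- classifyCallset(cs2, gm)
  expect_equal(as.character(rec2$category), "gene_disrupting")
})

test_that("one inversion yields one record per overlapped gene, judged independently", {
  gm <- toyGenes()
  # breakpoints inside gA and gB respectively -> two gene_disrupting records
  two <- toyInvCallset(c("chr1", 1599, 5200, "two"))
  rec <- classifyCallset(two, gm)
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$gene_id, c("gA", "gB"))
  expect_true(all(rec$category == "gene_disrupting"))
  expect_true(all(rec$breakpoints_in_gene == 1L))

  # an inversion containing gA, gB and gC entirely -> three gene_spanning
  three <- toyInvCallset(c("chr1", 900, 8300, "three"))
  rec3 <- classifyCallset(three, gm)
  expect_equal(nrow(rec3), 3L)
  expect_true(all(rec3$category == "gene_spanning"))
})

test_that("classifyPair returns NULL without overlap and matches classifyCallset", {
  gm <- toyGenes()
  cs <- toyInvCallset(c("chr1", 2500, 3000, "nohit"), c("chr1", 1250, 1400, "hit"))
  expect_null(classifyPair(cs, gm, "nohit", "gA"))
  expect_null(classifyPair(cs, gm, "hit", "gD"))  # different chromosome
  one <- classifyPair(cs, gm, "hit", "gA")
  expect_equal(as.character(one$category), "intragenic")
})

test_that("intron context distinguishes single-intron containment from boundary crossing", {
  gm <- toyGenes()
  cs <- toyInvCallset(
    c("chr1", 1250, 1400, "single"),   # inside intron 1 of gA
    c("chr1", 1190, 1240, "crossing"), # exon 1 / intron 1 boundary at 1200
    c("chr1", 1250, 1750, "multi"))    # intron 1, exon 2, intron 2
  ctx1 <- intronContext(cs, gm, "single", "gA")
  expect_true(ctx1$single_intron)
  expect_equal(ctx1$introns_overlapped, 1L)
  expect_equal(ctx1$exons_overlapped, 0L)

  ctx2 <- intronContext(cs, gm, "crossing", "gA")
  expect_false(ctx2$single_intron)
  expect_gte(ctx2$exons_overlapped, 1L)

  ctx3 <- intronContext(cs, gm, "multi", "gA")
  expect_false(ctx3$single_intron)
  expect_equal(ctx3$disrupted_introns, c(1L, 2L))
  expect_equal(ctx3$exons_overlapped, 1L)

  span <- toyInvCallset(c("chr1", 900, 2100, "span"))
  expect_error(intronContext(span, gm, "span", "gA"), "not intragenic")
})

test_that("intron ordinals are 5'-to-3' in transcription orientation", {
  # minus-strand gene with two introns: genomic intron 1 is ordinal 2
  gm <- GeneModelSet("gE", "E", "chr1", "-",
                     exonStarts0 = list(c(20000, 20200, 20400)),
                     exonEnds0 = list(c(20100, 20300, 20500)))
  cs <- toyInvCallset(c("chr1", 20120, 20180, "minusIntron"))
  ctx <- intronContext(cs, gm, "minusIntron", "gE")
  expect_true(ctx$single_intron)
  expect_equal(ctx$disrupted_introns, 2L)
})

test_that("category distribution reports per-dataset percentages summing to 100", {
  rec <- data.frame(
    dataset = "d",
    inversion_id = sprintf("i%03d", 1:100),
    gene_id = "g",
    category = factor(c(rep("gene_spanning", 97), rep("gene_disrupting", 2),
                        "intragenic"), levels = inversionscape:::INV_CATEGORIES),
    stringsAsFactors = FALSE)
  dist <- categoryDistribution(rec)
  expect_equal(dist$percent, c(97, 2, 1))
  expect_equal(sum(dist$percent), 100)

  one <- categoryDistribution(rec[1, , drop = FALSE])
  expect_equal(one$percent[one$category == "gene_spanning"], 100)
  expect_error(categoryDistribution(rec[0, ]), "no intersection")
})

test_that("classification agrees with the all-pairs oracle and is a trichotomy", {
  u <- syntheticUniverse(seed = 19, nGenes = 60, nCalls = 150)
  rec <- classifyCallset(u$callset, u$genes)
  oracle <- bruteClassify(u$callset, u$genes)
  expect_equal(nrow(rec), nrow(oracle))
  key <- function(d) paste(d$inversion_id, d$gene_id)
  expect_setequal(key(rec), key(oracle))
  m <- match(key(oracle), key(rec))
  expect_equal(as.character(rec$category[m]), oracle$category)

  # every overlapping pair gets exactly one category; counts conserve
  expect_false(any(is.na(rec$category)))
  expect_equal(sum(table(rec$category)), nrow(rec))

  # geometric implications of the categories
  gr <- calls(u$callset); g <- genes(u$genes)
  qi <- match(rec$inversion_id, invIds(u$callset))
  si <- match(rec$gene_id, geneIds(u$genes))
  spanning <- rec$category == "gene_spanning"
  expect_true(all(GenomicRanges::start(gr)[qi][spanning] <= GenomicRanges::start(g)[si][spanning] &
                    GenomicRanges::end(gr)[qi][spanning] >= GenomicRanges::end(g)[si][spanning]))
  intra <- rec$category == "intragenic"
  expect_true(all(GenomicRanges::start(gr)[qi][intra] >= GenomicRanges::start(g)[si][intra] &
                    GenomicRanges::end(gr)[qi][intra] <= GenomicRanges::end(g)[si][intra]))
})
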