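## Brute-force oracles and small fixture builders. Everything here is
## independent of the package's indexed code paths: plain loops and plain
## arithmetic on coordinate vectors.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# random GRanges on a couple of chromosomes, 0-based half-open converted to
# the 1-based container convention
randomGRanges <- function(n, maxPos = 1e5, maxLen = 5e3,
                          chroms = c("chr1", "chr2")) {
  s0 <- floor(runif(n, 0, maxPos))
  len <- ceiling(runif(n, 1, maxLen))
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s0 + 1, s0 + len))
}

# all-pairs fractional-overlap scan (floating-point threshold deliberately
# avoided the same way: integer compare with f given as num/den)
bruteFractionPairs <- function(query, subject, num = 1, den = 2) {
  qc <- as.character(GenomicRanges::seqnames(query))
  sc <- as.character(GenomicRanges::seqnames(subject))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  out <- NULL
  for (i in seq_along(query)) {
    for (j in seq_along(subject)) {
      if (qc[i] != sc[j]) next
      ov <- min(qe[i], se[j]) - max(qs[i], ss[j]) + 1
      if (ov <= 0) next
      if (ov * den >= num * (qe[i] - qs[i] + 1)) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# all-pairs classification scan over a callset and gene set: for every pair
# with >= 1 bp overlap, count breakpoints (first/last inverted base) falling
# on gene bases and map 0/1/2 to the category
bruteClassify <- function(cs, gm) {
  gr <- calls(cs); g <- genes(gm)
  ic <- as.character(GenomicRanges::seqnames(gr)); gc <- as.character(GenomicRanges::seqnames(g))
  is_ <- GenomicRanges::start(gr); ie <- GenomicRanges::end(gr)
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  out <- NULL
  for (i in seq_along(gr)) {
    for (j in seq_along(g)) {
      if (ic[i] != gc[j]) next
      ov <- min(ie[i], ge[j]) - max(is_[i], gs[j]) + 1
      if (ov <= 0) next
      nbp <- sum(c(is_[i], ie[i]) >= gs[j] & c(is_[i], ie[i]) <= ge[j])
      out <- rbind(out, data.frame(
        inversion_id = invIds(cs)[i], gene_id = geneIds(gm)[j],
        category = c("gene_spanning", "gene_disrupting", "intragenic")[nbp + 1],
        stringsAsFactors = FALSE))
    }
  }
  out
}

# exact two-sided Wilcoxon p by explicit enumeration of every subset of
# ranks (utils::combn), nothing shared with the package's DP
enumWilcoxonP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(idx) - n * (n + 1) / 2)
  pl <- mean(us <= U); pu <- mean(us >= U)
  min(1, 2 * min(pl, pu))
}

# small deterministic gene fixture:
#   gA chr1 [1001, 2000] + exons [1001,1200],[1501,1700],[1901,2000]
#   gB chr1 [5001, 5400] - exons [5001,5100],[5301,5400]
#   gC chr1 [8001, 8200] + single exon
#   gD chr2 [1001, 1600] + exons [1001,1100],[1501,1600]
toyGenes <- function() {
  GeneModelSet(
    geneId = c("gA", "gB", "gC", "gD"),
    symbol = c("A", "B", "C", "D"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "-", "+", "+"),
    exonStarts0 = list(c(1000, 1500, 1900), c(5000, 5300), 8000, c(1000, 1500)),
    exonEnds0 = list(c(1200, 1700, 2000), c(5100, 5400), 8200, c(1100, 1600)))
}

toyAnnotations <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    symbol = c("A", "B", "C", "D"),
    omim_status = factor(c("phenotype_linked", "phenotype_linked",
                           "cataloged_no_phenotype", "not_in_omim"),
                         levels = c("phenotype_linked", "cataloged_no_phenotype",
                                    "not_in_omim")),
    inheritance_modes = c("AR", "AD,AR", "", ""),
    orphanet_linked = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# standard synthetic universe used by several planted-truth tests
syntheticUniverse <- function(seed = 11L, nGenes = 120L, nCalls = 400L,
                              planted = c(gene_spanning = 15, gene_disrupting = 15,
                                          intragenic = 15, intragenic_single_intron = 15)) {
  genome <- makeGenome(2, 1e7, seed)
  sim <- makeGenes(genome, nGenes, seed = seed)
  prof <- gnomadLikeProfile(nCalls)
  res <- makeCallset(prof, sim$genes, genome, planted = planted, seed = seed + 1L)
  list(genome = genome, genes = sim$genes, annotations = sim$annotations,
       callset = res$callset, truth = res$truth)
}
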