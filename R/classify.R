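## Core of the three-way inversion-gene classification.
##
## An inversion's breakpoints are operationalized as its first and last
## inverted base. For a given gene, a breakpoint is "within" the gene when it
## falls on any base of the gene span (closed containment at base level,
## boundary bases included). Per overlapping (inversion, gene) pair:
##   both breakpoints within the gene  -> intragenic   (inversion inside gene)
##   exactly one within                -> gene_disrupting
##   none within, overlap > 0          -> gene_spanning (gene inside inversion)
## The three cases are exhaustive and mutually exclusive for any pair with
## positive overlap, and each implies the containment noted in parentheses.

.intronExonContext <- function(s, e, exonsIR, strandChar) {
  nEx <- length(exonsIR)
  exOv <- sum(pmin(e, IRanges::end(exonsIR)) - pmax(s, IRanges::start(exonsIR)) + 1 > 0)
  if (nEx < 2L) {
    return(list(introns_overlapped = 0L, exons_overlapped = exOv,
                single_intron = FALSE, disrupted_introns = integer()))
  }
  inS <- IRanges::end(exonsIR)[-nEx] + 1
  inE <- IRanges::start(exonsIR)[-1] - 1
  hit <- which(pmin(e, inE) - pmax(s, inS) + 1 > 0)
  single <- any(inS <= s & e <= inE)
  nIn <- nEx - 1L
  ord <- if (identical(strandChar, "-")) nIn + 1L - hit else hit
  list(introns_overlapped = length(hit), exons_overlapped = exOv,
       single_intron = single, disrupted_introns = sort(ord))
}

.classifyPairsCore <- function(cs, gm, qIdx, sIdx) {
  gr <- calls(cs); g <- genes(gm); ex <- exons(gm)
  s <- GenomicRanges::start(gr)[qIdx]; e <- GenomicRanges::end(gr)[qIdx]
  gs <- GenomicRanges::start(g)[sIdx]; ge <- GenomicRanges::end(g)[sIdx]
  bpFirst <- gs <= s & s <= ge
  bpLast <- gs <= e & e <= ge
  nBp <- as.integer(bpFirst) + as.integer(bpLast)
  category <- c("gene_spanning", "gene_disrupting", "intragenic")[nBp + 1L]

  n <- length(qIdx)
  intronsOv <- integer(n); exonsOv <- integer(n)
  single <- rep(NA, n); disrupted <- character(n)
  strandChr <- as.character(strand(g))
  for (k in seq_len(n)) {
    ctx <- .intronExonContext(s[k], e[k], ex[[sIdx[k]]], strandChr[sIdx[k]])
    intronsOv[k] <- ctx$introns_overlapped
    exonsOv[k] <- ctx$exons_overlapped
    if (category[k] == "intragenic") {
      single[k] <- ctx$single_intron
      disrupted[k] <- paste(ctx$disrupted_introns, collapse = ",")
    }
  }
  data.frame(
    dataset = datasetLabel(cs),
    inversion_id = invIds(cs)[qIdx],
    gene_id = mcols(g)$gene_id[sIdx],
    category = factor(category, levels = INV_CATEGORIES),
    breakpoints_in_gene = nBp,
    introns_overlapped = intronsOv,
    exons_overlapped = exonsOv,
    single_intron = as.logical(single),
    disrupted_introns = disrupted,
    stringsAsFactors = FALSE)
}

#' Classify one inversion-gene pair
#'
#' Returns the pair's intersection record (category plus intron/exon
#' context), or NULL when the inversion and the gene do not overlap.
#'
#' @param cs an \linkS4class{InversionCallset}.
#' @param gm a \linkS4class{GeneModelSet}.
#' @param invId,geneId ids selecting the pair.
#' @return one-row data.frame (see \code{\link{classifyCallset}}) or NULL.
#' @export
classifyPair <- function(cs, gm, invId, geneId) {
  qi <- match(invId, invIds(cs)); si <- match(geneId, geneIds(gm))
  .assert(!is.na(qi), sprintf("unknown inversion id '%s'", invId))
  .assert(!is.na(si), sprintf("unknown gene id '%s'", geneId))
  gr <- calls(cs)[qi]; g <- genes(gm)[si]
  ov <- overlapLength(GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                      GenomicRanges::start(g) - 1, GenomicRanges::end(g),
                      seqnames(gr), seqnames(g))
  if (ov == 0) return(NULL)
  .classifyPairsCore(cs, gm, qi, si)
}

#' Classify every overlapping inversion-gene pair in a callset
#'
#' Finds all (inversion, gene) pairs with >= 1 bp overlap and assigns each
#' pair one of the three categories: \code{gene_spanning} (gene fully inside
#' the inversion, neither breakpoint in the gene), \code{gene_disrupting}
#' (exactly one breakpoint inside the gene) or \code{intragenic} (both
#' breakpoints inside the gene, i.e. inversion contained in the gene). An
#' inversion overlapping several genes yields one record per gene, judged
#' independently — an inversion with its two breakpoints in two different
#' genes produces two gene_disrupting records.
#'
#' @param cs an \linkS4class{InversionCallset}.
#' @param gm a \linkS4class{GeneModelSet}.
#' @return data.frame with one row per overlapping pair: dataset,
#'   inversion_id, gene_id, category, breakpoints_in_gene,
#'   introns_overlapped, exons_overlapped, single_intron (NA unless
#'   intragenic), disrupted_introns (comma-joined 5'-to-3' intron ordinals;
#'   "" unless intragenic).
#' @export
classifyCallset <- function(cs, gm) {
  hits <- findOverlaps(calls(cs), genes(gm), ignore.strand = TRUE)
  .classifyPairsCore(cs, gm, queryHits(hits), subjectHits(hits))
}

#' Intron/exon context of an intragenic inversion
#'
#' For an intragenic (inversion, gene) pair, reports how many intron and
#' exon blocks of the canonical transcript the inversion overlaps, whether it
#' is wholly contained in a single intron, and the ordinals (5' to 3' in
#' transcription orientation) of the introns it touches. Calling this on a
#' non-intragenic pair is a hard error.
#'
#' @inheritParams classifyPair
#' @return list(introns_overlapped, exons_overlapped, single_intron,
#'   disrupted_introns).
#' @export
intronContext <- function(cs, gm, invId, geneId) {
  rec <- classifyPair(cs, gm, invId, geneId)
  .assert(!is.null(rec) && rec$category == "intragenic",
          sprintf("pair (%s, %s) is not intragenic", invId, geneId))
  si <- match(geneId, geneIds(gm))
  qi <- match(invId, invIds(cs))
  .intronExonContext(GenomicRanges::start(calls(cs))[qi],
                     GenomicRanges::end(calls(cs))[qi],
                     exons(gm)[[si]], as.character(strand(genes(gm)))[si])
}

#' Distribution of intersection records over the three categories
#'
#' @param records data.frame from \code{\link{classifyCallset}} (possibly
#'   several datasets row-bound).
#' @param perDataset when TRUE (default) percentages are computed within
#'   each dataset's records; when FALSE, over all records pooled.
#' @return data.frame with columns dataset (absent when pooled), category,
#'   n, percent; percentages within each dataset sum to 100 up to rounding.
#' @export
categoryDistribution <- function(records, perDataset = TRUE) {
  .assert(nrow(records) > 0L, "no intersection records to summarize")
  one <- function(df, label = NULL) {
    tab <- table(factor(df$category, levels = INV_CATEGORIES))
    out <- data.frame(category = names(tab), n = as.integer(tab),
                      percent = 100 * as.integer(tab) / nrow(df),
                      stringsAsFactors = FALSE)
    if (!is.null(label)) out <- cbind(dataset = label, out, stringsAsFactors = FALSE)
    out
  }
  if (!perDataset) return(one(records))
  do.call(rbind, lapply(split(records, records$dataset),
                        function(df) one(df, df$dataset[1])))
}

#' Write intersection records as TSV
#'
#' @param records data.frame from \code{\link{classifyCallset}}.
#' @param path output path.
#' @export
writeIntersections <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
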