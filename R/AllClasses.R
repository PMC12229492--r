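#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges findOverlaps seqnames strand
#' @importFrom IRanges IRanges IRangesList
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb seqlevels seqnames
NULL

#' InversionCallset: a harmonized set of inversion calls
#'
#' Container for one dataset's inversion calls after dialect harmonization.
#' Calls live in a \link[GenomicRanges]{GRanges} (1-based, closed intervals:
#' start is the first inverted base, end the last) with metadata columns
#' \code{inv_id}, \code{allele_frequency}, \code{n_homalt} and
#' \code{svtype_raw}. Zero-based half-open coordinates, the convention of BED
#' and of the published coordinates most SV browsers print, are available via
#' \code{\link{start0}} / \code{\link{end0}}.
#'
#' Validity requires: calls restricted to chr1-chr22, chrX, chrY; unique ids;
#' widths >= 1; calls sorted by (chrom, start, end); allele frequencies, when
#' present, in [0, 1]; homozygote counts, when present, non-negative.
#'
#' @slot dataset single dataset label.
#' @slot genomeBuild genome build label (analysis assumes "GRCh38/hg38").
#' @slot calls GRanges of inversion calls.
#' @slot provenance list: source path, dialect and filter counters recording
#'   how many input records were kept or dropped (and why).
#' @export
setClass("InversionCallset",
  representation(
    dataset = "character",
    genomeBuild = "character",
    calls = "GRanges",
    provenance = "list"
  )
)

setValidity("InversionCallset", function(object) {
  msg <- character()
  gr <- object@calls
  if (length(object@dataset) != 1L) msg <- c(msg, "dataset must be a single label")
  if (!all(as.character(seqnames(gr)) %in% ACCEPTED_CONTIGS))
    msg <- c(msg, "calls on non-accepted contigs (allowed: chr1-chr22, chrX, chrY)")
  need <- c("inv_id", "allele_frequency", "n_homalt", "svtype_raw")
  if (!all(need %in% colnames(mcols(gr))))
    msg <- c(msg, sprintf("calls must carry metadata columns %s", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(mcols(gr)$inv_id)) msg <- c(msg, "inversion ids must be unique within a callset")
    af <- mcols(gr)$allele_frequency
    if (any(!is.na(af) & (af < 0 | af > 1))) msg <- c(msg, "allele_frequency must lie in [0, 1]")
    nh <- mcols(gr)$n_homalt
    if (any(!is.na(nh) & nh < 0)) msg <- c(msg, "n_homalt must be non-negative")
  }
  if (length(gr) && any(GenomicRanges::width(gr) < 1L)) msg <- c(msg, "all calls must span >= 1 base")
  if (length(gr) > 1L) {
    o <- order(match(as.character(seqnames(gr)), ACCEPTED_CONTIGS),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
    if (!identical(o, seq_along(gr))) msg <- c(msg, "calls must be sorted by (chrom, start, end)")
  }
  if (length(msg)) msg else TRUE
})

#' GeneModelSet: canonical-transcript protein-coding gene models
#'
#' One canonical transcript per gene. Gene spans are a GRanges (1-based
#' closed); exon blocks per gene are a parallel \link[IRanges]{IRangesList}
#' in genomic coordinates. Introns are derived, never stored: the complement
#' of the exons within the gene span.
#'
#' Validity requires, per gene: exons sorted and pairwise disjoint, the first
#' exon starting at the gene start and the last ending at the gene end, so
#' exon union plus intron union tile the span exactly and a gene with n exons
#' has n - 1 introns.
#'
#' @slot genes GRanges with metadata columns \code{gene_id}, \code{symbol}.
#' @slot exons IRangesList parallel to \code{genes}, named by gene_id.
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    exons = "IRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  g <- object@genes
  ex <- object@exons
  msg <- character()
  if (!all(c("gene_id", "symbol") %in% colnames(mcols(g))))
    msg <- c(msg, "genes must carry gene_id and symbol metadata columns")
  else if (anyDuplicated(mcols(g)$gene_id))
    msg <- c(msg, "gene_id must be unique (one canonical transcript per gene)")
  if (length(ex) != length(g)) msg <- c(msg, "exons must be parallel to genes")
  if (!all(as.character(seqnames(g)) %in% ACCEPTED_CONTIGS))
    msg <- c(msg, "genes on non-accepted contigs")
  if (!all(as.character(strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be + or -")
  if (length(g) && !length(msg)) {
    for (i in seq_along(g)) {
      e <- ex[[i]]
      s <- GenomicRanges::start(g)[i]; t <- GenomicRanges::end(g)[i]
      id <- mcols(g)$gene_id[i]
      if (length(e) == 0L) { msg <- c(msg, sprintf("gene %s has no exons", id)); break }
      if (is.unsorted(IRanges::start(e)) ||
          (length(e) > 1L && any(IRanges::start(e)[-1] <= IRanges::end(e)[-length(e)]))) {
        msg <- c(msg, sprintf("gene %s has unsorted or overlapping exon blocks", id)); break
      }
      if (IRanges::start(e)[1] != s || IRanges::end(e)[length(e)] != t) {
        msg <- c(msg, sprintf("gene %s exons do not tile the gene span", id)); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})
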