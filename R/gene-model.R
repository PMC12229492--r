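#' Construct a GeneModelSet from per-gene block coordinates
#'
#' @param geneId,symbol,chrom,strand per-gene vectors.
#' @param exonStarts0,exonEnds0 lists of numeric vectors, 0-based half-open
#'   exon blocks per gene (the genePred convention). The gene span is derived
#'   from the first exon start and last exon end.
#' @return A \linkS4class{GeneModelSet}.
#' @examples
#' gm <- GeneModelSet("g1", "G1", "chr1", "+",
#'                    exonStarts0 = list(c(100, 300)), exonEnds0 = list(c(200, 400)))
#' introns(gm)
#' @export
GeneModelSet <- function(geneId, symbol = geneId, chrom, strand,
                         exonStarts0, exonEnds0) {
  n <- length(geneId)
  .assert(all(lengths(exonStarts0) == lengths(exonEnds0)),
          "exon start/end lists must be congruent")
  chrom <- normalizeChrom(chrom)
  gstart <- vapply(exonStarts0, function(v) min(v), numeric(1))
  gend <- vapply(exonEnds0, function(v) max(v), numeric(1))
  for (i in seq_len(n)) {
    s <- sort(exonStarts0[[i]]); e <- exonEnds0[[i]][order(exonStarts0[[i]])]
    if (any(e <= s) || (length(s) > 1L && any(s[-1] < e[-length(e)])))
      stop(sprintf("gene %s: overlapping or empty exon blocks", geneId[i]), call. = FALSE)
    exonStarts0[[i]] <- s; exonEnds0[[i]] <- e
  }
  genes <- GRanges(chrom, IRanges(gstart + 1, gend), strand = strand)
  mcols(genes) <- DataFrame(gene_id = as.character(geneId), symbol = as.character(symbol))
  ex <- IRangesList(lapply(seq_len(n), function(i)
    IRanges(exonStarts0[[i]] + 1, exonEnds0[[i]])))
  names(ex) <- geneId
  o <- order(match(chrom, ACCEPTED_CONTIGS), gstart, gend)
  new("GeneModelSet", genes = genes[o], exons = ex[o])
}

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname GeneModelSet-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Accessors for GeneModelSet
#'
#' \code{genes} returns the gene-span GRanges, \code{exons} the per-gene exon
#' IRangesList, \code{introns} the derived per-gene intron IRangesList (the
#' complement of the exons within the span; a gene with n exons has n - 1
#' introns), \code{geneIds} the ids, \code{nGenes} the count.
#'
#' @param x a GeneModelSet.
#' @name GeneModelSet-accessors
#' @aliases genes exons introns geneIds nGenes
NULL

#' @rdname GeneModelSet-accessors
setMethod("genes", "GeneModelSet", function(x) x@genes)
#' @rdname GeneModelSet-accessors
setMethod("exons", "GeneModelSet", function(x) x@exons)
#' @rdname GeneModelSet-accessors
setMethod("geneIds", "GeneModelSet", function(x) mcols(x@genes)$gene_id)
#' @rdname GeneModelSet-accessors
setMethod("nGenes", "GeneModelSet", function(x) length(x@genes))
#' @rdname GeneModelSet-accessors
setMethod("introns", "GeneModelSet", function(x) {
  out <- lapply(seq_along(x@genes), function(i) {
    e <- x@exons[[i]]
    if (length(e) < 2L) return(IRanges())
    IRanges(IRanges::end(e)[-length(e)] + 1, IRanges::start(e)[-1] - 1)
  })
  out <- IRangesList(out)
  names(out) <- mcols(x@genes)$gene_id
  out
})

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d protein-coding genes on %d contigs; %d exons total\n",
              length(object@genes),
              length(unique(as.character(seqnames(object@genes)))),
              sum(lengths(object@exons))))
})

#' Read a canonical-transcript gene table
#'
#' Reads a genePred-style tab-delimited table with header columns
#' \code{gene_id}, \code{symbol}, \code{chrom}, \code{strand}, \code{biotype},
#' \code{exon_starts}, \code{exon_ends} (comma-separated 0-based half-open
#' block coordinates, trailing comma tolerated). Only \code{protein_coding}
#' rows on the 24 accepted contigs are retained; the table is assumed
#' pre-filtered to one canonical transcript per gene and the reader errors on
#' a duplicated gene_id. Overlapping exon blocks within one record are a hard
#' error naming the gene.
#'
#' @param path path to the table.
#' @return A \linkS4class{GeneModelSet}.
#' @export
readGeneTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  need <- c("gene_id", "symbol", "chrom", "strand", "biotype", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(tab))
  .assert(length(miss) == 0L, sprintf("gene table missing column(s): %s", paste(miss, collapse = ", ")))
  tab <- tab[tolower(tab$biotype) == "protein_coding", , drop = FALSE]
  tab <- tab[normalizeChrom(tab$chrom) %in% ACCEPTED_CONTIGS, , drop = FALSE]
  .assert(!anyDuplicated(tab$gene_id),
          "gene table must contain one canonical transcript per gene_id")
  parse <- function(x) lapply(strsplit(x, ","), function(v) as.numeric(v[nzchar(v)]))
  GeneModelSet(tab$gene_id, tab$symbol, tab$chrom, tab$strand,
               parse(tab$exon_starts), parse(tab$exon_ends))
}

#' Write a GeneModelSet as a genePred-style table
#'
#' Inverse of \code{\link{readGeneTable}}; all genes are written with biotype
#' \code{protein_coding}.
#'
#' @param gm a GeneModelSet.
#' @param path output path.
#' @export
writeGeneTable <- function(gm, path) {
  g <- genes(gm); ex <- exons(gm)
  df <- data.frame(
    gene_id = mcols(g)$gene_id,
    symbol = mcols(g)$symbol,
    chrom = as.character(seqnames(g)),
    strand = as.character(strand(g)),
    biotype = "protein_coding",
    exon_starts = vapply(seq_along(ex), function(i)
      paste0(paste(IRanges::start(ex[[i]]) - 1, collapse = ","), ","), character(1)),
    exon_ends = vapply(seq_along(ex), function(i)
      paste0(paste(IRanges::end(ex[[i]]), collapse = ","), ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## synonym map from free-text inheritance strings to mode codes
.MODE_SYNONYMS <- c(
  "autosomal recessive" = "AR", "ar" = "AR",
  "autosomal dominant" = "AD", "ad" = "AD",
  "x-linked recessive" = "XLR", "xlr" = "XLR", "x linked recessive" = "XLR",
  "x-linked dominant" = "XLD", "xld" = "XLD", "x linked dominant" = "XLD"
)

.normalizeMode <- function(x) {
  x <- tolower(trimws(x))
  out <- unname(.MODE_SYNONYMS[x])
  out[is.na(out) & nzchar(x)] <- "other"
  out[!is.na(out)]
}

#' Join OMIM-style and Orphanet-style disease annotations onto genes
#'
#' The OMIM-style table must be tab-delimited with header columns
#' \code{symbol} (and/or \code{gene_id}), \code{phenotype} and
#' \code{inheritance}; one row per gene-phenotype association, with empty
#' \code{phenotype} marking a gene cataloged without a phenotype. Free-text
#' inheritance strings are normalized via a documented synonym map
#' ("Autosomal recessive" to AR, etc.; unrecognized non-empty strings become
#' "other"); multiple modes may be separated by ";" or ",". A gene with
#' phenotype rows of several modes gets the union of modes. The Orphanet
#' table needs a \code{symbol} or \code{gene_id} column; membership sets
#' \code{orphanet_linked}.
#'
#' The result classifies every gene of the model set into exactly one of
#' \code{phenotype_linked}, \code{cataloged_no_phenotype} or
#' \code{not_in_omim}; inheritance modes are non-empty only for
#' phenotype-linked genes.
#'
#' @param gm a \linkS4class{GeneModelSet} (the gene universe).
#' @param omimPath path to the OMIM-style TSV.
#' @param orphanetPath optional path to the Orphanet-style TSV.
#' @return data.frame with columns gene_id, symbol, omim_status,
#'   inheritance_modes (comma-joined, "" when none), orphanet_linked.
#' @export
joinAnnotations <- function(gm, omimPath, orphanetPath = NULL) {
  g <- genes(gm)
  uni <- data.frame(gene_id = mcols(g)$gene_id, symbol = mcols(g)$symbol,
                    stringsAsFactors = FALSE)
  om <- read.table(omimPath, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "", na.strings = NULL)
  .assert(any(c("symbol", "gene_id") %in% names(om)),
          "OMIM table needs a symbol or gene_id column")
  .assert(all(c("phenotype", "inheritance") %in% names(om)),
          "OMIM table needs phenotype and inheritance columns")

  # resolve table rows to gene ids; prefer explicit gene_id, else symbol
  if ("gene_id" %in% names(om) && any(nzchar(om$gene_id))) {
    om$.gid <- om$gene_id
  } else {
    sym2id <- split(uni$gene_id, uni$symbol)
    multi <- names(sym2id)[lengths(sym2id) > 1L]
    if (length(multi) && any(om$symbol %in% multi))
      warning(sprintf("symbol(s) %s map to multiple gene ids; first id (by sort order) wins",
                      paste(intersect(multi, om$symbol), collapse = ", ")))
    om$.gid <- vapply(om$symbol, function(s) {
      ids <- sym2id[[s]]
      if (is.null(ids)) NA_character_ else sort(ids)[1]
    }, character(1))
  }
  om <- om[!is.na(om$.gid) & om$.gid %in% uni$gene_id, , drop = FALSE]

  hasPheno <- nzchar(trimws(om$phenotype))
  modesByGene <- lapply(split(seq_len(nrow(om)), om$.gid), function(idx) {
    idx <- idx[hasPheno[idx]]
    if (!length(idx)) return(character())
    raw <- unlist(strsplit(om$inheritance[idx], "[;,]"))
    sort(unique(.normalizeMode(raw)))
  })
  cataloged <- unique(om$.gid)
  phenoLinked <- names(modesByGene)[vapply(split(hasPheno, om$.gid)[names(modesByGene)],
                                           any, logical(1))]

  status <- rep("not_in_omim", nrow(uni))
  status[uni$gene_id %in% cataloged] <- "cataloged_no_phenotype"
  status[uni$gene_id %in% phenoLinked] <- "phenotype_linked"
  modes <- vapply(uni$gene_id, function(id) {
    m <- modesByGene[[id]]
    if (is.null(m)) "" else paste(m, collapse = ",")
  }, character(1))
  modes[status != "phenotype_linked"] <- ""

  orpha <- rep(FALSE, nrow(uni))
  if (!is.null(orphanetPath)) {
    ot <- read.table(orphanetPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "", comment.char = "")
    if ("gene_id" %in% names(ot)) orpha <- uni$gene_id %in% ot$gene_id
    else if ("symbol" %in% names(ot)) orpha <- uni$symbol %in% ot$symbol
    else stop("Orphanet table needs a symbol or gene_id column", call. = FALSE)
  }
  data.frame(gene_id = uni$gene_id, symbol = uni$symbol,
             omim_status = factor(status, levels = OMIM_STATUSES),
             inheritance_modes = unname(modes),
             orphanet_linked = orpha, stringsAsFactors = FALSE)
}

#' Inheritance-mode background distribution over phenotype-linked genes
#'
#' Counts, per inheritance mode, the phenotype-linked genes carrying that
#' mode; a gene with k modes contributes to k mode counts. Proportions are
#' denominated by the number of phenotype-linked genes, so they can exceed 1
#' in sum when multi-mode genes exist.
#'
#' @param annotations data.frame from \code{\link{joinAnnotations}}.
#' @return data.frame with columns mode, n_genes, proportion.
#' @export
inheritanceBackground <- function(annotations) {
  ph <- annotations[annotations$omim_status == "phenotype_linked", , drop = FALSE]
  .assert(nrow(ph) > 0L, "no phenotype-linked genes in the annotation table")
  modes <- .splitModes(ph$inheritance_modes)
  counts <- vapply(INHERITANCE_MODES, function(m)
    sum(vapply(modes, function(v) m %in% v, logical(1))), numeric(1))
  data.frame(mode = INHERITANCE_MODES, n_genes = unname(counts),
             proportion = unname(counts) / nrow(ph),
             stringsAsFactors = FALSE)
}
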