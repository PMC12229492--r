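#' Construct a harmonized InversionCallset
#'
#' Takes raw per-record vectors in 0-based half-open coordinates (the
#' convention all readers convert their dialect into) and applies the
#' harmonization policy: drop records on non-accepted contigs, drop
#' zero/negative-length records, collapse exact (chrom, start, end)
#' duplicates to one record, and sort by (chrom, start, end). Every dropped
#' record is counted in the provenance filter counters, which always satisfy
#' kept + dropped = input.
#'
#' @param dataset dataset label.
#' @param chrom chromosome names (any style; normalized to "chr" prefix).
#' @param start0 0-based inclusive first inverted base.
#' @param end0 exclusive end (half-open); length = end0 - start0.
#' @param id record ids; defaults to \code{dataset_<i>}.
#' @param alleleFrequency per-call allele frequency in [0,1], NA when unknown.
#' @param nHomalt count of homozygous-alternate individuals, NA when unknown.
#' @param svtypeRaw SV type string as read from the source.
#' @param genomeBuild genome build label.
#' @param provenance list merged into the provenance slot (source, dialect,
#'   upstream counters).
#' @return An \linkS4class{InversionCallset}.
#' @examples
#' cs <- InversionCallset("toy", c("chr1", "chr2"), c(0, 100), c(100, 400))
#' nCalls(cs)
#' @export
InversionCallset <- function(dataset, chrom, start0, end0, id = NULL,
                             alleleFrequency = NA_real_, nHomalt = NA_integer_,
                             svtypeRaw = "INV", genomeBuild = "GRCh38/hg38",
                             provenance = list()) {
  n <- length(chrom)
  .assert(length(start0) == n && length(end0) == n,
          "chrom, start0 and end0 must have equal length")
  chrom <- normalizeChrom(chrom)
  start0 <- as.numeric(start0); end0 <- as.numeric(end0)
  if (is.null(id)) id <- if (n) sprintf("%s_%05d", dataset, seq_len(n)) else character()
  alleleFrequency <- rep_len(as.numeric(alleleFrequency), n)
  nHomalt <- rep_len(as.integer(nHomalt), n)
  svtypeRaw <- rep_len(as.character(svtypeRaw), n)

  counters <- c(input = n, kept = 0L, dropped_contig = 0L,
                dropped_invalid_span = 0L, dropped_duplicate = 0L)

  keep <- chrom %in% ACCEPTED_CONTIGS
  counters["dropped_contig"] <- sum(!keep)
  ok <- keep & (end0 > start0)
  counters["dropped_invalid_span"] <- sum(keep & !(end0 > start0))

  chrom <- chrom[ok]; start0 <- start0[ok]; end0 <- end0[ok]
  id <- id[ok]; alleleFrequency <- alleleFrequency[ok]
  nHomalt <- nHomalt[ok]; svtypeRaw <- svtypeRaw[ok]

  dup <- duplicated(paste(chrom, start0, end0, sep = ":"))
  counters["dropped_duplicate"] <- sum(dup)
  if (any(dup)) {
    chrom <- chrom[!dup]; start0 <- start0[!dup]; end0 <- end0[!dup]
    id <- id[!dup]; alleleFrequency <- alleleFrequency[!dup]
    nHomalt <- nHomalt[!dup]; svtypeRaw <- svtypeRaw[!dup]
  }
  counters["kept"] <- length(chrom)

  o <- order(match(chrom, ACCEPTED_CONTIGS), start0, end0)
  gr <- GRanges(chrom[o], IRanges(start = start0[o] + 1, end = end0[o]))
  mcols(gr) <- DataFrame(inv_id = id[o],
                         allele_frequency = alleleFrequency[o],
                         n_homalt = nHomalt[o],
                         svtype_raw = svtypeRaw[o])
  prov <- provenance
  prov$harmonization <- as.list(counters)
  new("InversionCallset", dataset = dataset, genomeBuild = genomeBuild,
      calls = gr, provenance = prov)
}

#' @rdname InversionCallset-accessors
#' @export
setGeneric("datasetLabel", function(x) standardGeneric("datasetLabel"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("invIds", function(x) standardGeneric("invIds"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("start0", function(x) standardGeneric("start0"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("end0", function(x) standardGeneric("end0"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("invLengths", function(x) standardGeneric("invLengths"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("alleleFrequency", function(x) standardGeneric("alleleFrequency"))
#' @rdname InversionCallset-accessors
#' @export
setGeneric("nHomalt", function(x) standardGeneric("nHomalt"))

#' Accessors for InversionCallset
#'
#' \code{datasetLabel}, \code{genomeBuild}, \code{calls} (the underlying
#' GRanges), \code{provenance}, \code{nCalls}, \code{invIds},
#' \code{start0}/\code{end0} (0-based half-open coordinates),
#' \code{invLengths} (bp), \code{alleleFrequency} and \code{nHomalt}.
#'
#' @param x an InversionCallset.
#' @name InversionCallset-accessors
#' @aliases datasetLabel genomeBuild calls provenance nCalls invIds start0
#'   end0 invLengths alleleFrequency nHomalt
NULL

#' @rdname InversionCallset-accessors
setMethod("datasetLabel", "InversionCallset", function(x) x@dataset)
#' @rdname InversionCallset-accessors
setMethod("genomeBuild", "InversionCallset", function(x) x@genomeBuild)
#' @rdname InversionCallset-accessors
setMethod("calls", "InversionCallset", function(x) x@calls)
#' @rdname InversionCallset-accessors
setMethod("provenance", "InversionCallset", function(x) x@provenance)
#' @rdname InversionCallset-accessors
setMethod("nCalls", "InversionCallset", function(x) length(x@calls))
#' @rdname InversionCallset-accessors
setMethod("invIds", "InversionCallset", function(x) mcols(x@calls)$inv_id)
#' @rdname InversionCallset-accessors
setMethod("start0", "InversionCallset", function(x) GenomicRanges::start(x@calls) - 1)
#' @rdname InversionCallset-accessors
setMethod("end0", "InversionCallset", function(x) GenomicRanges::end(x@calls))
#' @rdname InversionCallset-accessors
setMethod("invLengths", "InversionCallset", function(x) GenomicRanges::width(x@calls))
#' @rdname InversionCallset-accessors
setMethod("alleleFrequency", "InversionCallset", function(x) mcols(x@calls)$allele_frequency)
#' @rdname InversionCallset-accessors
setMethod("nHomalt", "InversionCallset", function(x) mcols(x@calls)$n_homalt)

setMethod("show", "InversionCallset", function(object) {
  cat(sprintf("InversionCallset '%s' (%s): %d calls\n",
              object@dataset, object@genomeBuild, length(object@calls)))
  h <- object@provenance$harmonization
  if (!is.null(h))
    cat(sprintf("  harmonization: %d input, %d kept, %d dropped (contig %d, span %d, duplicate %d)\n",
                h$input, h$kept, h$input - h$kept,
                h$dropped_contig, h$dropped_invalid_span, h$dropped_duplicate))
  if (length(object@calls)) {
    af <- mcols(object@calls)$allele_frequency
    cat(sprintf("  length range: %s-%s bp; AF known for %d calls\n",
                format(min(GenomicRanges::width(object@calls)), big.mark = ","),
                format(max(GenomicRanges::width(object@calls)), big.mark = ","),
                sum(!is.na(af))))
  }
})
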