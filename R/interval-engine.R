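#' Overlap length between two half-open intervals
#'
#' Vectorized. Coordinates are 0-based half-open; the overlap of [a1,a2) and
#' [b1,b2) is max(0, min(a2,b2) - max(a1,b1)), and 0 when the chromosomes
#' differ. The same arithmetic holds verbatim for 1-based closed intervals
#' expressed as (start, end + 1).
#'
#' @param aStart,aEnd,bStart,bEnd interval bounds (half-open).
#' @param aChrom,bChrom optional chromosome names; unequal names force 0.
#' @return integer-valued overlap lengths, >= 0.
#' @export
overlapLength <- function(aStart, aEnd, bStart, bEnd,
                          aChrom = NULL, bChrom = NULL) {
  ov <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
  if (!is.null(aChrom) || !is.null(bChrom))
    ov[as.character(aChrom) != as.character(bChrom)] <- 0
  ov
}

#' Directional fractional-overlap predicate
#'
#' TRUE iff the overlap of a and b covers at least a fraction f of a's
#' length. The fraction applies to the first (query) interval only — the
#' semantics of the classic intersection tool's \code{-f} option — so the
#' predicate is deliberately asymmetric: a short query inside a long subject
#' can pass while the reverse comparison fails. The boundary is inclusive
#' (overlap == f * length passes) and is evaluated in exact integer
#' arithmetic: f is replaced by its best rational approximation num/den and
#' the test is overlap * den >= num * length, so boundary cases are
#' bit-stable.
#'
#' @inheritParams overlapLength
#' @param f required fraction of the query's length, in (0, 1].
#' @return logical vector.
#' @examples
#' overlapsFraction(0, 100, 50, 200, f = 0.5)   # TRUE: 50 >= 0.5 * 100
#' overlapsFraction(50, 200, 0, 100, f = 0.5)   # FALSE: 50 < 0.5 * 150
#' @export
overlapsFraction <- function(aStart, aEnd, bStart, bEnd, f = 0.5,
                             aChrom = NULL, bChrom = NULL) {
  .assert(is.numeric(f) && length(f) == 1L && f > 0 && f <= 1,
          "f must be a single fraction in (0, 1]")
  r <- asRational(f)
  ov <- overlapLength(aStart, aEnd, bStart, bEnd, aChrom, bChrom)
  ov * r[["den"]] >= r[["num"]] * (aEnd - aStart)
}

#' Point containment in a half-open interval
#'
#' TRUE iff start <= pos < end (and chromosomes match, when given).
#'
#' @param aStart,aEnd interval bounds (0-based half-open).
#' @param pos position (0-based).
#' @param aChrom,posChrom optional chromosome names.
#' @return logical vector.
#' @export
containsPoint <- function(aStart, aEnd, pos, aChrom = NULL, posChrom = NULL) {
  ok <- aStart <= pos & pos < aEnd
  if (!is.null(aChrom) || !is.null(posChrom))
    ok[as.character(aChrom) != as.character(posChrom)] <- FALSE
  ok
}

#' All (query, subject) pairs satisfying a fractional overlap
#'
#' Index-backed pair finder over two GRanges: candidate pairs come from
#' \code{\link[GenomicRanges]{findOverlaps}} and are then filtered by the
#' exact-arithmetic \code{\link{overlapsFraction}} predicate on the query's
#' length. Must (and, by the tests, does) agree exactly with an all-pairs
#' brute-force scan.
#'
#' @param query,subject GRanges.
#' @param f required fraction of each query's length, in (0, 1]; \code{f}
#'   close to 0 degenerates to any-overlap.
#' @param reciprocal when TRUE, additionally require the overlap to cover
#'   fraction f of the subject's length as well.
#' @return a \link[S4Vectors]{Hits} object (query/subject index pairs, sorted
#'   by query then subject).
#' @export
fractionOverlapPairs <- function(query, subject, f = 0.5, reciprocal = FALSE) {
  .assert(is.numeric(f) && length(f) == 1L && f > 0 && f <= 1,
          "f must be a single fraction in (0, 1]")
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (!length(hits)) return(hits)
  q <- queryHits(hits); s <- subjectHits(hits)
  # 1-based closed bounds; half-open arithmetic on (start - 1, end)
  qs <- GenomicRanges::start(query)[q] - 1; qe <- GenomicRanges::end(query)[q]
  ss <- GenomicRanges::start(subject)[s] - 1; se <- GenomicRanges::end(subject)[s]
  keep <- overlapsFraction(qs, qe, ss, se, f = f)
  if (reciprocal)
    keep <- keep & overlapsFraction(ss, se, qs, qe, f = f)
  hits[keep]
}

#' Subjects overlapping one query at a required fraction
#'
#' @param query a length-1 GRanges.
#' @param subject GRanges, sorted.
#' @param f fraction of the query's length, in (0, 1].
#' @return integer indices into \code{subject}, in subject order.
#' @export
queryOverlaps <- function(query, subject, f = 0.5) {
  .assert(length(query) == 1L, "query must be a single interval")
  sort(subjectHits(fractionOverlapPairs(query, subject, f = f)))
}
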