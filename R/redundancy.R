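#' Exact-coordinate matching between two callsets
#'
#' The stringent cross-dataset criterion: an inversion of \code{a} matches
#' when \code{b} contains a record with identical (chrom, start, end).
#'
#' @param a,b \linkS4class{InversionCallset}s on the same build.
#' @return logical vector along \code{a}'s calls.
#' @export
matchExact <- function(a, b) {
  keyOf <- function(cs) paste(as.character(seqnames(calls(cs))),
                              start0(cs), end0(cs), sep = ":")
  keyOf(a) %in% keyOf(b)
}

#' Fractional-overlap matching between two callsets
#'
#' The relaxed criterion: an inversion x of \code{a} matches when some y in
#' \code{b} overlaps at least a fraction f of x's length. Directional — the
#' fraction applies to \code{a}'s lengths — unless \code{reciprocal = TRUE}.
#'
#' @param a,b \linkS4class{InversionCallset}s on the same build.
#' @param f required fraction of each of a's lengths, default 0.5.
#' @param reciprocal also require fraction f of the partner's length.
#' @return logical vector along \code{a}'s calls.
#' @export
matchFraction <- function(a, b, f = 0.5, reciprocal = FALSE) {
  hits <- fractionOverlapPairs(calls(a), calls(b), f = f, reciprocal = reciprocal)
  seq_len(nCalls(a)) %in% queryHits(hits)
}

#' Pairwise redundancy matrix across callsets
#'
#' For every ordered dataset pair (a, b), the percentage of a's inversions
#' with at least one match in b under the chosen criterion ("exact":
#' identical coordinates; "fraction": directional fractional overlap, see
#' \code{\link{matchFraction}}). Matching is existential, not one-to-one.
#' The diagonal is 100 by construction under both criteria; the fraction
#' matrix is generally asymmetric because the length denominator follows the
#' row dataset. Also returns per-inversion membership profiles (in how many
#' other datasets each inversion has a match), the basis for upset-style
#' counting, with an inversion called dataset-specific when it is unmatched
#' in every other callset.
#'
#' @param callsets list of >= 2 \linkS4class{InversionCallset}s.
#' @param criterion "fraction" (default) or "exact".
#' @param f fraction for the relaxed criterion, default 0.5.
#' @param reciprocal reciprocal fractional matching (default FALSE).
#' @return list with \code{percent} (matrix, rows = query dataset),
#'   \code{membership} (data.frame: dataset, inv_id, n_datasets_matched,
#'   dataset_specific) and \code{criterion}.
#' @export
redundancyMatrix <- function(callsets, criterion = c("fraction", "exact"),
                             f = 0.5, reciprocal = FALSE) {
  criterion <- match.arg(criterion)
  .assert(length(callsets) >= 2L, "redundancy requires at least 2 callsets")
  labels <- vapply(callsets, datasetLabel, character(1))
  .assert(!anyDuplicated(labels), "dataset labels must be unique")
  names(callsets) <- labels

  matchFun <- function(a, b) {
    if (criterion == "exact") matchExact(a, b)
    else matchFraction(a, b, f = f, reciprocal = reciprocal)
  }
  k <- length(callsets)
  percent <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  matchedElsewhere <- lapply(callsets, function(a) integer(nCalls(a)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m <- if (i == j) rep(TRUE, nCalls(callsets[[i]]))
           else matchFun(callsets[[i]], callsets[[j]])
      percent[i, j] <- if (length(m)) 100 * mean(m) else NA_real_
      if (i != j) matchedElsewhere[[i]] <- matchedElsewhere[[i]] + as.integer(m)
    }
  }
  membership <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(dataset = lab, inv_id = invIds(callsets[[lab]]),
               n_datasets_matched = matchedElsewhere[[lab]],
               dataset_specific = matchedElsewhere[[lab]] == 0L,
               stringsAsFactors = FALSE)
  }))
  list(percent = percent, membership = membership,
       criterion = if (criterion == "fraction")
         sprintf("fraction(%g%s)", f, if (reciprocal) ", reciprocal" else "")
       else "exact")
}
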