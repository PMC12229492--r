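#' Stratify a callset by allele frequency
#'
#' Partitions calls into rare (AF < threshold), common (AF >= threshold; a
#' call exactly at the threshold is common) and unknown (AF missing).
#' Percentages are computed over rare + common only; calls with unknown AF
#' are excluded from the denominator and reported separately, so a callset
#' with no known frequencies yields 0 rare / 0 common / all unknown.
#'
#' @param cs an \linkS4class{InversionCallset}.
#' @param threshold AF threshold in (0, 1); default 0.05 (the conventional
#'   5\% rare/common boundary).
#' @return data.frame with columns stratum (rare/common/unknown), n, percent
#'   (NA for unknown).
#' @examples
#' cs <- InversionCallset("toy", rep("chr1", 3), c(0, 100, 200),
#'                        c(50, 150, 250), alleleFrequency = c(0.001, 0.2, NA))
#' stratifyByFrequency(cs)
#' @export
stratifyByFrequency <- function(cs, threshold = 0.05) {
  .assert(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  af <- alleleFrequency(cs)
  nRare <- sum(!is.na(af) & af < threshold)
  nCommon <- sum(!is.na(af) & af >= threshold)
  nUnknown <- sum(is.na(af))
  denom <- nRare + nCommon
  data.frame(
    stratum = c("rare", "common", "unknown"),
    n = c(nRare, nCommon, nUnknown),
    percent = c(if (denom) 100 * nRare / denom else NA_real_,
                if (denom) 100 * nCommon / denom else NA_real_,
                NA_real_),
    stringsAsFactors = FALSE)
}

#' Recessive-disease candidate cascade
#'
#' Filters classified (inversion, gene) pairs down to recessive-disease
#' candidates: (i) category gene_disrupting or intragenic (gene-spanning
#' events are excluded — their breakpoints lie outside the gene); (ii) gene
#' phenotype-linked in OMIM; (iii) inversion rare (AF < threshold; unknown AF
#' fails the rare requirement). Surviving pairs are flagged
#' \code{never_homozygous} (n_homalt == 0; NA when the count is missing — the
#' row is retained but flagged unknown). The final AR-candidate set comprises
#' never-homozygous pairs whose gene carries the AR inheritance mode.
#'
#' The funnel reports, at each stage, the number of pairs and the distinct
#' inversion- and gene-level counts; counts are non-increasing through the
#' cascade.
#'
#' @param records data.frame from \code{\link{classifyCallset}}.
#' @param cs the \linkS4class{InversionCallset} the records came from.
#' @param annotations data.frame from \code{\link{joinAnnotations}}.
#' @param threshold rare/common AF boundary, default 0.05.
#' @return list with \code{candidates} (pairs surviving stages i-iii, with
#'   inheritance_modes and never_homozygous columns), \code{final} (the AR
#'   never-homozygous subset) and \code{funnel} (stage, n_pairs,
#'   n_inversions, n_genes).
#' @export
candidateCascade <- function(records, cs, annotations, threshold = 0.05) {
  af <- setNames(alleleFrequency(cs), invIds(cs))
  nh <- setNames(nHomalt(cs), invIds(cs))
  ann <- annotations[match(records$gene_id, annotations$gene_id), , drop = FALSE]

  stage <- function(df, label) data.frame(
    stage = label, n_pairs = nrow(df),
    n_inversions = length(unique(df$inversion_id)),
    n_genes = length(unique(df$gene_id)), stringsAsFactors = FALSE)

  s1 <- records[records$category %in% c("gene_disrupting", "intragenic"), , drop = FALSE]
  ann1 <- annotations[match(s1$gene_id, annotations$gene_id), , drop = FALSE]
  s2 <- s1[!is.na(ann1$omim_status) & ann1$omim_status == "phenotype_linked", , drop = FALSE]
  rareIds <- names(af)[!is.na(af) & af < threshold]
  s3 <- s2[s2$inversion_id %in% rareIds, , drop = FALSE]

  s3$inheritance_modes <- annotations$inheritance_modes[match(s3$gene_id, annotations$gene_id)]
  nh3 <- nh[s3$inversion_id]
  s3$never_homozygous <- ifelse(is.na(nh3), NA, nh3 == 0L)

  sNH <- s3[!is.na(s3$never_homozygous) & s3$never_homozygous, , drop = FALSE]
  isAR <- vapply(.splitModes(sNH$inheritance_modes), function(v) "AR" %in% v, logical(1))
  final <- sNH[isAR, , drop = FALSE]

  funnel <- rbind(stage(records, "all_pairs"),
                  stage(s1, "disrupting_or_intragenic"),
                  stage(s2, "omim_phenotype_linked"),
                  stage(s3, "rare"),
                  stage(sNH, "never_homozygous"),
                  stage(final, "ar_candidates"))
  rownames(funnel) <- NULL
  list(candidates = s3, final = final, funnel = funnel)
}

#' Fraction of genes disrupted, per OMIM status class
#'
#' For each OMIM status class, the number of distinct genes with at least one
#' gene_disrupting or intragenic intersection record, divided by the class
#' size in the gene universe.
#'
#' @param records data.frame from \code{\link{classifyCallset}}.
#' @param annotations data.frame from \code{\link{joinAnnotations}} (defines
#'   the gene universe and its OMIM classes).
#' @return data.frame with columns omim_status, n_genes_hit, class_size,
#'   percent.
#' @export
omimDisruptionRates <- function(records, annotations) {
  .assert(nrow(annotations) > 0L, "empty gene universe")
  hitGenes <- unique(records$gene_id[records$category %in%
                                       c("gene_disrupting", "intragenic")])
  out <- do.call(rbind, lapply(OMIM_STATUSES, function(st) {
    cls <- annotations$gene_id[annotations$omim_status == st]
    data.frame(omim_status = st,
               n_genes_hit = sum(cls %in% hitGenes),
               class_size = length(cls), stringsAsFactors = FALSE)
  }))
  out$percent <- ifelse(out$class_size > 0,
                        100 * out$n_genes_hit / out$class_size, NA_real_)
  out
}
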