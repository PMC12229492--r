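#' @import methods
#' @importFrom stats quantile rlnorm runif rpois pnorm phyper dbinom setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom tools file_path_sans_ext
NULL

## The 24 contigs retained for analysis: autosomes plus both sex chromosomes.
ACCEPTED_CONTIGS <- c(paste0("chr", 1:22), "chrX", "chrY")

INV_CATEGORIES <- c("gene_spanning", "gene_disrupting", "intragenic")

INHERITANCE_MODES <- c("AR", "AD", "XLR", "XLD", "other")

OMIM_STATUSES <- c("phenotype_linked", "cataloged_no_phenotype", "not_in_omim")

#' Normalize chromosome names to the "chr"-prefixed convention
#'
#' Adds a "chr" prefix where missing and maps "MT" style mitochondrial names
#' to "chrM" (which is subsequently dropped as a non-accepted contig).
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @keywords internal
normalizeChrom <- function(x) {
  x <- as.character(x)
  has <- startsWith(x, "chr")
  x[!has] <- paste0("chr", x[!has])
  x
}

#' Best rational approximation of a fraction
#'
#' Continued-fraction expansion of \code{f} with denominator bounded by
#' \code{maxDenom}. Used so that fractional-overlap thresholds are compared
#' in exact integer arithmetic (overlap * denominator >= numerator * length)
#' rather than through floating-point products.
#'
#' @param f numeric scalar in (0, 1].
#' @param maxDenom largest denominator considered.
#' @return integer vector c(numerator, denominator).
#' @keywords internal
asRational <- function(f, maxDenom = 1e6L) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  x <- f
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > maxDenom) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(num = p1, den = q1)
}

## stopifnot-style checker with a readable message
.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## split a "AR,AD" style mode string into a character vector
.splitModes <- function(x) {
  x <- as.character(x)
  if (!length(x)) return(list())
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
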