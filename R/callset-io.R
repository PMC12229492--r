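#' Read inversions from a structural-variant VCF
#'
#' Parses a VCF 4.x (plain or bgzipped) with symbolic SV records via
#' \code{\link[VariantAnnotation]{readVcf}} and retains records whose INFO
#' SVTYPE equals \code{INV}. Coordinates: VCF POS is 1-based and INFO END is
#' the 1-based inclusive last base. Under the default anchoring
#' (\code{posAnchor = "first_base"}, matching the gnomAD-SV dialect) POS is
#' the first inverted base, so the half-open record is (POS - 1, END);
#' producers that anchor POS at the base before the event are handled with
#' \code{posAnchor = "preceding_base"}, giving (POS, END). When END is absent
#' the record length is taken from SVLEN; if both are absent the reader stops
#' with the offending record named.
#'
#' Records failing the FILTER policy (default: keep \code{PASS} and \code{.})
#' are dropped and counted; records with missing SVTYPE are skipped with a
#' warning counter. The filter counters in the provenance slot partition the
#' input: kept + dropped-by-type + dropped-by-filter + malformed +
#' dropped-by-contig/span/duplicate = total records.
#'
#' @param path VCF path.
#' @param datasetLabel label for the resulting callset.
#' @param afField,homaltField INFO key names carrying the (global) allele
#'   frequency and the homozygous-alternate count; set to NULL when absent.
#' @param posAnchor \code{"first_base"} (default) or \code{"preceding_base"}.
#' @param filterPolicy FILTER values to keep; NULL keeps everything.
#' @param expectedBuild build label; if the VCF header declares a
#'   \code{##reference} that matches neither "GRCh38" nor "hg38" (or, in
#'   general, no token of this label), reading stops with a build-mismatch
#'   error.
#' @return An \linkS4class{InversionCallset}.
#' @export
readVcfInversions <- function(path, datasetLabel,
                              afField = "AF", homaltField = "N_HOMALT",
                              posAnchor = c("first_base", "preceding_base"),
                              filterPolicy = c("PASS", "."),
                              expectedBuild = "GRCh38/hg38") {
  posAnchor <- match.arg(posAnchor)

  # build check against the declared reference, if any
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  hdr <- character()
  open(con, "r")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "##")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  ref <- grep("^##reference=", hdr, value = TRUE)
  if (length(ref) && !is.null(expectedBuild)) {
    tokens <- strsplit(expectedBuild, "/")[[1]]
    if (!any(vapply(tokens, function(t) grepl(t, ref[1], ignore.case = TRUE), logical(1))))
      stop(sprintf("genome build mismatch: VCF declares '%s', expected %s",
                   sub("^##reference=", "", ref[1]), expectedBuild), call. = FALSE)
  }

  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  info <- VariantAnnotation::info(vcf)
  counters <- c(input = n, dropped_filter = 0L, malformed_svtype = 0L,
                dropped_type = 0L)

  if (n == 0L) {
    return(InversionCallset(datasetLabel, character(), numeric(), numeric(),
                            genomeBuild = expectedBuild,
                            provenance = list(source = path, dialect = "vcf",
                                              reader = as.list(counters))))
  }

  keep <- rep(TRUE, n)
  filt <- VariantAnnotation::filt(vcf)
  if (!is.null(filterPolicy)) {
    passf <- filt %in% filterPolicy | is.na(filt)
    counters["dropped_filter"] <- sum(!passf)
    keep <- keep & passf
  }
  svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE) else rep(NA_character_, n)
  noType <- is.na(svtype)
  if (any(noType & keep)) {
    warning(sprintf("%d record(s) without SVTYPE skipped", sum(noType & keep)))
    counters["malformed_svtype"] <- sum(noType & keep)
    keep <- keep & !noType
  }
  isInv <- !is.na(svtype) & toupper(svtype) == "INV"
  counters["dropped_type"] <- sum(keep & !isInv)
  keep <- keep & isInv

  idx <- which(keep)
  rr <- SummarizedExperiment::rowRanges(vcf)[idx]
  pos <- GenomicRanges::start(rr)
  getInfo <- function(key) {
    if (is.null(key) || !(key %in% names(info))) return(NULL)
    v <- info[[key]][idx]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(e) if (length(e)) as.numeric(e[1]) else NA_real_, numeric(1))
    as.numeric(v)
  }
  endv <- getInfo("END")
  svlen <- getInfo("SVLEN")
  if (is.null(endv)) endv <- rep(NA_real_, length(idx))
  needLen <- is.na(endv)
  if (any(needLen)) {
    if (is.null(svlen) || any(is.na(svlen[needLen])))
      stop(sprintf("record '%s': neither END nor SVLEN present",
                   names(rr)[which(needLen & (is.null(svlen) | is.na(svlen)))[1]]),
           call. = FALSE)
    endv[needLen] <- pos[needLen] + abs(svlen[needLen]) - 1
  }
  start0 <- if (posAnchor == "first_base") pos - 1 else pos
  af <- getInfo(afField); if (is.null(af)) af <- NA_real_
  nh <- getInfo(homaltField); if (is.null(nh)) nh <- NA_integer_

  InversionCallset(datasetLabel,
                   chrom = as.character(seqnames(rr)),
                   start0 = start0, end0 = endv,
                   id = names(rr),
                   alleleFrequency = af, nHomalt = as.integer(nh),
                   svtypeRaw = svtype[idx],
                   genomeBuild = expectedBuild,
                   provenance = list(source = path, dialect = "vcf",
                                     pos_anchor = posAnchor,
                                     reader = as.list(counters)))
}

#' Read inversions from a DGV-style variant table
#'
#' Tab-delimited with a header. Rows whose variant subtype matches an
#' inversion synonym (case-insensitive) are retained; 1-based inclusive
#' coordinates are converted to half-open as (start - 1, end); chromosome
#' names are normalized to the "chr" prefix. Rows with unparseable
#' coordinates are skipped and counted; a missing required column is a hard
#' error.
#'
#' @param path table path.
#' @param datasetLabel label for the resulting callset.
#' @param chromCol,startCol,endCol,typeCol,idCol column names; \code{typeCol}
#'   falls back to \code{varianttype} when \code{variantsubtype} is absent,
#'   \code{idCol} is optional.
#' @param typeSynonyms variant-type strings accepted as inversions.
#' @return An \linkS4class{InversionCallset}.
#' @export
readDgvTable <- function(path, datasetLabel,
                         chromCol = "chr", startCol = "start", endCol = "end",
                         typeCol = "variantsubtype", idCol = "variantaccession",
                         typeSynonyms = c("inversion", "inv")) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  if (!(typeCol %in% names(tab)) && "varianttype" %in% names(tab)) typeCol <- "varianttype"
  miss <- setdiff(c(chromCol, startCol, endCol, typeCol), names(tab))
  .assert(length(miss) == 0L, sprintf("DGV table missing column(s): %s",
                                      paste(miss, collapse = ", ")))
  isInv <- tolower(trimws(tab[[typeCol]])) %in% tolower(typeSynonyms)
  counters <- c(input = nrow(tab), dropped_type = sum(!isInv), malformed_coord = 0L)
  tab <- tab[isInv, , drop = FALSE]
  s1 <- suppressWarnings(as.numeric(tab[[startCol]]))
  e1 <- suppressWarnings(as.numeric(tab[[endCol]]))
  bad <- is.na(s1) | is.na(e1)
  if (any(bad)) {
    warning(sprintf("%d row(s) with unparseable coordinates skipped", sum(bad)))
    counters["malformed_coord"] <- sum(bad)
    tab <- tab[!bad, , drop = FALSE]; s1 <- s1[!bad]; e1 <- e1[!bad]
  }
  id <- if (idCol %in% names(tab)) as.character(tab[[idCol]]) else NULL
  InversionCallset(datasetLabel, chrom = tab[[chromCol]],
                   start0 = s1 - 1, end0 = e1, id = id,
                   svtypeRaw = if (nrow(tab)) tab[[typeCol]] else character(),
                   provenance = list(source = path, dialect = "dgv",
                                     reader = as.list(counters)))
}

#' Read inversions from a BED3+ file
#'
#' BED is 0-based half-open, matching the harmonized convention, so
#' coordinates are ingested verbatim; an optional 4th column supplies ids.
#' Rows with start >= end are rejected and counted.
#'
#' @param path BED path.
#' @param datasetLabel label for the resulting callset.
#' @return An \linkS4class{InversionCallset}.
#' @export
readBedInversions <- function(path, datasetLabel) {
  tab <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               quote = "", comment.char = "#"),
    error = function(e) data.frame())
  if (nrow(tab) == 0L)
    return(InversionCallset(datasetLabel, character(), numeric(), numeric(),
                            provenance = list(source = path, dialect = "bed")))
  .assert(ncol(tab) >= 3L, "BED file must have at least 3 columns")
  id <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else NULL
  InversionCallset(datasetLabel, chrom = tab[[1]],
                   start0 = as.numeric(tab[[2]]), end0 = as.numeric(tab[[3]]),
                   id = id,
                   provenance = list(source = path, dialect = "bed"))
}

#' Write a harmonized callset
#'
#' BED output is 0-based half-open (chrom, start, end, id). TSV output
#' carries 1-based inclusive display coordinates plus the population fields
#' (dataset, chrom, start, end, inv_id, allele_frequency, n_homalt,
#' svtype_raw). A JSON provenance sidecar (\code{<path>.prov.json}) records
#' the filter counters. \code{write -> read} round-trips coordinates exactly
#' in either format.
#'
#' @param cs an \linkS4class{InversionCallset}.
#' @param path output path.
#' @param format "bed" or "tsv".
#' @param sidecar write the provenance sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeCallset <- function(cs, path, format = c("tsv", "bed"), sidecar = TRUE) {
  format <- match.arg(format)
  gr <- calls(cs)
  if (format == "bed") {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr),
                     name = mcols(gr)$inv_id)
    # header-only (empty) BED is a zero-line file
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(dataset = rep(datasetLabel(cs), length(gr)),
                     chrom = as.character(seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     inv_id = mcols(gr)$inv_id,
                     allele_frequency = mcols(gr)$allele_frequency,
                     n_homalt = mcols(gr)$n_homalt,
                     svtype_raw = mcols(gr)$svtype_raw)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (sidecar)
    jsonlite::write_json(
      list(dataset = datasetLabel(cs), genome_build = genomeBuild(cs),
           n_calls = nCalls(cs), provenance = provenance(cs)),
      paste0(path, ".prov.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a callset written by \code{writeCallset(..., format = "tsv")}
#'
#' @param path TSV path.
#' @param datasetLabel optional label override; defaults to the file's
#'   dataset column (or the file name for an empty file).
#' @return An \linkS4class{InversionCallset}.
#' @export
readCallsetTsv <- function(path, datasetLabel = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  if (is.null(datasetLabel))
    datasetLabel <- if (nrow(tab)) tab$dataset[1] else
      tools::file_path_sans_ext(basename(path))
  if (nrow(tab) == 0L)
    return(InversionCallset(datasetLabel, character(), numeric(), numeric(),
                            provenance = list(source = path, dialect = "tsv")))
  InversionCallset(datasetLabel, chrom = tab$chrom,
                   start0 = tab$start - 1, end0 = tab$end, id = tab$inv_id,
                   alleleFrequency = tab$allele_frequency,
                   nHomalt = tab$n_homalt, svtypeRaw = tab$svtype_raw,
                   provenance = list(source = path, dialect = "tsv"))
}

#' Write a callset as a symbolic-allele VCF
#'
#' Emits a minimal VCF 4.2 in the gnomAD-SV dialect: symbolic \code{<INV>}
#' ALT, INFO keys SVTYPE, END, AF and N_HOMALT, POS anchored at the first
#' inverted base. Primarily the synthetic-data emitter, so simulated
#' callsets exercise the same reader path as real downloads.
#'
#' @param cs an \linkS4class{InversionCallset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCallsetVcf <- function(cs, path) {
  gr <- calls(cs)
  hdr <- c("##fileformat=VCFv4.2",
           "##reference=GRCh38",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="1-based inclusive end">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">',
           '##INFO=<ID=N_HOMALT,Number=1,Type=Integer,Description="Homozygous-alternate count">',
           '##ALT=<ID=INV,Description="Inversion">',
           paste0("##contig=<ID=", unique(as.character(seqnames(gr))), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  af <- mcols(gr)$allele_frequency
  nh <- mcols(gr)$n_homalt
  infos <- vapply(seq_along(gr), function(i) {
    f <- c(sprintf("END=%d", GenomicRanges::end(gr)[i]), "SVTYPE=INV")
    if (!is.na(af[i])) f <- c(f, sprintf("AF=%.8g", af[i]))
    if (!is.na(nh[i])) f <- c(f, sprintf("N_HOMALT=%d", nh[i]))
    paste(f, collapse = ";")
  }, character(1))
  body <- if (length(gr)) sprintf("%s\t%d\t%s\tN\t<INV>\t.\tPASS\t%s",
                                  as.character(seqnames(gr)),
                                  GenomicRanges::start(gr),
                                  mcols(gr)$inv_id, infos) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
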