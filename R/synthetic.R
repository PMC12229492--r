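#' DatasetProfile: generative parameters emulating one source dataset
#'
#' Length model is a split (two-piece) log-normal on base pairs: below the
#' median, log-lengths fall off with scale \code{lengthSdlogLower}; above it,
#' with \code{lengthSdlogUpper}. Real inversion callsets are asymmetric even
#' on the log scale (the median-to-Q1 ratio far exceeds the Q3-to-median
#' ratio), so a symmetric log-normal cannot reproduce all three quartiles at
#' once; the split form hits them exactly while keeping log-normal tails.
#' With equal scales it degenerates to the ordinary log-normal. The
#' allele-frequency model is a two-component mixture: with probability
#' \code{propRare} an AF uniform on \code{rareRange}, else uniform on
#' \code{commonRange}. \code{propHomaltZero} is the fraction of calls never
#' observed homozygous.
#'
#' @slot label dataset label.
#' @slot nCalls number of calls to generate.
#' @slot lengthMeanlog log of the median length (bp).
#' @slot lengthSdlogLower,lengthSdlogUpper log-scale spreads below/above the
#'   median.
#' @slot propRare mixture weight of the rare AF component.
#' @slot rareRange,commonRange AF ranges of the two components.
#' @slot propHomaltZero fraction of calls with n_homalt = 0.
#' @export
setClass("DatasetProfile",
  representation(label = "character", nCalls = "integer",
                 lengthMeanlog = "numeric", lengthSdlogLower = "numeric",
                 lengthSdlogUpper = "numeric",
                 propRare = "numeric", rareRange = "numeric",
                 commonRange = "numeric", propHomaltZero = "numeric"))

setValidity("DatasetProfile", function(object) {
  msg <- character()
  if (object@lengthSdlogLower <= 0 || object@lengthSdlogUpper <= 0)
    msg <- c(msg, "length sdlog parameters must be > 0")
  for (p in c(object@propRare, object@propHomaltZero))
    if (p < 0 || p > 1) msg <- c(msg, "proportions must lie in [0, 1]")
  if (object@nCalls < 0) msg <- c(msg, "nCalls must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DatasetProfile", function(object) {
  cat(sprintf("DatasetProfile '%s': %d calls, length ~ split-lognormal(%.3f; %.3f/%.3f) bp, %.1f%% rare\n",
              object@label, object@nCalls, object@lengthMeanlog,
              object@lengthSdlogLower, object@lengthSdlogUpper,
              100 * object@propRare))
})

#' Construct a DatasetProfile
#'
#' @param label dataset label.
#' @param nCalls number of calls.
#' @param lengthMeanlog log of the median length (bp).
#' @param lengthSdlogLower,lengthSdlogUpper log-scale spreads below and above
#'   the median (equal values give an ordinary log-normal).
#' @param propRare mixture weight of the rare AF component.
#' @param rareRange,commonRange AF ranges (rare below, common at or above the
#'   conventional 5\% boundary).
#' @param propHomaltZero fraction of never-homozygous calls.
#' @return a \linkS4class{DatasetProfile}.
#' @export
datasetProfile <- function(label, nCalls, lengthMeanlog, lengthSdlogLower,
                           lengthSdlogUpper = lengthSdlogLower,
                           propRare = 0.989,
                           rareRange = c(1e-5, 0.05),
                           commonRange = c(0.05, 0.5),
                           propHomaltZero = 254 / 279) {
  new("DatasetProfile", label = label, nCalls = as.integer(nCalls),
      lengthMeanlog = lengthMeanlog, lengthSdlogLower = lengthSdlogLower,
      lengthSdlogUpper = lengthSdlogUpper,
      propRare = propRare, rareRange = rareRange,
      commonRange = commonRange, propHomaltZero = propHomaltZero)
}

## split log-normal sampler: median exp(mu), lower/upper quartiles at
## exp(mu -/+ 0.6745 * s)
.rSplitLognorm <- function(n, mu, sLower, sUpper) {
  z <- abs(stats::rnorm(n))
  s <- ifelse(stats::runif(n) < 0.5, -sLower, sUpper)
  exp(mu + s * z)
}

#' Calibrate a length model from target quartiles
#'
#' Quantile matching for the split log-normal: meanlog = ln(median),
#' sdlogLower = (ln(median) - ln(q1)) / 0.6745 and
#' sdlogUpper = (ln(q3) - ln(median)) / 0.6745, 0.6745 being the standard
#' normal upper quartile, so the generated lengths reproduce all three target
#' quartiles exactly in expectation.
#'
#' @param label,nCalls passed through to \code{\link{datasetProfile}}.
#' @param medianKb,q1Kb,q3Kb target length quartiles in kb.
#' @param ... further arguments to \code{\link{datasetProfile}}.
#' @return a \linkS4class{DatasetProfile}.
#' @export
profileFromQuartiles <- function(label, nCalls, medianKb, q1Kb, q3Kb, ...) {
  q <- 0.6744898  # qnorm(0.75)
  datasetProfile(label, nCalls,
                 lengthMeanlog = log(medianKb * 1000),
                 lengthSdlogLower = (log(medianKb) - log(q1Kb)) / q,
                 lengthSdlogUpper = (log(q3Kb) - log(medianKb)) / q,
                 ...)
}

#' gnomAD-like profile preset
#'
#' Length model calibrated to the short-read population callset's quartiles
#' (median 7.12 kb, Q1 0.896 kb, Q3 23.63 kb); 98.9\% rare alleles; 254/279
#' never homozygous.
#'
#' @param nCalls number of calls (default 2185).
#' @return a \linkS4class{DatasetProfile}.
#' @export
gnomadLikeProfile <- function(nCalls = 2185) {
  profileFromQuartiles("gnomad_like", nCalls,
                       medianKb = 7.12, q1Kb = 0.896, q3Kb = 23.63)
}

#' Generate a toy genome description
#'
#' @param nChroms number of contigs (<= 24; named chr1, chr2, ...).
#' @param chromLength length of each contig in bp (scalar or per-contig).
#' @param seed unused for the genome itself (it is deterministic) but kept in
#'   the signature so pipelines thread one seed through all generators.
#' @return data.frame with columns chrom, length.
#' @export
makeGenome <- function(nChroms, chromLength, seed = 1L) {
  .assert(nChroms >= 1L && nChroms <= 24L, "nChroms must lie in 1..24")
  .assert(all(chromLength > 0), "chromLength must be positive")
  data.frame(chrom = ACCEPTED_CONTIGS[seq_len(nChroms)],
             length = rep_len(chromLength, nChroms),
             stringsAsFactors = FALSE)
}

#' Generate gene models and disease annotations with known structure
#'
#' Places non-overlapping multi-exon genes along the toy genome with
#' intergenic gaps, exon counts uniform on \code{exonCountRange}, exon
#' lengths uniform on \code{exonLengthRange} and intron lengths log-normal.
#' Each gene receives an OMIM status drawn from \code{omimMix} and, when
#' phenotype-linked, one inheritance mode drawn from \code{inheritanceMix}
#' (a second, distinct mode is added with probability \code{multiModeProb}).
#' The mixes are synthetic defaults for testing, not estimates of the real
#' OMIM composition.
#'
#' @param genome data.frame from \code{\link{makeGenome}}.
#' @param nGenes number of genes.
#' @param exonCountRange integer range of exons per gene.
#' @param exonLengthRange exon length range (bp).
#' @param intronMeanlog,intronSdlog log-normal intron-length parameters (bp).
#' @param gapRange intergenic gap range (bp).
#' @param omimMix named proportions over phenotype_linked,
#'   cataloged_no_phenotype, not_in_omim.
#' @param inheritanceMix named proportions over AR, AD, XLR, XLD, other.
#' @param multiModeProb probability a phenotype-linked gene carries two modes.
#' @param orphanetProb probability a phenotype-linked gene is in Orphanet.
#' @param seed RNG seed; identical seeds give identical output.
#' @return list(genes = \linkS4class{GeneModelSet}, annotations = data.frame
#'   as from \code{\link{joinAnnotations}}).
#' @export
makeGenes <- function(genome, nGenes,
                      exonCountRange = c(2L, 10L),
                      exonLengthRange = c(100L, 300L),
                      intronMeanlog = log(2000), intronSdlog = 0.8,
                      gapRange = c(10000L, 50000L),
                      omimMix = c(phenotype_linked = 0.3,
                                  cataloged_no_phenotype = 0.5,
                                  not_in_omim = 0.2),
                      inheritanceMix = c(AR = 0.45, AD = 0.30, XLR = 0.05,
                                         XLD = 0.02, other = 0.18),
                      multiModeProb = 0.1, orphanetProb = 0.5,
                      seed = 1L) {
  set.seed(seed)
  .assert(nGenes >= 1L, "nGenes must be >= 1")
  perChrom <- table(factor(genome$chrom[1 + (seq_len(nGenes) - 1L) %% nrow(genome)],
                           levels = genome$chrom))
  geneId <- sprintf("SYNG%05d", seq_len(nGenes))
  chromOut <- character(nGenes); strandOut <- character(nGenes)
  exS <- vector("list", nGenes); exE <- vector("list", nGenes)
  gi <- 0L
  for (ci in seq_len(nrow(genome))) {
    pos <- 0
    for (k in seq_len(perChrom[[ci]])) {
      gi <- gi + 1L
      nEx <- sample(exonCountRange[1]:exonCountRange[2], 1L)
      exLen <- sample(exonLengthRange[1]:exonLengthRange[2], nEx, replace = TRUE)
      inLen <- if (nEx > 1L) pmax(2L, round(rlnorm(nEx - 1L, intronMeanlog, intronSdlog))) else integer()
      gap <- sample(gapRange[1]:gapRange[2], 1L)
      gstart <- pos + gap
      starts <- gstart + cumsum(c(0L, head(exLen, -1L) + inLen))
      ends <- starts + exLen
      if (ends[nEx] > genome$length[ci])
        stop(sprintf("requested genes cannot fit: gene %d exceeds %s (%d > %d)",
                     gi, genome$chrom[ci], ends[nEx], genome$length[ci]), call. = FALSE)
      chromOut[gi] <- genome$chrom[ci]
      strandOut[gi] <- sample(c("+", "-"), 1L)
      exS[[gi]] <- starts; exE[[gi]] <- ends
      pos <- ends[nEx]
    }
  }
  gm <- GeneModelSet(geneId, paste0("SYM", seq_len(nGenes)), chromOut,
                     strandOut, exS, exE)

  status <- sample(names(omimMix), nGenes, replace = TRUE, prob = omimMix)
  modes <- vapply(seq_len(nGenes), function(i) {
    if (status[i] != "phenotype_linked") return("")
    m <- sample(names(inheritanceMix), 1L, prob = inheritanceMix)
    if (runif(1) < multiModeProb) {
      m2 <- sample(setdiff(names(inheritanceMix), m), 1L)
      m <- sort(c(m, m2))
    }
    paste(m, collapse = ",")
  }, character(1))
  orpha <- status == "phenotype_linked" & runif(nGenes) < orphanetProb
  ann <- data.frame(gene_id = geneId, symbol = paste0("SYM", seq_len(nGenes)),
                    omim_status = factor(status, levels = OMIM_STATUSES),
                    inheritance_modes = modes, orphanet_linked = orpha,
                    stringsAsFactors = FALSE)
  # report in gene-sorted order to match the GeneModelSet
  ann <- ann[match(geneIds(gm), ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(genes = gm, annotations = ann)
}

## free-text forms used when emitting OMIM-style tables
.MODE_FREETEXT <- c(AR = "Autosomal recessive", AD = "Autosomal dominant",
                    XLR = "X-linked recessive", XLD = "X-linked dominant",
                    other = "Multifactorial")

#' Write annotations as OMIM-style and Orphanet-style tables
#'
#' Emits the same dialects \code{\link{joinAnnotations}} consumes, so that
#' simulate -> write -> read round-trips the annotation structure.
#'
#' @param annotations data.frame (as from \code{\link{makeGenes}}).
#' @param omimPath,orphanetPath output paths.
#' @export
writeAnnotationTables <- function(annotations, omimPath, orphanetPath) {
  inOmim <- annotations$omim_status != "not_in_omim"
  df <- annotations[inOmim, , drop = FALSE]
  pheno <- ifelse(df$omim_status == "phenotype_linked",
                  paste0("Synthetic phenotype of ", df$symbol), "")
  inh <- vapply(.splitModes(df$inheritance_modes), function(v)
    paste(.MODE_FREETEXT[v], collapse = "; "), character(1))
  write.table(data.frame(symbol = df$symbol, gene_id = df$gene_id,
                         phenotype = pheno, inheritance = inh),
              omimPath, sep = "\t", quote = FALSE, row.names = FALSE)
  orp <- annotations[annotations$orphanet_linked, c("symbol", "gene_id"), drop = FALSE]
  write.table(orp, orphanetPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(omimPath)
}

## per-gene safe flanks: intergenic distance to the neighbouring gene (or
## contig boundary) on each side, in bp
.geneFlanks <- function(gm, genome) {
  g <- genes(gm)
  chrom <- as.character(seqnames(g))
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  left <- numeric(length(g)); right <- numeric(length(g))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(gs[idx])]
    chLen <- genome$length[genome$chrom == ch]
    prevEnd <- c(0, ge[idx][-length(idx)])
    nextStart <- c(gs[idx][-1], chLen + 1)
    left[idx] <- gs[idx] - prevEnd - 1
    right[idx] <- nextStart - ge[idx] - 1
  }
  data.frame(left = left, right = right)
}

#' Generate an inversion callset with planted ground truth
#'
#' Plants inversions whose (inversion, gene) category is constructed to be
#' exactly the requested one — \code{gene_spanning} (both breakpoints in the
#' flanking intergenic space of one gene), \code{gene_disrupting} (one
#' breakpoint inside the gene, one in the right flank), \code{intragenic}
#' (breakpoints in the gene's first and last exon, so never single-intron
#' for multi-exon genes) and \code{intragenic_single_intron} (both
#' breakpoints inside one intron) — then fills up to \code{nCalls} with
#' background calls drawn from the profile's log-normal length model placed
#' uniformly. Allele frequencies follow the profile's rare/common mixture
#' and homozygote counts its never-homozygous fraction. Infeasible quotas
#' (e.g. single-intron events in a universe without a wide-enough intron)
#' are a hard error naming the quota.
#'
#' @param profile a \linkS4class{DatasetProfile}.
#' @param gm a \linkS4class{GeneModelSet} from \code{\link{makeGenes}}.
#' @param genome data.frame from \code{\link{makeGenome}}.
#' @param planted named integer vector with any of gene_spanning,
#'   gene_disrupting, intragenic, intragenic_single_intron.
#' @param seed RNG seed (single global stream; identical seeds give
#'   identical callsets).
#' @return list(callset = \linkS4class{InversionCallset}, truth = data.frame
#'   with inv_id, gene_id, category, single_intron, af_stratum). Truth rows
#'   refer to planted calls only; the callset's provenance records the seed
#'   and quotas.
#' @export
makeCallset <- function(profile, gm, genome,
                        planted = c(gene_spanning = 0L, gene_disrupting = 0L,
                                    intragenic = 0L, intragenic_single_intron = 0L),
                        seed = 1L) {
  set.seed(seed)
  quotas <- c(gene_spanning = 0L, gene_disrupting = 0L, intragenic = 0L,
              intragenic_single_intron = 0L)
  quotas[names(planted)] <- as.integer(planted)
  nPlanted <- sum(quotas)
  .assert(nPlanted <= profile@nCalls,
          "planted quotas exceed the profile's number of calls")

  g <- genes(gm); ex <- exons(gm); ins <- introns(gm)
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  chrom <- as.character(seqnames(g))
  flanks <- .geneFlanks(gm, genome)

  sampleIn <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1L)
  pickGene <- function(ok, quota) {
    .assert(any(ok), sprintf("infeasible quota '%s': no suitable gene", quota))
    sample(which(ok), 1L)
  }

  tChrom <- character(nPlanted); tS0 <- numeric(nPlanted); tE0 <- numeric(nPlanted)
  truth <- data.frame(inv_id = character(nPlanted), gene_id = character(nPlanted),
                      category = character(nPlanted), single_intron = logical(nPlanted),
                      af_stratum = character(nPlanted), stringsAsFactors = FALSE)
  k <- 0L
  for (cat in names(quotas)) {
    for (r in seq_len(quotas[[cat]])) {
      k <- k + 1L
      if (cat == "gene_spanning") {
        i <- pickGene(flanks$left >= 1 & flanks$right >= 1, cat)
        d1 <- sampleIn(1, min(flanks$left[i], 5000))
        d2 <- sampleIn(1, min(flanks$right[i], 5000))
        s1 <- gs[i] - d1; e1 <- ge[i] + d2
        single <- NA
      } else if (cat == "gene_disrupting") {
        i <- pickGene(flanks$right >= 1, cat)
        s1 <- sampleIn(gs[i], ge[i])
        e1 <- ge[i] + sampleIn(1, min(flanks$right[i], 5000))
        single <- NA
      } else if (cat == "intragenic") {
        nEx <- lengths(ex)
        i <- pickGene(nEx >= 2L, cat)
        e_first <- ex[[i]][1]; e_last <- ex[[i]][length(ex[[i]])]
        s1 <- sampleIn(IRanges::start(e_first), IRanges::end(e_first))
        e1 <- sampleIn(IRanges::start(e_last), IRanges::end(e_last))
        single <- FALSE
      } else { # intragenic_single_intron
        wide <- vapply(ins, function(ii) length(ii) > 0L && max(IRanges::width(ii)) >= 2L,
                       logical(1))
        i <- pickGene(wide, cat)
        ii <- ins[[i]]
        j <- which(IRanges::width(ii) == max(IRanges::width(ii)))[1]
        s1 <- sampleIn(IRanges::start(ii)[j], IRanges::end(ii)[j] - 1L)
        e1 <- sampleIn(s1 + 1L, IRanges::end(ii)[j])
        single <- TRUE
      }
      tChrom[k] <- chrom[i]; tS0[k] <- s1 - 1; tE0[k] <- e1
      truth$gene_id[k] <- geneIds(gm)[i]
      truth$category[k] <- sub("_single_intron$", "", cat)
      truth$single_intron[k] <- single
    }
  }

  nBg <- profile@nCalls - nPlanted
  bgChromIdx <- sample.int(nrow(genome), nBg, replace = TRUE, prob = genome$length)
  bgLen <- pmax(50, round(.rSplitLognorm(nBg, profile@lengthMeanlog,
                                         profile@lengthSdlogLower,
                                         profile@lengthSdlogUpper)))
  bgLen <- pmin(bgLen, floor(genome$length[bgChromIdx] / 2))
  bgS0 <- floor(runif(nBg, 0, genome$length[bgChromIdx] - bgLen))
  allChrom <- c(tChrom, genome$chrom[bgChromIdx])
  allS0 <- c(tS0, bgS0)
  allE0 <- c(tE0, bgS0 + bgLen)
  n <- length(allChrom)

  isRare <- runif(n) < profile@propRare
  af <- ifelse(isRare,
               runif(n, profile@rareRange[1], profile@rareRange[2]),
               runif(n, profile@commonRange[1], profile@commonRange[2]))
  nh <- ifelse(runif(n) < profile@propHomaltZero, 0L, 1L + rpois(n, 1))
  ids <- sprintf("%s_%05d", profile@label, seq_len(n))

  truth$inv_id <- ids[seq_len(nPlanted)]
  truth$af_stratum <- ifelse(isRare[seq_len(nPlanted)], "rare", "common")

  cs <- InversionCallset(profile@label, allChrom, allS0, allE0, id = ids,
                         alleleFrequency = af, nHomalt = as.integer(nh),
                         svtypeRaw = "INV",
                         provenance = list(source = "synthetic", dialect = "synthetic",
                                           seed = seed, planted = as.list(quotas)))
  truth <- truth[truth$inv_id %in% invIds(cs), , drop = FALSE]
  rownames(truth) <- NULL
  list(callset = cs, truth = truth)
}
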