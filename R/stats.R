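#' Length summary of a callset
#'
#' Six-number summary of inversion lengths in kilobases. Quartiles use
#' linear interpolation between order statistics (the "type 7" definition,
#' the default of most statistical environments); \code{quantileType = 6}
#' selects the alternative interpolation some spreadsheet-style tools use.
#'
#' @param cs an \linkS4class{InversionCallset} with >= 1 call.
#' @param quantileType 7 (default) or 6; passed to \code{\link[stats]{quantile}}.
#' @return one-row data.frame: dataset, n, min_kb, q1_kb, median_kb, mean_kb,
#'   q3_kb, max_kb.
#' @export
lengthSummary <- function(cs, quantileType = 7) {
  .assert(nCalls(cs) >= 1L, "length summary of an empty callset")
  kb <- invLengths(cs) / 1000
  q <- quantile(kb, c(0.25, 0.5, 0.75), type = quantileType, names = FALSE)
  data.frame(dataset = datasetLabel(cs), n = nCalls(cs),
             min_kb = min(kb), q1_kb = q[1], median_kb = q[2],
             mean_kb = mean(kb), q3_kb = q[3], max_kb = max(kb),
             stringsAsFactors = FALSE)
}

## Exact null distribution of the Mann-Whitney U statistic: counts[u + 1] is
## the number of the choose(n + m, n) rank assignments giving U = u,
## u = 0..n*m. Recurrence f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u).
.uCounts <- function(n, m) {
  prev <- matrix(0, nrow = m + 1L, ncol = n * m + 1L)
  prev[, 1L] <- 1  # n' = 0: only U = 0
  for (np in seq_len(n)) {
    cur <- matrix(0, nrow = m + 1L, ncol = n * m + 1L)
    cur[1L, 1L] <- 1  # m' = 0
    for (mp in seq_len(m)) {
      shifted <- c(rep(0, mp), prev[mp + 1L, seq_len(n * m + 1L - mp)])
      cur[mp + 1L, ] <- shifted + cur[mp, ]
    }
    prev <- cur
  }
  prev[m + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided by default. In exact mode the null distribution of U is fully
#' enumerated by dynamic programming (feasible and tie-free only); in normal
#' mode a tie-corrected normal approximation with continuity correction is
#' used. \code{mode = "auto"} picks exact when n*m <= 10000 and the pooled
#' sample has no ties.
#'
#' @param x,y numeric samples, both nonempty.
#' @param mode "auto", "exact" or "normal".
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list: statistic (U, number of (x, y) pairs with x > y, ties
#'   counted 1/2), p_value, method, n (per-group sizes), mode.
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal"),
                            alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode); alternative <- match.arg(alternative)
  .assert(length(x) >= 1L && length(y) >= 1L, "both samples must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = n * m / 2, p_value = 1,
                method = "Wilcoxon rank-sum (degenerate)", n = c(n, m), mode = mode))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0L
  if (mode == "auto") mode <- if (n * m <= 10000 && !hasTies) "exact" else "normal"

  if (mode == "exact") {
    .assert(!hasTies, "exact mode requires tie-free samples")
    counts <- .uCounts(n, m)
    total <- sum(counts)
    pLower <- sum(counts[seq_len(U + 1L)]) / total
    pUpper <- sum(counts[(U + 1L):(n * m + 1L)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pLower, pUpper)),
                less = pLower, greater = pUpper)
    method <- "Wilcoxon rank-sum, exact enumeration"
  } else {
    mu <- n * m / 2
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tieCorr)
    if (sigma2 <= 0) {
      warning("zero variance under ties; p = 1")
      return(list(statistic = U, p_value = 1,
                  method = "Wilcoxon rank-sum (degenerate)", n = c(n, m), mode = mode))
    }
    cc <- switch(alternative, two.sided = sign(U - mu) * 0.5, less = -0.5, greater = 0.5)
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * pnorm(-abs(z))),
                less = pnorm(z), greater = pnorm(z, lower.tail = FALSE))
    method <- "Wilcoxon rank-sum, tie-corrected normal approximation"
  }
  list(statistic = U, p_value = p, method = method, n = c(n, m), mode = mode)
}

#' Exact binomial test
#'
#' Two-sided p-values use the small-P method: the sum of P(x) over all
#' outcomes x whose null probability does not exceed P(k) (up to a 1e-7
#' relative tolerance guarding floating-point equality at the observed
#' outcome). When k sits at the distribution's mode, every outcome qualifies
#' and p = 1. One-sided and central two-sided alternatives are available
#' behind the \code{alternative} flag.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @param alternative "two.sided" (small-P, default), "less", "greater" or
#'   "two.sided.central" (twice the smaller tail, capped at 1).
#' @return list: statistic (k), estimate (k/n), p_value, method, n.
#' @export
binomialTest <- function(k, n, p0,
                         alternative = c("two.sided", "less", "greater",
                                         "two.sided.central")) {
  alternative <- match.arg(alternative)
  .assert(k >= 0 && k <= n, "k must lie in 0..n")
  .assert(p0 > 0 && p0 < 1, "p0 must lie in (0, 1)")
  d <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    two.sided = sum(d[d <= d[k + 1L] * (1 + 1e-7)]),
    less = sum(d[seq_len(k + 1L)]),
    greater = sum(d[(k + 1L):(n + 1L)]),
    two.sided.central = min(1, 2 * min(sum(d[seq_len(k + 1L)]),
                                       sum(d[(k + 1L):(n + 1L)]))))
  list(statistic = k, estimate = k / n, p_value = min(1, p),
       method = sprintf("exact binomial (%s)", alternative), n = n)
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric enumeration over the table's support; the two-sided
#' p-value uses the small-P method (sum of outcome probabilities not
#' exceeding the observed one).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param alternative "two.sided" (default), "greater" or "less" (on the
#'   [1,1] cell).
#' @return list: p_value, method.
#' @export
fisherExact <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .assert(all(dim(tab) == c(2L, 2L)) && all(tab >= 0), "tab must be a 2x2 count table")
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(r1 + r2, c1)
  pr <- exp(logp)
  obs <- pr[support == a]
  p <- switch(alternative,
    two.sided = sum(pr[pr <= obs * (1 + 1e-7)]),
    greater = sum(pr[support >= a]),
    less = sum(pr[support <= a]))
  list(p_value = min(1, p), method = sprintf("Fisher exact (%s)", alternative))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, q_(i) =
#' min_{j >= i} p_(j) * n / j, capped at 1. Monotone non-decreasing along the
#' sorted p-values by construction.
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values in the original order.
#' @export
bhAdjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric())
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

#' Over-representation analysis across gene sets
#'
#' One-sided Fisher exact enrichment (hypergeometric upper tail) of a hit
#' list against each gene set, with Benjamini-Hochberg adjustment across
#' sets. Gene sets and hits are intersected with the universe first.
#'
#' @param geneHits character vector of hit gene ids (subset of universe).
#' @param geneSets named list of character vectors.
#' @param universe character vector defining the testable gene universe.
#' @return data.frame: gene_set, set_size, n_hits, overlap, p_value, q_value,
#'   sorted by p.
#' @export
overrepresentation <- function(geneHits, geneSets, universe) {
  .assert(length(universe) > 0L, "empty gene universe")
  universe <- unique(universe)
  geneHits <- intersect(unique(geneHits), universe)
  N <- length(universe); nH <- length(geneHits)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(set); k <- length(intersect(geneHits, set))
    p <- if (K == 0L || nH == 0L) 1 else
      phyper(k - 1, K, N - K, nH, lower.tail = FALSE)
    data.frame(gene_set = nm, set_size = K, n_hits = nH, overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(v) v[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Inheritance-mode distribution of disrupted genes, with AR binomial test
#'
#' Over the distinct phenotype-linked genes carrying at least one record of
#' the requested category, counts genes per inheritance mode (a gene with k
#' modes contributes to k counts) and tests whether the proportion of AR
#' genes differs from the background AR proportion among all phenotype-linked
#' genes (\code{\link{inheritanceBackground}}), via the exact two-sided
#' binomial test.
#'
#' @param records data.frame from \code{\link{classifyCallset}}.
#' @param annotations data.frame from \code{\link{joinAnnotations}}.
#' @param category one of "gene_disrupting", "intragenic", "gene_spanning",
#'   or "any".
#' @param background optional data.frame from
#'   \code{\link{inheritanceBackground}}; computed from \code{annotations}
#'   when NULL.
#' @return list: table (mode, n_genes, percent over distinct phenotype-linked
#'   genes hit), n_genes (that distinct count), ar_test
#'   (\code{\link{binomialTest}} result).
#' @export
inheritanceDistribution <- function(records, annotations, category = "any",
                                    background = NULL) {
  sel <- if (identical(category, "any")) rep(TRUE, nrow(records))
         else records$category == category
  genesHit <- unique(records$gene_id[sel])
  ann <- annotations[annotations$gene_id %in% genesHit &
                       annotations$omim_status == "phenotype_linked", , drop = FALSE]
  .assert(nrow(ann) > 0L, "no phenotype-linked genes hit in this category")
  modes <- .splitModes(ann$inheritance_modes)
  counts <- vapply(INHERITANCE_MODES, function(m)
    sum(vapply(modes, function(v) m %in% v, logical(1))), numeric(1))
  tab <- data.frame(mode = INHERITANCE_MODES, n_genes = unname(counts),
                    percent = 100 * unname(counts) / nrow(ann),
                    stringsAsFactors = FALSE)
  if (is.null(background)) background <- inheritanceBackground(annotations)
  p0 <- background$proportion[background$mode == "AR"]
  arTest <- if (p0 > 0 && p0 < 1)
    binomialTest(counts[["AR"]], nrow(ann), p0)
  else list(statistic = counts[["AR"]], estimate = counts[["AR"]] / nrow(ann),
            p_value = NA_real_, method = "degenerate background", n = nrow(ann))
  list(table = tab, n_genes = nrow(ann), ar_test = arTest)
}
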