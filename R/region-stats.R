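#' Promoter region partition
#'
#' The four half-open relative-position regions used for region-wise CpG
#' frequency comparisons: R1 = \[0, +500) (TSS into the first exon),
#' R2 = \[-500, 0), R3 = \[-1000, -500), R4 = \[-3000, -1000). Position 0
#' (the TSS base) belongs to R1; a dinucleotide belongs to the region of its
#' first base.
#'
#' @param starts,ends integer vectors of half-open interval bounds.
#' @param labels region labels.
#' @return a data.frame with columns \code{region}, \code{start}, \code{end}.
#' @export
regionPartition <- function(starts = c(0, -500, -1000, -3000),
                            ends = c(500, 0, -500, -1000),
                            labels = c("R1", "R2", "R3", "R4")) {
  if (length(starts) != length(ends) || length(starts) != length(labels))
    stop("starts, ends and labels must have equal length")
  if (any(starts >= ends)) stop("each region must satisfy start < end")
  o <- order(starts)
  if (any(ends[o][-length(o)] > starts[o][-1]))
    stop("regions must be disjoint")
  data.frame(region = labels, start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

#' Per-gene CpG frequency per promoter region
#'
#' For each gene and region, the fraction of dinucleotide start positions
#' (first base inside the region) that begin the motif, computed on raw,
#' unsmoothed counts. Ambiguous bases are excluded from the denominator;
#' (gene, region) pairs with no covered position emit no row.
#'
#' @param windows a [PromoterWindows] object.
#' @param partition a [regionPartition()].
#' @param motif the 2-mer counted (default \code{"CG"}).
#' @return a data.frame with columns \code{gene_id}, \code{region},
#'   \code{cpg_freq}, \code{n_positions}.
#' @export
regionFrequencyTable <- function(windows, partition = regionPartition(),
                                 motif = "CG") {
  if (length(windows) == 0L) stop("no windows")
  seqs <- windowSequences(windows)
  ids <- names(windows)
  o <- tssOffset(windows)
  L <- Biostrings::width(seqs)
  nACGT <- rowSums(letterFrequency(seqs, c("A", "C", "G", "T")))
  clean <- nACGT == L

  out <- vector("list", nrow(partition))
  for (r in seq_len(nrow(partition))) {
    a <- partition$start[r]
    b <- partition$end[r]
    pa <- pmax(a, -o)                 # first dinuc start position in region
    pbex <- pmin(b, L - 1L - o)       # exclusive upper bound
    npos <- pbex - pa
    sel <- which(npos > 0L)
    if (length(sel) == 0L) next
    sub <- subseq(seqs[sel], start = pa[sel] + o[sel] + 1L,
                  end = pbex[sel] + o[sel] + 1L)
    cnt <- vcountPattern(motif, sub)
    den <- npos[sel]
    dirty <- sel[!clean[sel]]
    if (length(dirty) > 0L) {
      # exact N handling for windows carrying ambiguous bases
      for (k in dirty) {
        ind <- motifIndicator(as.character(seqs[[k]]), motif)
        idx <- (pa[k] + o[k] + 1L):(pbex[k] + o[k])
        j <- which(sel == k)
        cnt[j] <- sum(ind[idx], na.rm = TRUE)
        den[j] <- sum(!is.na(ind[idx]))
      }
    }
    keep <- den > 0L
    out[[r]] <- data.frame(
      gene_id = ids[sel][keep], region = partition$region[r],
      cpg_freq = cnt[keep] / den[keep], n_positions = den[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), region = character(0),
                      cpg_freq = numeric(0), n_positions = integer(0))
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis rank test
#'
#' H computed with mid-ranks for ties and the standard tie-correction
#' divisor \code{1 - sum(t^3 - t) / (N^3 - N)}; p from the chi-square
#' distribution with k - 1 degrees of freedom. When every pooled value is
#' identical, H = 0 and p = 1.
#'
#' @param groups a list (ideally named) of k >= 2 numeric vectors.
#' @return list with \code{statistic} (H), \code{df}, \code{p.value},
#'   \code{n} (per-group sizes) and \code{meanRanks}.
#' @export
kruskalWallis <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 1L)) stop("each group needs at least 1 value")
  N <- sum(n)
  if (N < 3L) stop("need at least 3 values in total")
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), n)
  r <- rank(v)
  Rsum <- tapply(r, g, sum)
  H0 <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  t <- table(v)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H0 / C
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  list(statistic = H, df = k - 1L, p.value = p,
       n = setNames(as.integer(n), nm),
       meanRanks = setNames(as.numeric(Rsum / n), nm))
}

#' Dunn's post-hoc pairwise rank comparisons
#'
#' For each group pair, \code{z = (Rbar_i - Rbar_j) / SE} with
#' \code{SE = sqrt((N(N+1)/12 - sum(t^3 - t) / (12(N-1))) (1/n_i + 1/n_j))}
#' on the pooled mid-ranks, two-sided normal p-values, and the configured
#' multiple-comparison adjustment over the k(k-1)/2 pairs (none by default).
#'
#' @param groups a named list of k >= 2 numeric vectors.
#' @param method p-adjustment over pairs: \code{"none"} (default),
#'   \code{"bonferroni"} or \code{"holm"}.
#' @return data.frame with columns \code{group1}, \code{group2}, \code{z},
#'   \code{p.value}, \code{p.adjusted}, \code{n1}, \code{n2}.
#' @export
dunnPosthoc <- function(groups, method = c("none", "bonferroni", "holm")) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  N <- sum(n)
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), n)
  r <- rank(v)
  Rbar <- tapply(r, g, mean)
  t <- table(v)
  varTerm <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pairs <- combn(k, 2L)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]
    j <- pairs[2, c]
    se <- sqrt(varTerm * (1 / n[i] + 1 / n[j]))
    z[c] <- if (se > 0) (Rbar[i] - Rbar[j]) / se else 0
    p[c] <- min(1, 2 * pnorm(-abs(z[c])))
  }
  padj <- p.adjust(p, method = method)
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = z, p.value = p, p.adjusted = padj,
             n1 = as.integer(n[pairs[1, ]]), n2 = as.integer(n[pairs[2, ]]),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Statistic is the rank sum of \code{x} under pooled mid-ranks. The
#' two-sided p-value is exact (full enumeration of rank assignments, doubled
#' one-sided tail capped at 1) when \code{nx + ny <= exactLimit} with no
#' ties, and otherwise a normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) enumeration;
#'   \code{NULL} (default) decides by size and ties.
#' @param exactLimit maximum pooled size for enumeration (default 20).
#' @return list with \code{statistic} (rank sum of x), \code{p.value},
#'   \code{exact}, \code{n}.
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL, exactLimit = 20L) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples need at least 1 value")
  N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- if (is.null(exact)) N <= exactLimit && !ties else isTRUE(exact)
  if (useExact && ties)
    stop("exact enumeration requires tie-free data")
  if (useExact) {
    cmb <- combn(N, nx)
    rs <- colSums(matrix(seq_len(N)[cmb], nrow = nx))
    p <- min(1, 2 * min(mean(rs <= W), mean(rs >= W)))
    return(list(statistic = W, p.value = p, exact = TRUE,
                n = c(nx = nx, ny = ny)))
  }
  E <- nx * (N + 1) / 2
  t <- table(c(x, y))
  V <- nx * ny / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (V <= 0) {
    p <- 1
  } else {
    zc <- max(abs(W - E) - 0.5, 0) / sqrt(V)
    p <- min(1, 2 * pnorm(-zc))
  }
  list(statistic = W, p.value = p, exact = FALSE, n = c(nx = nx, ny = ny))
}

#' Bonferroni adjustment
#'
#' \code{p_adj = min(1, m p)} for a family of m tests.
#'
#' @param pvals numeric p-values.
#' @param m family size; must be at least \code{length(pvals)}.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("family size m smaller than number of tests")
  pmin(1, m * pvals)
}

# Compact letter display (insert-and-absorb): groups sharing a letter are
# not significantly different.
.letterGroups <- function(groupNames, sigPairs) {
  sets <- list(groupNames)
  if (NROW(sigPairs) > 0) {
    for (r in seq_len(NROW(sigPairs))) {
      a <- sigPairs[r, 1]
      b <- sigPairs[r, 2]
      newSets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          newSets <- c(newSets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          newSets <- c(newSets, list(s))
        }
      }
      # absorb subsets and duplicates
      newSets <- newSets[lengths(newSets) > 0]
      keep <- rep(TRUE, length(newSets))
      for (i in seq_along(newSets)) {
        for (j in seq_along(newSets)) {
          if (i != j && keep[j] &&
              all(newSets[[i]] %in% newSets[[j]]) &&
              (length(newSets[[i]]) < length(newSets[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      sets <- newSets[keep]
    }
  }
  lets <- letters[seq_along(sets)]
  out <- vapply(groupNames, function(g) {
    paste(lets[vapply(sets, function(s) g %in% s, TRUE)], collapse = "")
  }, "")
  out
}

#' Region-wise Kruskal-Wallis comparison across functional classes
#'
#' For every region of the partition: a Kruskal-Wallis test over the
#' per-gene CpG frequencies of the class gene sets, Bonferroni-corrected
#' over the regions; Dunn's post-hoc pairwise comparisons (and compact
#' letter codes at \code{alpha}) are reported only for regions whose
#' adjusted Kruskal-Wallis p is below \code{alpha}. Classes with fewer than
#' two genes in a region are dropped; a region with fewer than two populated
#' classes is skipped with a warning.
#'
#' @param freqTable a [regionFrequencyTable()].
#' @param classSets named list: class -> gene ids (see [uniqueClassSets()]).
#' @param partition a [regionPartition()].
#' @param alpha significance level (default 0.05).
#' @param family Bonferroni family size (default: number of regions).
#' @param dunnAdjust p-adjustment over Dunn pairs (default \code{"none"}).
#' @return list with elements \code{kruskal} (data.frame: region, statistic,
#'   df, p.value, p.adjusted, significant), \code{dunn} (per-region
#'   data.frames) and \code{letters} (per-region named letter codes).
#' @export
classRegionAnalysis <- function(freqTable, classSets,
                                partition = regionPartition(), alpha = 0.05,
                                family = nrow(partition),
                                dunnAdjust = "none") {
  kw <- data.frame(region = character(0), statistic = numeric(0),
                   df = integer(0), p.value = numeric(0))
  groupsByRegion <- list()
  for (r in seq_len(nrow(partition))) {
    reg <- partition$region[r]
    sub <- freqTable[freqTable$region == reg, ]
    groups <- lapply(classSets, function(ids)
      sub$cpg_freq[sub$gene_id %in% ids])
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) {
      warning("region ", reg, " skipped: fewer than 2 populated classes")
      next
    }
    res <- kruskalWallis(groups)
    kw <- rbind(kw, data.frame(region = reg, statistic = res$statistic,
                               df = res$df, p.value = res$p.value))
    groupsByRegion[[reg]] <- groups
  }
  if (nrow(kw) == 0L) stop("no region could be tested")
  kw$p.adjusted <- bonferroniAdjust(kw$p.value, m = family)
  kw$significant <- kw$p.adjusted < alpha
  dunn <- list()
  lettersOut <- list()
  for (reg in kw$region[kw$significant]) {
    d <- dunnPosthoc(groupsByRegion[[reg]], method = dunnAdjust)
    dunn[[reg]] <- d
    sig <- d[d$p.adjusted < alpha, c("group1", "group2"), drop = FALSE]
    lettersOut[[reg]] <- .letterGroups(names(groupsByRegion[[reg]]),
                                       as.matrix(sig))
  }
  rownames(kw) <- NULL
  list(kruskal = kw, dunn = dunn, letters = lettersOut)
}

#' Region-wise Wilcoxon comparison of a focal gene set
#'
#' Per region: Wilcoxon rank-sum test of the focal genes against all
#' remaining genes, Bonferroni-corrected over the regions, with the
#' direction of the difference (mean-rank of focal vs background).
#'
#' @param freqTable a [regionFrequencyTable()].
#' @param focalSet character vector of focal gene ids.
#' @param partition a [regionPartition()].
#' @param alpha significance level.
#' @param family Bonferroni family size (default: number of regions).
#' @return data.frame with one row per region: \code{region}, \code{n_focal},
#'   \code{n_background}, \code{statistic}, \code{p.value},
#'   \code{p.adjusted}, \code{significant}, \code{direction}.
#' @export
setRegionAnalysis <- function(freqTable, focalSet,
                              partition = regionPartition(), alpha = 0.05,
                              family = nrow(partition)) {
  rows <- vector("list", nrow(partition))
  for (r in seq_len(nrow(partition))) {
    reg <- partition$region[r]
    sub <- freqTable[freqTable$region == reg, ]
    inF <- sub$gene_id %in% focalSet
    x <- sub$cpg_freq[inF]
    y <- sub$cpg_freq[!inF]
    if (length(x) == 0L) stop("focal set covers no gene in region ", reg)
    if (length(y) == 0L) stop("empty complement in region ", reg,
                              ": focal set spans the whole gene list")
    res <- wilcoxonRankSum(x, y)
    rk <- rank(c(x, y))
    dir <- mean(rk[seq_along(x)]) - mean(rk[-seq_along(x)])
    rows[[r]] <- data.frame(
      region = reg, n_focal = length(x), n_background = length(y),
      statistic = res$statistic, p.value = res$p.value,
      direction = if (dir > 0) "higher" else if (dir < 0) "lower" else "equal",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p.adjusted <- bonferroniAdjust(out$p.value, m = family)
  out$significant <- out$p.adjusted < alpha
  rownames(out) <- NULL
  out[, c("region", "n_focal", "n_background", "statistic", "p.value",
          "p.adjusted", "significant", "direction")]
}
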