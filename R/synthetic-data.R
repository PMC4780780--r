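#' Synthetic genome configuration
#'
#' Generative parameters for a fully synthetic test genome with a known,
#' position-dependent CpG observed/expected (o/e) profile: a background
#' o/e level far upstream with a linear enrichment ramp from
#' \code{rampStart} to the TSS (reaching \code{rampPeakFactor} times the
#' background and staying at the peak through the first exon), optional
#' multiplicative class- and focal-set-specific o/e offsets over stated
#' intervals, and plus/minus-strand gene placement on multiple scaffolds.
#'
#' The defaults mirror the study conditions the profiling pipeline targets:
#' uniform base composition, background CpG o/e 0.6 (a typical
#' invertebrate-genome depletion level), ramp from -2000 bp reaching 1.38x
#' at the TSS, and an even strand split.
#'
#' @param nGenes number of genes.
#' @param scaffoldLen scaffold length in bp; genes are packed per scaffold.
#' @param intergenicGap bases of random intergenic sequence between gene
#'   territories.
#' @param baseFreqs named A,C,G,T fractions summing to 1.
#' @param rhoBackground background CpG o/e level (>= 0).
#' @param rampStart relative position where the enrichment ramp begins.
#' @param rampPeakFactor multiplier reached at the TSS.
#' @param classes class labels genes are drawn from (uniformly); default the
#'   five KEGG classes.
#' @param classRhoOffsets named list: class -> \code{list(factor=, interval=
#'   c(lo, hi))}, a multiplicative o/e offset over a half-open interval.
#' @param focalFraction fraction of genes flagged as the focal set.
#' @param focalRhoOffset \code{list(factor=, interval=)} applied to focal
#'   genes, or NULL.
#' @param multiclassFraction fraction of genes given a second KEGG class in
#'   the written map (they drop out of unique-class sets).
#' @param minusStrandFraction fraction of minus-strand genes.
#' @param upstreamLen,downstreamLen window extent (3000 / 500).
#' @param seed RNG seed; all outputs are reproducible from it.
#' @return a list with class \code{"SyntheticGenomeConfig"}.
#' @export
syntheticGenomeConfig <- function(nGenes = 1000L, scaffoldLen = 200000L,
                                  intergenicGap = 1000L,
                                  baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                  rhoBackground = 0.6, rampStart = -2000L,
                                  rampPeakFactor = 1.38,
                                  classes = keggClassVocabulary(),
                                  classRhoOffsets = list(),
                                  focalFraction = 0, focalRhoOffset = NULL,
                                  multiclassFraction = 0,
                                  minusStrandFraction = 0.5,
                                  upstreamLen = 3000L, downstreamLen = 500L,
                                  seed = 1L) {
  baseFreqs <- .checkBaseFreqs(baseFreqs)
  if (rhoBackground < 0) stop("rhoBackground must be >= 0")
  if (rampPeakFactor < 0) stop("rampPeakFactor must be >= 0")
  if (rampStart >= 0 || rampStart < -upstreamLen)
    stop("rampStart must lie in [-upstreamLen, 0)")
  cfg <- structure(
    list(nGenes = as.integer(nGenes), scaffoldLen = as.integer(scaffoldLen),
         intergenicGap = as.integer(intergenicGap), baseFreqs = baseFreqs,
         rhoBackground = rhoBackground, rampStart = as.integer(rampStart),
         rampPeakFactor = rampPeakFactor, classes = classes,
         classRhoOffsets = classRhoOffsets, focalFraction = focalFraction,
         focalRhoOffset = focalRhoOffset,
         multiclassFraction = multiclassFraction,
         minusStrandFraction = minusStrandFraction,
         upstreamLen = as.integer(upstreamLen),
         downstreamLen = as.integer(downstreamLen), seed = as.integer(seed)),
    class = "SyntheticGenomeConfig"
  )
  # generability of every class/focal rho track under the emission model
  pos <- seq(-cfg$upstreamLen, cfg$downstreamLen - 1L)
  combos <- expand.grid(class = c(NA_character_, classes),
                        focal = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    rho <- rhoProfile(cfg, pos, class = combos$class[i], focal = combos$focal[i])
    .checkGenerable(rho, baseFreqs)
  }
  cfg
}

#' Positional CpG observed/expected profile
#'
#' The generative o/e level at one or more relative positions: the
#' background level up to \code{rampStart}, linear interpolation up to
#' \code{rampPeakFactor * rhoBackground} at the TSS, constant at the peak
#' through \[0, downstreamLen), multiplied by any class or focal offset
#' whose interval covers the position.
#'
#' @param config a [syntheticGenomeConfig()].
#' @param position integer vector of relative positions.
#' @param class class label of the gene (or NA/NULL for none).
#' @param focal whether the gene is in the focal set.
#' @return numeric vector of o/e values.
#' @export
rhoProfile <- function(config, position, class = NULL, focal = FALSE) {
  rs <- config$rampStart
  pk <- config$rampPeakFactor
  fac <- ifelse(position <= rs, 1,
                ifelse(position < 0, 1 + (pk - 1) * (position - rs) / (0 - rs), pk))
  rho <- config$rhoBackground * fac
  if (!is.null(class) && !is.na(class) && class %in% names(config$classRhoOffsets)) {
    off <- config$classRhoOffsets[[class]]
    inside <- position >= off$interval[1] & position < off$interval[2]
    rho[inside] <- rho[inside] * off$factor
  }
  if (isTRUE(focal) && !is.null(config$focalRhoOffset)) {
    off <- config$focalRhoOffset
    inside <- position >= off$interval[1] & position < off$interval[2]
    rho[inside] <- rho[inside] * off$factor
  }
  rho
}

# Shared generability check for the marginal-preserving Markov emission.
.checkGenerable <- function(rho, baseFreqs) {
  fC <- baseFreqs[["C"]]
  fG <- baseFreqs[["G"]]
  if (fC >= 1 || fG >= 1)
    stop("ungenerable configuration: f_C and f_G must be < 1")
  if (max(rho) * fG > 1 + 1e-12 || max(rho) * fC > 1 + 1e-12)
    stop("ungenerable configuration: rho(x) * f_G (and rho(x) * f_C) must be <= 1")
  # positivity of the compensating post-non-C distribution
  if (fC * (1 - min(rho) * fG) > (1 - fG) + 1e-12)
    stop("ungenerable configuration: base composition cannot compensate rho")
  invisible(TRUE)
}

# First-order Markov sequence emission for n genes sharing one rho track.
# After a C the next base is G with probability rho(position of the C)*f_G,
# with the remaining mass shared by A, C, T in proportion to their base
# frequencies; after any other base the distribution is the compensating one
# that keeps the marginal frequency of every base at baseFreqs exactly, so
# P(CpG start at x) = f_C * rho(x) * f_G holds exactly at every position.
# Consumes runif(n) once per position regardless of content, so the RNG
# stream is layout-stable.
.simulateCodes <- function(n, rho, baseFreqs) {
  L <- length(rho) + 1L  # rho is indexed by the position of the preceding base
  .checkGenerable(rho, baseFreqs)
  fA <- baseFreqs[["A"]]
  fC <- baseFreqs[["C"]]
  fG <- baseFreqs[["G"]]
  cum <- cumsum(baseFreqs)
  codes <- matrix(0L, nrow = n, ncol = L)
  codes[, 1L] <- findInterval(runif(n), cum, left.open = TRUE) + 1L
  for (j in 2:L) {
    u <- runif(n)
    r <- rho[j - 1L]
    pG <- r * fG                      # P(G | prev C)
    sC <- (1 - pG) / (1 - fG)         # A,C,T scale after a C
    if (fC > 0) {
      qG <- fG * (1 - fC * r) / (1 - fC)  # P(G | prev not C), marginal-preserving
      sN <- (1 - fC * sC) / (1 - fC)      # A,C,T scale after a non-C
    } else {
      qG <- fG
      sN <- 1
    }
    cA <- fA * sC
    cC <- cA + fC * sC
    cG <- cC + pG
    nA <- fA * sN
    nC <- nA + fC * sN
    nG <- nC + qG
    prevC <- codes[, j - 1L] == 2L
    b <- ifelse(prevC,
      ifelse(u < cA, 1L, ifelse(u < cC, 2L, ifelse(u < cG, 3L, 4L))),
      ifelse(u < nA, 1L, ifelse(u < nC, 2L, ifelse(u < nG, 3L, 4L))))
    codes[, j] <- b
  }
  codes
}

#' Simulate one promoter window sequence
#'
#' Emits a single window of \code{upstreamLen + downstreamLen} bases under
#' the configuration's positional o/e model (optionally with a class/focal
#' offset) using the current RNG state; seed management is left to the
#' caller.
#'
#' Emission is a first-order Markov chain conditioning only on whether the
#' preceding base is C: after a C the next base is G with probability
#' \code{rho(x) * f_G} (x the position of the C); after any other base the
#' distribution is the compensating one that keeps every per-position base
#' marginal exactly at \code{baseFreqs}. Consequently the CpG start
#' probability at position x is exactly \code{f_C * rho(x) * f_G} and the
#' windowed observed/expected CpG ratio recovers \code{rho}.
#'
#' @param config a [syntheticGenomeConfig()].
#' @param class,focal gene attributes selecting o/e offsets.
#' @return a character string of length \code{upstreamLen + downstreamLen}.
#' @export
simulatePromoter <- function(config, class = NULL, focal = FALSE) {
  pos <- seq(-config$upstreamLen, config$downstreamLen - 1L)
  rho <- rhoProfile(config, pos, class = class, focal = focal)
  # rho for emission is indexed at the dinucleotide start (the C), i.e. the
  # first L-1 positions
  codes <- .simulateCodes(1L, rho[-length(rho)], config$baseFreqs)
  .collapseRows(codes)
}

# Draw gene attributes and emit all windows (grouped by shared rho track).
.simulateWindowSet <- function(config) {
  n <- config$nGenes
  strand <- ifelse(runif(n) < config$minusStrandFraction, "-", "+")
  cls <- if (length(config$classes) > 0)
    sample(config$classes, n, replace = TRUE) else rep(NA_character_, n)
  focal <- runif(n) < config$focalFraction
  extra <- runif(n) < config$multiclassFraction
  ids <- sprintf("g%05d", seq_len(n))
  pos <- seq(-config$upstreamLen, config$downstreamLen - 1L)
  key <- paste(cls, focal)
  seqsChr <- character(n)
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    rho <- rhoProfile(config, pos, class = cls[idx[1]], focal = focal[idx[1]])
    codes <- .simulateCodes(length(idx), rho[-length(rho)], config$baseFreqs)
    seqsChr[idx] <- .collapseRows(codes)
  }
  genes <- data.frame(gene_id = ids, class = cls, focal = focal,
                      multiclass = extra, strand = strand,
                      stringsAsFactors = FALSE)
  seqs <- DNAStringSet(seqsChr)
  names(seqs) <- ids
  list(genes = genes,
       windows = PromoterWindows(seqs, tssOffset = config$upstreamLen,
                                 fullUpstream = TRUE, strand = strand))
}

#' Simulate promoter windows with known truth
#'
#' Seeds the RNG from the configuration and emits \code{nGenes} promoter
#' windows (with class / focal / strand labels) without genome embedding -
#' the direct route for testing the profiling and statistics stages.
#'
#' @param config a [syntheticGenomeConfig()].
#' @return list with \code{windows} (a [PromoterWindows]) and \code{genes}
#'   (a data.frame of per-gene labels).
#' @export
simulatePromoterWindows <- function(config) {
  set.seed(config$seed)
  .simulateWindowSet(config)
}

#' Simulate a complete synthetic dataset
#'
#' Generates promoter windows with known truth, embeds them in
#' multi-scaffold genome sequences (minus-strand genes as reverse
#' complements, random intergenic sequence between territories), and builds
#' the matching gene annotation, KEGG class map and focal gene list.
#' Re-extracting windows from the genome with [extractPromoterWindows()]
#' reproduces each generated window exactly.
#'
#' When \code{dir} is given, standard files are written: \code{genome.fa},
#' \code{genes.gff3}, \code{kegg_map.tsv}, \code{focal_set.txt} and
#' \code{truth.json} (all generative parameters and per-gene labels; the
#' data are synthetic, no real genome is involved).
#'
#' @param config a [syntheticGenomeConfig()].
#' @param dir output directory, or NULL to keep everything in memory.
#' @return list with \code{genome} (DNAStringSet), \code{genes} (GRanges
#'   with \code{gene_id}, \code{tss}), \code{windows} (truth
#'   [PromoterWindows]), \code{geneTable} (per-gene labels), \code{kegg}
#'   (data.frame), \code{focalSet} (character) and \code{config}.
#' @export
simulateDataset <- function(config, dir = NULL) {
  set.seed(config$seed)
  sim <- .simulateWindowSet(config)
  genes <- sim$genes
  n <- config$nGenes
  winLen <- config$upstreamLen + config$downstreamLen
  gap <- config$intergenicGap
  per <- (config$scaffoldLen - gap) %/% (winLen + gap)
  if (per < 1L)
    stop("scaffold too short for the gene layout (need >= ",
         winLen + 2L * gap, " bp)")
  scafIdx <- (seq_len(n) - 1L) %/% per + 1L
  slot <- (seq_len(n) - 1L) %% per
  sliceStart0 <- gap + slot * (winLen + gap)
  nScaf <- max(scafIdx)
  scafNames <- sprintf("scaffold_%03d", seq_len(nScaf))

  winChr <- as.character(windowSequences(sim$windows))
  minus <- genes$strand == "-"
  embed <- winChr
  if (any(minus))
    embed[minus] <- as.character(reverseComplement(DNAStringSet(winChr[minus])))

  scafs <- character(nScaf)
  for (s in seq_len(nScaf)) {
    onS <- which(scafIdx == s)
    nFill <- config$scaffoldLen - length(onS) * (winLen + gap)
    fillLen <- c(rep(gap, length(onS)), nFill + gap)  # gap before each gene + tail
    fillTot <- sum(fillLen)
    fillStr <- .collapseRows(matrix(
      sample.int(4L, fillTot, replace = TRUE, prob = config$baseFreqs),
      nrow = 1L))
    ends <- cumsum(fillLen)
    starts <- c(1, ends[-length(ends)] + 1)
    pieces <- character(2L * length(onS) + 1L)
    for (g in seq_along(onS)) {
      pieces[2L * g - 1L] <- substring(fillStr, starts[g], ends[g])
      pieces[2L * g] <- embed[onS[g]]
    }
    pieces[2L * length(onS) + 1L] <-
      substring(fillStr, starts[length(fillLen)], ends[length(fillLen)])
    scafs[s] <- paste(pieces, collapse = "")
  }
  genome <- DNAStringSet(scafs)
  names(genome) <- scafNames

  tss0 <- ifelse(minus, sliceStart0 + config$downstreamLen - 1L,
                 sliceStart0 + config$upstreamLen)
  gffStart1 <- ifelse(minus, tss0 + 1L - (config$downstreamLen - 1L), tss0 + 1L)
  gffEnd1 <- ifelse(minus, tss0 + 1L, tss0 + config$downstreamLen)
  gr <- GRanges(
    seqnames = scafNames[scafIdx],
    ranges = IRanges(start = gffStart1, end = gffEnd1),
    strand = genes$strand
  )
  gr$gene_id <- genes$gene_id
  gr$tss <- as.integer(tss0)

  kegg <- data.frame(gene_id = genes$gene_id, class = genes$class,
                     stringsAsFactors = FALSE)
  kegg <- kegg[!is.na(kegg$class), ]
  if (any(genes$multiclass) && length(config$classes) > 1L) {
    mg <- genes[genes$multiclass & !is.na(genes$class), ]
    if (nrow(mg) > 0L) {
      second <- vapply(mg$class, function(cl)
        sample(setdiff(config$classes, cl), 1L), "")
      kegg <- rbind(kegg, data.frame(gene_id = mg$gene_id, class = second,
                                     stringsAsFactors = FALSE))
    }
  }
  kegg <- kegg[order(kegg$gene_id, kegg$class), ]
  rownames(kegg) <- NULL
  focalSet <- genes$gene_id[genes$focal]

  out <- list(genome = genome, genes = gr, windows = sim$windows,
              geneTable = genes, kegg = kegg, focalSet = focalSet,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeXStringSet(genome, file.path(dir, "genome.fa"))
    gffLines <- c("##gff-version 3",
      sprintf("%s\tpromoterCpG_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              scafNames[scafIdx], gffStart1, gffEnd1, genes$strand,
              genes$gene_id))
    writeLines(gffLines, file.path(dir, "genes.gff3"))
    write.table(kegg, file.path(dir, "kegg_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(focalSet, file.path(dir, "focal_set.txt"))
    truth <- c(unclass(config)[setdiff(names(config), "classRhoOffsets")],
               list(classRhoOffsets = config$classRhoOffsets,
                    genes = cbind(genes, scaffold = scafNames[scafIdx],
                                  tss = as.integer(tss0))))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}
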