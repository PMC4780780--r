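#' Profile configuration
#'
#' Collects the tunable parameters of the density profiler: the 2-mer motif,
#' the odd moving-average window width (51 by default, a standard smoothing
#' scale for dinucleotide density), the normalization mode, the smoothing
#' kernel, and the relative-position range retained around the TSS.
#'
#' Normalization modes: \code{"gc_fraction"} divides the motif frequency by
#' the windowed G+C fraction; \code{"obs_over_exp"} divides by the product
#' of the windowed C and G mononucleotide fractions (the classical CpG
#' observed/expected ratio); \code{"none"} reports the raw frequency.
#'
#' @param motif a 2-mer over A,C,G,T (default \code{"CG"}).
#' @param width odd positive moving-average width (default 51).
#' @param normalization one of \code{"gc_fraction"}, \code{"obs_over_exp"},
#'   \code{"none"}.
#' @param kernel \code{"uniform"} (simple moving average, the default) or
#'   \code{"triangular"} for sensitivity checks.
#' @param range numeric length-2, half-open relative-position range kept,
#'   default \code{c(-3000, 500)}.
#' @return a list with class \code{"ProfileConfig"}.
#' @export
profileConfig <- function(motif = "CG", width = 51L,
                          normalization = c("gc_fraction", "obs_over_exp", "none"),
                          kernel = c("uniform", "triangular"),
                          range = c(-3000, 500)) {
  normalization <- match.arg(normalization)
  kernel <- match.arg(kernel)
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  if (nchar(motif) != 2L || !all(.splitBases(motif) %in% c("A", "C", "G", "T")))
    stop("motif must be a 2-mer over A,C,G,T")
  if (length(range) != 2L || range[1] >= range[2]) stop("invalid position range")
  structure(
    list(motif = motif, width = width, normalization = normalization,
         kernel = kernel, range = as.integer(range)),
    class = "ProfileConfig"
  )
}

#' Dinucleotide indicator vector
#'
#' Entry p (1-based) is 1 iff \code{seq[p..p+1] == motif}; entries where
#' either base is ambiguous (not A/C/G/T) are \code{NA} and are excluded
#' from moving-average denominators downstream.
#'
#' @param seq a character string or [Biostrings::DNAString].
#' @param motif a 2-mer.
#' @return numeric vector of length \code{nchar(seq) - 1}.
#' @export
motifIndicator <- function(seq, motif = "CG") {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < 2L) stop("sequence shorter than 2 bases")
  x <- .splitBases(toupper(seq))
  ok <- x %in% c("A", "C", "G", "T")
  m <- .splitBases(motif)
  ind <- as.numeric(x[-L] == m[1] & x[-1] == m[2])
  ind[!(ok[-L] & ok[-1])] <- NA_real_
  ind
}

# Core per-gene profile: returns NULL when the window is too short, else a
# list of aligned vectors at positions with a full centered window inside
# the sequence and the configured range.
.profileOne <- function(s, offset0, cfg) {
  x <- .splitBases(toupper(s))
  L <- length(x)
  w <- cfg$width
  if (L < w + 1L) return(NULL)
  h <- (w - 1L) %/% 2L
  ok <- x %in% c("A", "C", "G", "T")
  m <- .splitBases(cfg$motif)
  hit <- as.numeric(x[-L] == m[1] & x[-1] == m[2])
  okd <- as.numeric(ok[-L] & ok[-1])
  hit[okd == 0] <- 0
  gcv <- as.numeric((x == "G" | x == "C") & ok)
  okb <- as.numeric(ok)

  if (cfg$kernel == "uniform") {
    wsum <- function(v) .movingSum(v, w)
  } else {
    wts <- (h + 1 - abs(seq(-h, h))) / (h + 1)
    wsum <- function(v) .weightedMovingSum(v, wts)
  }
  nd <- L - w                      # number of dinucleotide windows
  num <- wsum(hit)                 # length nd (dinucleotide track is L-1 long)
  den <- wsum(okd)
  gcn <- wsum(gcv)[seq_len(nd)]    # base track windows, aligned on centers
  bden <- wsum(okb)[seq_len(nd)]

  raw <- ifelse(den > 0, num / den, NA_real_)
  gcf <- ifelse(bden > 0, gcn / bden, NA_real_)
  centers <- (1L + h):(L - 1L - h)           # 1-based base index of window center
  pos <- centers - (offset0 + 1L)            # relative to TSS

  if (cfg$normalization == "obs_over_exp") {
    cv <- as.numeric(x == "C" & ok)
    gv <- as.numeric(x == "G" & ok)
    fC <- ifelse(bden > 0, wsum(cv)[seq_len(nd)] / bden, NA_real_)
    fG <- ifelse(bden > 0, wsum(gv)[seq_len(nd)] / bden, NA_real_)
    denom <- fC * fG
  } else if (cfg$normalization == "gc_fraction") {
    denom <- gcf
  } else {
    denom <- rep(1, nd)
  }
  norm <- ifelse(!is.na(denom) & denom > 0, raw / denom, NA_real_)

  keep <- pos >= cfg$range[1] & pos < cfg$range[2] & !is.na(raw)
  list(pos = pos[keep], raw = raw[keep], gc = gcf[keep], norm = norm[keep])
}

#' Per-gene moving-average density profile
#'
#' Computes the motif frequency, G+C fraction and normalized density of a
#' single promoter window as centered moving averages of width
#' \code{config$width}. Positions whose centered window is not fully inside
#' the sequence are absent (no edge padding); ambiguous bases reduce window
#' denominators.
#'
#' @param window a length-1 [PromoterWindows], or a character sequence (then
#'   \code{tssOffset} must be given).
#' @param config a [profileConfig()].
#' @param tssOffset 0-based TSS index when \code{window} is a character.
#' @return a [DensityProfile] (single gene; \code{nGenes} is 1 everywhere).
#' @export
windowedProfile <- function(window, config = profileConfig(), tssOffset = NULL) {
  if (is(window, "PromoterWindows")) {
    if (length(window) != 1L)
      stop("windowedProfile() profiles one gene; use profileWindows() for sets")
    s <- as.character(windowSequences(window))[1]
    offset0 <- tssOffset(window)[1]
  } else {
    if (is.null(tssOffset)) stop("tssOffset required for a bare sequence")
    s <- as.character(window)
    offset0 <- as.integer(tssOffset)
  }
  p <- .profileOne(s, offset0, config)
  if (is.null(p))
    stop("window shorter than width + 1 (", config$width + 1L, " bases)")
  DensityProfile(p$pos, p$raw, p$gc, p$norm, rep(1L, length(p$pos)),
                 motif = config$motif, config = unclass(config))
}

#' Normalize a raw motif frequency
#'
#' @param rawFreq numeric raw motif frequency (or vector).
#' @param gcFraction matching G+C fraction, used in \code{"gc_fraction"} mode.
#' @param mode normalization mode; see [profileConfig()].
#' @param fC,fG windowed mononucleotide fractions for \code{"obs_over_exp"}.
#' @return normalized density; positions with a zero denominator are NA.
#' @export
normalizeDensity <- function(rawFreq, gcFraction = NULL,
                             mode = c("gc_fraction", "obs_over_exp", "none"),
                             fC = NULL, fG = NULL) {
  mode <- match.arg(mode)
  denom <- switch(mode,
    none = rep(1, length(rawFreq)),
    gc_fraction = gcFraction,
    obs_over_exp = fC * fG
  )
  if (is.null(denom)) stop("missing denominator inputs for mode ", mode)
  ifelse(!is.na(denom) & denom > 0, rawFreq / denom, NA_real_)
}

#' Aggregate per-gene profiles into a mean profile
#'
#' At each relative position the unweighted mean over genes having a value
#' there; \code{nGenes} records the contributing count and positions with no
#' contributing gene are absent. Normalized densities are averaged over the
#' genes where they are defined.
#'
#' @param profiles a non-empty list of [DensityProfile] objects.
#' @return an aggregated [DensityProfile].
#' @export
aggregateMeanProfile <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  rng <- range(unlist(lapply(profiles, profilePositions)))
  acc <- .newAccumulator(rng[1], rng[2])
  for (p in profiles)
    acc <- .accumulate(acc, profilePositions(p), rawFreq(p), gcFraction(p),
                       normDensity(p), geneCounts(p))
  .finishAccumulator(acc, motif = profiles[[1]]@motif,
                     config = profiles[[1]]@config)
}

.newAccumulator <- function(pmin, pmax) {
  n <- pmax - pmin + 1L
  list(pmin = pmin, n = n,
       sraw = numeric(n), sgc = numeric(n), snorm = numeric(n),
       craw = integer(n), cgc = integer(n), cnorm = integer(n))
}

.accumulate <- function(acc, pos, raw, gc, norm, weight = 1L) {
  i <- pos - acc$pmin + 1L
  okr <- !is.na(raw)
  acc$sraw[i[okr]] <- acc$sraw[i[okr]] + raw[okr] * weight[okr]
  acc$craw[i[okr]] <- acc$craw[i[okr]] + weight[okr]
  okg <- !is.na(gc)
  acc$sgc[i[okg]] <- acc$sgc[i[okg]] + gc[okg] * weight[okg]
  acc$cgc[i[okg]] <- acc$cgc[i[okg]] + weight[okg]
  okn <- !is.na(norm)
  acc$snorm[i[okn]] <- acc$snorm[i[okn]] + norm[okn] * weight[okn]
  acc$cnorm[i[okn]] <- acc$cnorm[i[okn]] + weight[okn]
  acc
}

.finishAccumulator <- function(acc, motif, config) {
  keep <- acc$craw > 0L
  pos <- (acc$pmin:(acc$pmin + acc$n - 1L))[keep]
  DensityProfile(
    pos,
    acc$sraw[keep] / acc$craw[keep],
    ifelse(acc$cgc[keep] > 0L, acc$sgc[keep] / acc$cgc[keep], NA_real_),
    ifelse(acc$cnorm[keep] > 0L, acc$snorm[keep] / acc$cnorm[keep], NA_real_),
    acc$craw[keep],
    motif = motif, config = if (is.list(config)) config else list()
  )
}

#' Aggregated density profile of a window set
#'
#' The main profiling pipeline: per-gene moving-average profiles (see
#' [windowedProfile()]) accumulated into a cross-gene mean profile without
#' materializing the per-gene profiles. Genes shorter than \code{width + 1}
#' are skipped with one summary warning.
#'
#' @param windows a [PromoterWindows] object.
#' @param config a [profileConfig()].
#' @return an aggregated [DensityProfile].
#' @export
profileWindows <- function(windows, config = profileConfig()) {
  if (length(windows) == 0L) stop("no windows to profile")
  seqs <- as.character(windowSequences(windows))
  offs <- tssOffset(windows)
  acc <- .newAccumulator(config$range[1], config$range[2] - 1L)
  skipped <- 0L
  for (k in seq_along(seqs)) {
    p <- .profileOne(seqs[k], offs[k], config)
    if (is.null(p)) {
      skipped <- skipped + 1L
      next
    }
    one <- rep(1L, length(p$pos))
    acc <- .accumulate(acc, p$pos, p$raw, p$gc, p$norm, one)
  }
  if (skipped > 0L)
    warning(skipped, " window(s) shorter than width + 1 skipped")
  if (all(acc$craw == 0L)) stop("no positions populated by any window")
  .finishAccumulator(acc, motif = config$motif, config = unclass(config))
}

#' TSS enrichment ratio
#'
#' Ratio of the mean normalized density near the TSS to the far-upstream
#' background level; with the defaults, mean over \[-100, 0) divided by mean
#' over \[-3000, -2000) - the scale on which mammalian-style TSS-proximal
#' CpG enrichment is usually quoted.
#'
#' @param profile an aggregated [DensityProfile].
#' @param near,background numeric length-2 half-open relative intervals.
#' @return a single fold-change value.
#' @export
tssEnrichmentRatio <- function(profile, near = c(-100, 0),
                               background = c(-3000, -2000)) {
  pos <- profilePositions(profile)
  nd <- normDensity(profile)
  iN <- pos >= near[1] & pos < near[2] & !is.na(nd)
  iB <- pos >= background[1] & pos < background[2] & !is.na(nd)
  if (!any(iN) || !any(iB))
    stop("near or background interval contains no populated positions")
  bg <- mean(nd[iB])
  if (bg <= 0) stop("background mean density is zero")
  mean(nd[iN]) / bg
}

#' Write a profile as TSV
#'
#' @param profile a [DensityProfile].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
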