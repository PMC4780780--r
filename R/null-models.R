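#' Genome-wide base frequencies
#'
#' Fractions of A, C, G, T over all scaffolds; ambiguity codes are excluded
#' from the denominator.
#'
#' @param genome a [Biostrings::DNAStringSet] or character vector.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
genomeBaseFrequencies <- function(genome) {
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  counts <- colSums(letterFrequency(genome, c("A", "C", "G", "T")))
  tot <- sum(counts)
  if (tot == 0) stop("genome contains no unambiguous bases")
  counts / tot
}

#' Configuration for randomized control gene models
#'
#' Randomized controls emulate the genome's composition, not its gene
#' structure: each model is an i.i.d. upstream domain drawn from the genome
#' base frequencies followed by a first exon of i.i.d. codons drawn from a
#' codon usage table.
#'
#' @param nModels number of control models (default 20000, the size of the
#'   control set plotted against the real gene profiles).
#' @param upstreamLen,exonLen lengths of the two domains (3000 / 500).
#' @param baseFreqs named A,C,G,T fractions summing to 1 (default uniform).
#' @param codonUsage named codon-fraction vector (see [computeCodonUsage()];
#'   default uniform over the 64 codons).
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return a list with class \code{"NullModelConfig"}.
#' @export
nullModelConfig <- function(nModels = 20000L, upstreamLen = 3000L, exonLen = 500L,
                            baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            codonUsage = NULL, seed = 1L) {
  baseFreqs <- .checkBaseFreqs(baseFreqs)
  if (is.null(codonUsage))
    codonUsage <- setNames(rep(1 / 64, 64), .allCodons())
  if (any(codonUsage < 0) || sum(codonUsage) <= 0)
    stop("degenerate codon usage table")
  if (abs(sum(codonUsage) - 1) > 1e-9)
    stop("codon usage fractions must sum to 1")
  if (nModels < 1L) stop("nModels must be >= 1")
  structure(
    list(nModels = as.integer(nModels), upstreamLen = as.integer(upstreamLen),
         exonLen = as.integer(exonLen), baseFreqs = baseFreqs,
         codonUsage = codonUsage, seed = as.integer(seed)),
    class = "NullModelConfig"
  )
}

#' Generate randomized control gene models
#'
#' Each model is a window of \code{upstreamLen + exonLen} bases with the TSS
#' at index \code{upstreamLen}: upstream bases i.i.d. from
#' \code{baseFreqs}, exon a concatenation of i.i.d. codons from
#' \code{codonUsage} truncated to \code{exonLen} bases (167 codons minus the
#' final base at the default 500).
#'
#' @param config a [nullModelConfig()].
#' @return a [PromoterWindows] of \code{nModels} full-upstream plus-strand
#'   windows named \code{null_}\emph{k}.
#' @export
generateRandomizedModels <- function(config = nullModelConfig()) {
  stopifnot(inherits(config, "NullModelConfig"))
  set.seed(config$seed)
  n <- config$nModels
  up <- matrix(
    sample.int(4L, n * config$upstreamLen, replace = TRUE, prob = config$baseFreqs),
    nrow = n
  )
  upStr <- .collapseRows(up)
  nCodons <- ceiling(config$exonLen / 3)
  cod <- matrix(
    sample(names(config$codonUsage), n * nCodons, replace = TRUE,
           prob = config$codonUsage),
    nrow = n
  )
  exStr <- substr(apply(cod, 1L, paste, collapse = ""), 1L, config$exonLen)
  seqs <- DNAStringSet(paste0(upStr, exStr))
  names(seqs) <- sprintf("null_%05d", seq_len(n))
  PromoterWindows(seqs, tssOffset = config$upstreamLen,
                  fullUpstream = TRUE, strand = "+")
}

#' Mirror-image GpC control profile
#'
#' The GpC density analysis of a window set. Profiling the reversed
#' sequences for CpG is algebraically identical to profiling the forward
#' sequences for GpC (position-reversed), so the mirror control is computed
#' with motif \code{"GC"} on the forward sequences and aggregated exactly
#' like the CpG profile.
#'
#' @param windows a [PromoterWindows] object.
#' @param config a [profileConfig()]; its motif is replaced by \code{"GC"}.
#' @return an aggregated [DensityProfile] for motif GC.
#' @export
mirrorControlProfile <- function(windows, config = profileConfig()) {
  config$motif <- "GC"
  profileWindows(windows, config)
}
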