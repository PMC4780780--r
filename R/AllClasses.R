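#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet letterFrequency oligonucleotideFrequency vcountPattern
#'   subseq
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges strand start end seqnames
#' @importFrom IRanges IRanges CharacterList
#' @importFrom stats pchisq pnorm runif p.adjust setNames filter
#' @importFrom utils combn read.delim write.table
NULL

#' TSS-anchored promoter sequence windows
#'
#' A \code{PromoterWindows} object holds one sequence window per gene, read
#' 5'->3' in the gene's transcriptional orientation (minus-strand genes are
#' reverse-complemented at extraction time). The TSS base sits at 0-based
#' index \code{tssOffset} within each window; a window whose scaffold carried
#' all requested upstream bases has \code{fullUpstream = TRUE}.
#'
#' @slot seqs a [Biostrings::DNAStringSet] named by gene id.
#' @slot tssOffset integer, 0-based index of the TSS base in each window
#'   (3000 when the full upstream domain is present at the default widths).
#' @slot fullUpstream logical, whether all requested upstream bases exist.
#' @slot strand character, \code{"+"} or \code{"-"} per gene.
#'
#' @export
setClass("PromoterWindows",
  slots = c(
    seqs = "DNAStringSet",
    tssOffset = "integer",
    fullUpstream = "logical",
    strand = "character"
  )
)

setValidity("PromoterWindows", function(object) {
  n <- length(object@seqs)
  if (length(object@tssOffset) != n || length(object@fullUpstream) != n ||
      length(object@strand) != n)
    return("slot lengths disagree")
  if (n > 0 && (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs))))
    return("windows must carry unique gene ids as names")
  if (!all(object@strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  w <- Biostrings::width(object@seqs)
  if (any(object@tssOffset < 0L) || any(object@tssOffset >= w))
    return("tssOffset must index a base inside each window")
  TRUE
})

#' Construct a PromoterWindows object
#'
#' @param seqs a [Biostrings::DNAStringSet] (or character vector) named by
#'   gene id.
#' @param tssOffset integer vector (recycled), 0-based index of the TSS base.
#' @param fullUpstream logical vector (recycled).
#' @param strand character vector (recycled), \code{"+"} or \code{"-"}.
#' @return a \code{PromoterWindows} object.
#' @export
PromoterWindows <- function(seqs, tssOffset, fullUpstream = TRUE, strand = "+") {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  n <- length(seqs)
  new("PromoterWindows",
    seqs = seqs,
    tssOffset = as.integer(rep_len(tssOffset, n)),
    fullUpstream = rep_len(as.logical(fullUpstream), n),
    strand = rep_len(as.character(strand), n)
  )
}

#' Per-position dinucleotide density profile
#'
#' Positions are relative to the TSS (position 0 = the TSS base); a
#' dinucleotide is indexed at its first base. \code{rawFreq} is the
#' moving-average motif frequency, \code{gcFraction} the moving-average G+C
#' fraction over the same centered window, and \code{normDensity} the
#' normalized density under the profile configuration's mode. \code{nGenes}
#' counts genes contributing a (non-missing) raw frequency at each position.
#'
#' @slot position integer, relative positions.
#' @slot rawFreq,gcFraction,normDensity numeric per-position values.
#' @slot nGenes integer per-position contributing gene counts.
#' @slot motif the profiled 2-mer.
#' @slot config the profile configuration list used.
#' @export
setClass("DensityProfile",
  slots = c(
    position = "integer",
    rawFreq = "numeric",
    gcFraction = "numeric",
    normDensity = "numeric",
    nGenes = "integer",
    motif = "character",
    config = "list"
  )
)

setValidity("DensityProfile", function(object) {
  n <- length(object@position)
  if (length(object@rawFreq) != n || length(object@gcFraction) != n ||
      length(object@normDensity) != n || length(object@nGenes) != n)
    return("slot lengths disagree")
  rf <- object@rawFreq[!is.na(object@rawFreq)]
  if (any(rf < 0 | rf > 1)) return("rawFreq outside [0,1]")
  gc <- object@gcFraction[!is.na(object@gcFraction)]
  if (any(gc < 0 | gc > 1)) return("gcFraction outside [0,1]")
  nd <- object@normDensity[!is.na(object@normDensity)]
  if (any(nd < 0) || any(!is.finite(nd))) return("normDensity must be finite and >= 0")
  if (any(object@nGenes < 0L)) return("nGenes must be >= 0")
  TRUE
})

#' @rdname DensityProfile-class
#' @param position,rawFreq,gcFraction,normDensity,nGenes aligned per-position
#'   vectors.
#' @param motif the profiled 2-mer.
#' @param config optional profile configuration list.
#' @export
DensityProfile <- function(position, rawFreq, gcFraction, normDensity, nGenes,
                           motif = "CG", config = list()) {
  new("DensityProfile",
    position = as.integer(position), rawFreq = as.numeric(rawFreq),
    gcFraction = as.numeric(gcFraction), normDensity = as.numeric(normDensity),
    nGenes = as.integer(nGenes), motif = motif, config = config
  )
}
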