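#' @rdname PromoterWindows-class
#' @param x,object a \code{PromoterWindows} object.
#' @export
setGeneric("windowSequences", function(x) standardGeneric("windowSequences"))

#' @rdname PromoterWindows-class
#' @export
setGeneric("tssOffset", function(x) standardGeneric("tssOffset"))

#' @rdname PromoterWindows-class
#' @export
setGeneric("fullUpstream", function(x) standardGeneric("fullUpstream"))

#' @rdname PromoterWindows-class
#' @export
setGeneric("windowStrand", function(x) standardGeneric("windowStrand"))

#' @rdname PromoterWindows-class
#' @export
setMethod("windowSequences", "PromoterWindows", function(x) x@seqs)

#' @rdname PromoterWindows-class
#' @export
setMethod("tssOffset", "PromoterWindows", function(x) x@tssOffset)

#' @rdname PromoterWindows-class
#' @export
setMethod("fullUpstream", "PromoterWindows", function(x) x@fullUpstream)

#' @rdname PromoterWindows-class
#' @export
setMethod("windowStrand", "PromoterWindows", function(x) x@strand)

#' @rdname PromoterWindows-class
#' @export
setMethod("length", "PromoterWindows", function(x) length(x@seqs))

#' @rdname PromoterWindows-class
#' @export
setMethod("names", "PromoterWindows", function(x) names(x@seqs))

#' @rdname PromoterWindows-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PromoterWindows", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  initialize(x,
    seqs = x@seqs[i], tssOffset = x@tssOffset[i],
    fullUpstream = x@fullUpstream[i], strand = x@strand[i]
  )
})

setMethod("show", "PromoterWindows", function(object) {
  n <- length(object)
  cat("PromoterWindows with", n, "windows\n")
  if (n > 0) {
    cat("  widths:", paste(range(Biostrings::width(object@seqs)), collapse = ".."),
        " tssOffset:", paste(unique(range(object@tssOffset)), collapse = ".."), "\n")
    cat("  full upstream:", sum(object@fullUpstream), "/", n,
        "  minus strand:", sum(object@strand == "-"), "\n")
  }
})

#' @rdname DensityProfile-class
#' @param x,object a \code{DensityProfile}.
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' @rdname DensityProfile-class
#' @export
setGeneric("rawFreq", function(x) standardGeneric("rawFreq"))

#' @rdname DensityProfile-class
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))

#' @rdname DensityProfile-class
#' @export
setGeneric("normDensity", function(x) standardGeneric("normDensity"))

#' @rdname DensityProfile-class
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname DensityProfile-class
#' @export
setMethod("profilePositions", "DensityProfile", function(x) x@position)

#' @rdname DensityProfile-class
#' @export
setMethod("rawFreq", "DensityProfile", function(x) x@rawFreq)

#' @rdname DensityProfile-class
#' @export
setMethod("gcFraction", "DensityProfile", function(x) x@gcFraction)

#' @rdname DensityProfile-class
#' @export
setMethod("normDensity", "DensityProfile", function(x) x@normDensity)

#' @rdname DensityProfile-class
#' @export
setMethod("geneCounts", "DensityProfile", function(x) x@nGenes)

#' @rdname DensityProfile-class
#' @export
setMethod("length", "DensityProfile", function(x) length(x@position))

setMethod("show", "DensityProfile", function(object) {
  cat("DensityProfile for motif", object@motif, "over",
      length(object@position), "positions\n")
  if (length(object@position) > 0) {
    cat("  position range:", min(object@position), "..", max(object@position), "\n")
    cat("  genes per position:", paste(range(object@nGenes), collapse = ".."), "\n")
  }
})

#' Coerce a DensityProfile to a data.frame
#'
#' One row per populated position with columns \code{position},
#' \code{n_genes}, \code{raw_freq}, \code{gc_fraction}, \code{norm_density} -
#' the package's profile TSV layout.
#'
#' @param x a \code{DensityProfile}.
#' @param row.names,optional,... passed through for generic compatibility.
#' @return a data.frame.
#' @export
as.data.frame.DensityProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    position = x@position, n_genes = x@nGenes, raw_freq = x@rawFreq,
    gc_fraction = x@gcFraction, norm_density = x@normDensity,
    row.names = row.names
  )
}

setMethod("as.data.frame", "DensityProfile", as.data.frame.DensityProfile)
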