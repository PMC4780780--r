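#' Read a multi-scaffold genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet] that trims FASTA
#' headers to the first whitespace-delimited token and upper-cases
#' soft-masked bases (masking is ignored throughout the package).
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a named [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Parse gene models from a GFF3 annotation
#'
#' Reads a GFF3-like annotation and returns one gene model per feature of
#' \code{featureType}, with the transcriptional start site (TSS) resolved
#' strand-aware: the feature's 5' end, stored as a 0-based genomic
#' coordinate of the first transcribed base (feature start - 1 on the plus
#' strand, feature end - 1 on the minus strand).
#'
#' Features without a usable strand or id are skipped with a warning;
#' duplicated gene ids are an error.
#'
#' @param path path to a GFF3 file.
#' @param featureType feature type to keep (column 3), default \code{"gene"}.
#' @param idAttr attribute holding the gene id, default \code{"ID"}.
#' @return a [GenomicRanges::GRanges] with metadata columns \code{gene_id}
#'   and \code{tss} (0-based).
#' @export
parseGeneModels <- function(path, featureType = "gene", idAttr = "ID") {
  gff <- rtracklayer::import(path, format = "gff3")
  gff <- gff[as.character(gff$type) == featureType]
  ids <- as.character(mcols(gff)[[idAttr]])
  str <- as.character(GenomicRanges::strand(gff))
  bad <- !(str %in% c("+", "-")) | is.na(ids) | ids == ""
  if (any(bad)) {
    warning(sum(bad), " gene feature(s) skipped (missing strand or id): ",
            paste(utils::head(ifelse(is.na(ids[bad]), "<no id>", ids[bad]), 5),
                  collapse = ", "))
    gff <- gff[!bad]
    ids <- ids[!bad]
    str <- str[!bad]
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)])[1:min(5, sum(duplicated(ids)))],
               collapse = ", "))
  mcols(gff) <- NULL
  gff$gene_id <- ids
  gff$tss <- ifelse(str == "+",
                    GenomicRanges::start(gff) - 1L,
                    GenomicRanges::end(gff) - 1L)
  gff
}

#' Attach functional labels to gene models
#'
#' @param genes a GRanges from [parseGeneModels()].
#' @param kegg a KEGG assignment (named list, see [loadKeggMap()]) or NULL.
#' @param focalSet character vector of focal gene ids, or NULL.
#' @return \code{genes} with added metadata columns \code{kegg_classes}
#'   (CharacterList) and \code{in_focal_set} (logical).
#' @export
annotateGeneModels <- function(genes, kegg = NULL, focalSet = NULL) {
  ids <- genes$gene_id
  cls <- if (is.null(kegg)) rep(list(character(0)), length(ids)) else {
    lapply(ids, function(i) if (is.null(kegg[[i]])) character(0) else kegg[[i]])
  }
  genes$kegg_classes <- IRanges::CharacterList(cls)
  genes$in_focal_set <- if (is.null(focalSet)) rep(FALSE, length(ids)) else ids %in% focalSet
  genes
}

#' Extract strand-aware TSS-anchored promoter windows
#'
#' Isolates the \code{upstream} bases 5' of each TSS plus \code{downstream}
#' bases starting at the TSS, read 5'->3' in the gene's transcriptional
#' orientation (minus-strand genes are reverse-complemented). Windows are
#' clipped at scaffold ends; truncation is recorded via \code{tssOffset}
#' (< upstream when upstream bases were missing) and \code{fullUpstream}.
#'
#' @param genome a named [Biostrings::DNAStringSet] of scaffolds.
#' @param genes a GRanges from [parseGeneModels()] (needs \code{gene_id},
#'   \code{tss} metadata columns and strand).
#' @param upstream,downstream window extent around the TSS (defaults 3000
#'   and 500, i.e. relative positions \[-3000, +500)).
#' @return a [PromoterWindows] object.
#' @export
extractPromoterWindows <- function(genome, genes, upstream = 3000L, downstream = 500L) {
  stopifnot(is(genome, "DNAStringSet"))
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  sc <- as.character(GenomicRanges::seqnames(genes))
  hit <- match(sc, names(genome))
  if (anyNA(hit)) {
    miss <- which(is.na(hit))[1]
    stop("scaffold '", sc[miss], "' for gene '", genes$gene_id[miss],
         "' not found in genome")
  }
  lens <- Biostrings::width(genome)[hit]
  tss <- as.integer(genes$tss)
  if (any(tss < 0L) || any(tss >= lens)) {
    b <- which(tss < 0L | tss >= lens)[1]
    stop("TSS of gene '", genes$gene_id[b], "' lies outside its scaffold")
  }
  str <- as.character(GenomicRanges::strand(genes))
  plus <- str == "+"
  # 0-based half-open genomic slice
  s0 <- ifelse(plus, pmax(0L, tss - upstream), pmax(0L, tss - downstream + 1L))
  e0 <- ifelse(plus, pmin(lens, tss + downstream), pmin(lens, tss + upstream + 1L))
  seqs <- subseq(genome[hit], start = s0 + 1L, end = e0)
  if (any(!plus))
    seqs[!plus] <- reverseComplement(seqs[!plus])
  names(seqs) <- genes$gene_id
  off <- ifelse(plus, tss - s0, e0 - 1L - tss)
  full <- ifelse(plus, tss - upstream >= 0L, tss + upstream <= lens - 1L)
  PromoterWindows(seqs, tssOffset = off, fullUpstream = full, strand = str)
}

#' Keep only windows with the full upstream domain
#'
#' @param windows a [PromoterWindows] object.
#' @return the subset (input order preserved) with \code{fullUpstream} TRUE.
#' @export
filterFullUpstream <- function(windows) {
  windows[which(fullUpstream(windows))]
}

#' Write / read promoter windows as FASTA
#'
#' Headers carry the window metadata as
#' \code{gene_id|strand|tssOffset|fullUpstream}.
#'
#' @param windows a [PromoterWindows] object.
#' @param path output (input) FASTA path.
#' @return \code{writeWindowsFasta} returns \code{path} invisibly;
#'   \code{readWindowsFasta} returns a [PromoterWindows].
#' @export
writeWindowsFasta <- function(windows, path) {
  s <- windowSequences(windows)
  names(s) <- paste(names(s), windowStrand(windows), tssOffset(windows),
                    fullUpstream(windows), sep = "|")
  writeXStringSet(s, path)
  invisible(path)
}

#' @rdname writeWindowsFasta
#' @export
readWindowsFasta <- function(path) {
  s <- readDNAStringSet(path)
  parts <- strsplit(names(s), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("malformed window FASTA header; expected gene_id|strand|offset|full")
  names(s) <- vapply(parts, `[`, "", 1L)
  PromoterWindows(s,
    tssOffset = as.integer(vapply(parts, `[`, "", 3L)),
    fullUpstream = as.logical(vapply(parts, `[`, "", 4L)),
    strand = vapply(parts, `[`, "", 2L)
  )
}

#' Compute a codon usage table from CDS sequences
#'
#' Counts every non-overlapping in-frame codon over all coding sequences and
#' normalizes to fractions. Codons containing ambiguous bases are excluded
#' from numerator and denominator; sequences whose length is not a multiple
#' of 3 are skipped with a warning.
#'
#' @param cds a [Biostrings::DNAStringSet] (or character vector) of CDSs.
#' @return named numeric vector of length 64 summing to 1.
#' @export
computeCodonUsage <- function(cds) {
  if (!is(cds, "DNAStringSet")) cds <- DNAStringSet(cds)
  bad <- Biostrings::width(cds) %% 3L != 0L
  if (any(bad)) {
    warning(sum(bad), " CDS(s) with length not divisible by 3 skipped")
    cds <- cds[!bad]
  }
  if (length(cds) == 0L) stop("no usable CDS sequences")
  counts <- colSums(oligonucleotideFrequency(cds, width = 3L, step = 3L))
  tot <- sum(counts)
  if (tot == 0) stop("no unambiguous codons found")
  counts / tot
}
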