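#' Top-level KEGG class vocabulary
#'
#' The five top-level KEGG functional classes used to group genes.
#'
#' @return character vector of class labels.
#' @export
keggClassVocabulary <- function() {
  c("Metabolism",
    "Environmental Information Processing",
    "Genetic Information Processing",
    "Cellular Processes",
    "Organismal Systems")
}

#' Load a gene-to-KEGG-class map
#'
#' Reads a two-column TSV (\code{gene_id}, \code{class}; header optional)
#' and unions rows for the same gene into its class set. A class outside the
#' vocabulary is a hard error naming the offending row.
#'
#' @param path TSV path.
#' @param vocabulary allowed class labels (default [keggClassVocabulary()]).
#' @return a named list: gene id -> character vector of classes.
#' @export
loadKeggMap <- function(path, vocabulary = keggClassVocabulary()) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             colClasses = "character")
  hasHeader <- identical(tolower(as.character(first[1, 1])), "gene_id")
  df <- utils::read.delim(path, header = hasHeader, colClasses = "character")
  if (ncol(df) < 2L) stop("KEGG map must have columns gene_id and class")
  names(df)[1:2] <- c("gene_id", "class")
  bad <- !(df$class %in% vocabulary)
  if (any(bad)) {
    row1 <- which(bad)[1]
    stop("unknown KEGG class '", df$class[row1], "' for gene '",
         df$gene_id[row1], "' (row ", row1, ")")
  }
  lapply(split(df$class, df$gene_id), function(x) sort(unique(x)))
}

#' Uniquely-assigned class gene sets
#'
#' Genes whose class set has exactly one member are grouped by that class;
#' multi-class and unassigned genes appear in no output set. Only these
#' uniquely assigned genes enter the between-class statistics.
#'
#' @param assignment a named list from [loadKeggMap()].
#' @param vocabulary class labels to report (every label gets a, possibly
#'   empty, gene list).
#' @return named list: class -> character vector of gene ids.
#' @export
uniqueClassSets <- function(assignment, vocabulary = keggClassVocabulary()) {
  single <- lengths(assignment) == 1L
  cls <- vapply(assignment[single], `[`, "", 1L)
  ids <- names(assignment)[single]
  out <- lapply(vocabulary, function(v) ids[cls == v])
  names(out) <- vocabulary
  out
}

#' Load a focal gene set
#'
#' One gene id per line; blank lines and \code{#} comments are ignored. Ids
#' absent from \code{knownIds} are dropped with a warning. An empty
#' resulting set is an error (a focal-set analysis needs at least one gene).
#'
#' @param path path to the id list.
#' @param knownIds character vector of valid gene ids, or NULL to skip the
#'   check.
#' @return character vector of gene ids.
#' @export
loadGeneSet <- function(path, knownIds = NULL) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[nzchar(x)])
  if (!is.null(knownIds)) {
    unknown <- setdiff(x, knownIds)
    if (length(unknown) > 0)
      warning(length(unknown), " unknown gene id(s) dropped: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    x <- intersect(x, knownIds)
  }
  if (length(x) == 0L) stop("focal gene set is empty")
  x
}
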