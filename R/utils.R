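# Internal numeric helpers shared across modules.

# Sliding-window sums of width w; element i is sum(v[i:(i+w-1)]).
.movingSum <- function(v, w) {
  cs <- cumsum(c(0, v))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

# Centered weighted sliding sums for an arbitrary symmetric kernel of odd
# length w; element i is sum(wts * v[i:(i+w-1)]) like .movingSum but weighted.
.weightedMovingSum <- function(v, wts) {
  w <- length(wts)
  out <- stats::filter(v, rev(wts), method = "convolution", sides = 2)
  # stats::filter centers the kernel; realign to window-start indexing
  h <- (w - 1L) %/% 2L
  as.numeric(out[(1L + h):(length(v) - h)])
}

# Collapse an integer code matrix (rows = sequences, codes 1..4 = A,C,G,T)
# into one character string per row.
.collapseRows <- function(codes, alphabet = c("A", "C", "G", "T")) {
  n <- nrow(codes)
  L <- ncol(codes)
  big <- paste(alphabet[t(codes)], collapse = "")
  substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

.splitBases <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.checkBaseFreqs <- function(baseFreqs) {
  if (length(baseFreqs) != 4L)
    stop("baseFreqs must have four entries (A, C, G, T)")
  if (is.null(names(baseFreqs))) names(baseFreqs) <- c("A", "C", "G", "T")
  baseFreqs <- baseFreqs[c("A", "C", "G", "T")]
  if (any(is.na(baseFreqs)) || any(baseFreqs < 0))
    stop("baseFreqs must be named A,C,G,T and non-negative")
  if (abs(sum(baseFreqs) - 1) > 1e-9)
    stop("baseFreqs must sum to 1")
  baseFreqs
}

.allCodons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b, stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}
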