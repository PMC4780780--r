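# Small in-code fixtures shared across test files.

# Write a FASTA file from a named character vector, return the path.
writeFastaFixture <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "genome.fa")
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- names(seqs)
  Biostrings::writeXStringSet(s, path)
  path
}

# Write a GFF3 file from a data.frame with columns seqid, start, end,
# strand, id (1-based inclusive coordinates), return the path.
writeGffFixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "genes.gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     df$seqid, df$start, df$end, df$strand, df$id))
  writeLines(lines, path)
  path
}

# Independent naive promoter extraction used as an oracle: plain character
# slicing plus a hand-rolled reverse complement.
naiveRevComp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

naiveExtract <- function(scaffold, tss0, strand, up = 3000, down = 500) {
  len <- nchar(scaffold)
  if (strand == "+") {
    s0 <- max(0, tss0 - up)
    e0 <- min(len, tss0 + down)
    substr(scaffold, s0 + 1, e0)
  } else {
    s0 <- max(0, tss0 - down + 1)
    e0 <- min(len, tss0 + up + 1)
    naiveRevComp(substr(scaffold, s0 + 1, e0))
  }
}

# Random DNA string of length n under the current RNG.
randomDna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Brute-force moving-average motif frequency at every full-window center,
# returned as a data.frame(pos, raw); the oracle for windowedProfile.
bruteProfile <- function(seq, motif = "CG", w = 51, offset0 = 0) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  h <- (w - 1) / 2
  ind <- integer(L - 1)
  miss <- logical(L - 1)
  for (i in seq_len(L - 1)) {
    d <- paste0(x[i], x[i + 1])
    miss[i] <- grepl("N", d)
    ind[i] <- as.integer(d == motif)
  }
  centers <- (1 + h):(L - 1 - h)
  raw <- vapply(centers, function(cc) {
    win <- (cc - h):(cc + h)
    ok <- !miss[win]
    if (!any(ok)) return(NA_real_)
    sum(ind[win][ok]) / sum(ok)
  }, numeric(1))
  data.frame(pos = centers - offset0 - 1, raw = raw)
}
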