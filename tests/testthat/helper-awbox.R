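# Shared test helpers: an independent naive scanner oracle and small
# sequence generators. The oracle shares no code with the package scanner.

BASES <- c("A", "C", "G", "T")

randomDNA <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force regex scan of one strand; returns 0-based window starts.
naiveCanonicalStarts <- function(seq) {
  L <- nchar(seq)
  if (L < 14) return(integer(0))
  starts <- integer(0)
  for (j in 0:(L - 14)) {
    w <- substr(seq, j + 1, j + 14)
    if (grepl("^C[ACGT]T[ACGT]G[ACGT]{7}CG$", w)) starts <- c(starts, j)
  }
  starts
}

# Strand-aware naive oracle mirroring the hit-table layout.
naiveScan <- function(seq, tisIndex) {
  L <- nchar(seq)
  plus <- naiveCanonicalStarts(seq)
  rcseq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  minus <- L - 14 - naiveCanonicalStarts(rcseq)
  toTis <- function(i) ifelse(i < tisIndex, i - tisIndex, i - tisIndex + 1)
  d <- rbind(
    data.frame(local_start = plus, strand = rep("+", length(plus))),
    data.frame(local_start = minus, strand = rep("-", length(minus)))
  )
  d <- d[order(d$local_start, d$strand), , drop = FALSE]
  d$local_start <- as.integer(d$local_start)
  d$tis_start <- as.integer(toTis(d$local_start))
  rownames(d) <- NULL
  d
}

# A canonical box embedded in fixed flanks, with known placement.
embedBox <- function(box, left = "AAAAA", right = "AAAAA") {
  paste0(left, box, right)
}
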