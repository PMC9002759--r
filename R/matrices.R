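# slot <-> N-position bookkeeping: N1..N9 live at motif slots 2,4,6..12.
.nSlot <- function(nIndex) {
  if (!all(nIndex %in% 1:9)) stop("N index must be in 1..9")
  .AW_N_SLOTS[nIndex]
}

.seqMatrix <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (any(nchar(seqs) != .AW_LEN))
    stop("all sequences must be canonical 14-mers")
  if (!all(isCanonicalBox(seqs)))
    stop("sequence violates the canonical pattern: ",
         seqs[which(!isCanonicalBox(seqs))[1L]])
  t(vapply(seqs, function(s) substring(s, 1:14, 1:14),
           character(.AW_LEN)))
}

#' Build a position frequency matrix from canonical AW boxes
#'
#' Tallies the base observed at each of the 14 motif slots across an
#' aligned set of canonical boxes. Fixed slots (1, 3, 5, 13, 14) carry all
#' mass on their fixed base by construction.
#'
#' @param seqs Character vector of canonical 14-mers.
#' @return A [PositionFrequencyMatrix-class].
#' @examples
#' buildPFM(c("CCTCGTGCATATCG", "CTTAGATTATATCG"))
#' @export
buildPFM <- function(seqs) {
  m <- .seqMatrix(seqs)
  counts <- vapply(.BASES, function(b) colSums(m == b), numeric(.AW_LEN))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("pos", 1:14), .BASES)
  new("PositionFrequencyMatrix", counts = counts,
      nSequences = length(seqs))
}

#' Forbidden bases and base bias per N position
#'
#' A base is "forbidden" at an N position when it is never observed there
#' among the training motifs (a zero count in the PFM — pseudocounts are
#' deliberately not applied, the zeros are the signal). The bias base is
#' the most frequent base; ties are reported as a set, never broken.
#'
#' @param pfm A [PositionFrequencyMatrix-class] with `nSequences >= 1`.
#' @return A [ForbiddenReport-class].
#' @examples
#' rep <- forbiddenAndBias(buildPFM(boundSequences()))
#' rep
#' @export
forbiddenAndBias <- function(pfm) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"))
  if (pfm@nSequences < 1L) stop("empty training set")
  forb <- list()
  bias <- list()
  for (k in 1:9) {
    cnt <- pfm@counts[.nSlot(k), ]
    forb[[paste0("N", k)]] <- .BASES[cnt == 0L]
    mx <- max(cnt)
    bias[[paste0("N", k)]] <- list(base = .BASES[cnt == mx],
                                   prob = mx / pfm@nSequences)
  }
  new("ForbiddenReport", forbidden = forb, bias = bias,
      nSequences = pfm@nSequences)
}

#' Position probability matrix from a PFM
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param pseudocount Added to every cell before normalising; each slot's
#'   probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' @return A [PositionProbabilityMatrix-class].
#' @examples
#' buildPPM(buildPFM(boundSequences()), pseudocount = 0.5)
#' @export
buildPPM <- function(pfm, pseudocount = 0) {
  stopifnot(is(pfm, "PositionFrequencyMatrix"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  n <- pfm@nSequences
  if (n == 0L) stop("cannot normalise a PFM over zero sequences")
  probs <- (pfm@counts + pseudocount) / (n + 4 * pseudocount)
  new("PositionProbabilityMatrix", probs = probs,
      pseudocount = as.numeric(pseudocount))
}

#' Position weight matrix (log2 odds) from a PPM
#'
#' @param ppm A [PositionProbabilityMatrix-class]. Zero probabilities
#'   (pseudocount 0) map to `-Inf`.
#' @param background Four base frequencies (A, C, G, T) summing to 1, all
#'   positive. Defaults to uniform; supply genomic frequencies to fit the
#'   motif to a species' base composition.
#' @return A [PositionWeightMatrix-class].
#' @export
buildPWM <- function(ppm, background = rep(0.25, 4)) {
  stopifnot(is(ppm, "PositionProbabilityMatrix"))
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 positive frequencies summing to 1")
  names(background) <- .BASES
  w <- log2(sweep(ppm@probs, 2L, background, "/"))
  new("PositionWeightMatrix", weights = w, background = background)
}

#' Log-odds score of a canonical box under a PWM
#'
#' @param pwm A [PositionWeightMatrix-class].
#' @param seq Character vector of 14-mers (need not be pattern-conformant;
#'   a mismatch at a fixed slot simply scores that slot's weight).
#' @return Numeric vector of scores in bits.
#' @export
scoreSequence <- function(pwm, seq) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  seq <- toupper(as.character(seq))
  if (any(nchar(seq) != .AW_LEN))
    stop("scored sequences must be 14-mers")
  vapply(seq, function(s) {
    ch <- substring(s, 1:14, 1:14)
    if (any(!ch %in% .BASES)) stop("invalid base in ", s)
    sum(pwm@weights[cbind(1:14, match(ch, .BASES))])
  }, numeric(1), USE.NAMES = FALSE)
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

.iupacCode <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC[key]
  if (is.na(code)) stop("no IUPAC code for empty base set")
  unname(code)
}

#' Derive a degenerate IUPAC consensus from a PPM
#'
#' Fixed slots emit their fixed base. Each N slot emits the minimal IUPAC
#' code covering all bases whose probability is at least
#' `includeThreshold`; in `bias-collapse` mode a slot whose top base
#' reaches `collapseThreshold` collapses to that single base instead,
#' which is how the strongly biased N2/N6 positions surface as plain C/A
#' in the motif.
#'
#' @param ppm A [PositionProbabilityMatrix-class] (typically pseudocount 0).
#' @param mode "bias-collapse" (default) or "inclusion" (no collapsing).
#' @param includeThreshold Minimum probability for a base to enter a
#'   slot's code, in (0, 1).
#' @param collapseThreshold Top-base probability at which a slot collapses
#'   to a single letter, in (0, 1).
#' @return A 14-character IUPAC string.
#' @examples
#' iupacConsensus(buildPPM(buildPFM(boundSequences())))  # "CHTCGWKWAYWYCG"
#' @export
iupacConsensus <- function(ppm, mode = c("bias-collapse", "inclusion"),
                           includeThreshold = 0.2, collapseThreshold = 0.6) {
  stopifnot(is(ppm, "PositionProbabilityMatrix"))
  mode <- match.arg(mode)
  if (includeThreshold <= 0 || includeThreshold >= 1 ||
      collapseThreshold <= 0 || collapseThreshold >= 1)
    stop("thresholds must lie in (0, 1)")
  out <- character(.AW_LEN)
  out[as.integer(names(.AW_FIXED))] <- .AW_FIXED
  for (slot in .AW_N_SLOTS) {
    p <- ppm@probs[slot, ]
    if (mode == "bias-collapse" && max(p) >= collapseThreshold) {
      out[slot] <- .BASES[which.max(p)]
      next
    }
    keep <- .BASES[p >= includeThreshold]
    if (!length(keep)) keep <- .BASES[which.max(p)]  # degenerate threshold
    out[slot] <- .iupacCode(keep)
  }
  paste(out, collapse = "")
}

#' Export matrices as TSV or MEME minimal motif format
#'
#' @param x A PFM, PPM or PWM object.
#' @param file Output path.
#' @param name Motif name for the MEME record.
#' @return Invisibly, `file`.
#' @name matrix-export
NULL

.matrixOf <- function(x) {
  if (is(x, "PositionFrequencyMatrix")) x@counts
  else if (is(x, "PositionProbabilityMatrix")) x@probs
  else if (is(x, "PositionWeightMatrix")) x@weights
  else stop("not a position matrix")
}

#' @rdname matrix-export
#' @export
writeMatrixTSV <- function(x, file) {
  m <- .matrixOf(x)
  write.table(data.frame(slot = rownames(m), m, check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname matrix-export
#' @export
writeMEME <- function(x, file, name = "AWbox") {
  if (is(x, "PositionFrequencyMatrix"))
    x <- buildPPM(x, pseudocount = 0)
  stopifnot(is(x, "PositionProbabilityMatrix"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       .AW_LEN)), con)
  writeLines(apply(x@probs, 1L, function(p)
    paste(sprintf("%.6f", p), collapse = " ")), con)
  invisible(file)
}

#' Text logo of a position probability matrix
#'
#' Prints, per slot, the bases ordered by probability with bar lengths
#' proportional to probability — a console stand-in for a graphical
#' sequence logo.
#'
#' @param ppm A [PositionProbabilityMatrix-class].
#' @param width Bar width in characters for probability 1.
#' @param file Optional path; when given, the logo is written there.
#' @return Invisibly, the logo lines.
#' @export
textLogo <- function(ppm, width = 40, file = NULL) {
  stopifnot(is(ppm, "PositionProbabilityMatrix"))
  lines <- vapply(1:14, function(slot) {
    p <- sort(ppm@probs[slot, ], decreasing = TRUE)
    p <- p[p > 0]
    bars <- paste(vapply(names(p), function(b)
      sprintf("%s%s", b, strrep("#", max(1L, round(p[b] * width)))),
      ""), collapse = " ")
    sprintf("%5s | %s", paste0("pos", slot), bars)
  }, "")
  if (is.null(file)) cat(lines, sep = "\n") else writeLines(lines, file)
  invisible(lines)
}
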