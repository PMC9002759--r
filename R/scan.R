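#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' accepts the ACGTN alphabet and is an involution.
#'
#' @param seq Character vector of DNA sequences (5'->3').
#' @return Character vector of reverse complements.
#' @examples
#' revComp("CGTCGTTGCCGACG")  # "CGTCGGCAACGACG"
#' @export
revComp <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("invalid character in sequence: ", seq[which(bad)[1L]])
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Test whether sequences are canonical AW boxes
#'
#' A canonical AW box is a 14-mer matching CNTNG(N)7CG: C at position 1,
#' T at 3, G at 5 and CG at 13-14, with any of A/C/G/T at the nine N
#' positions. Sequence 'N' characters never match.
#'
#' @param seq Character vector.
#' @return Logical vector.
#' @examples
#' isCanonicalBox("CCTCGTGCATATCG")   # TRUE
#' isCanonicalBox("CTTTAGGTTATATCG")  # FALSE (15-mer, extra base)
#' @export
isCanonicalBox <- function(seq) {
  seq <- toupper(as.character(seq))
  ok <- nchar(seq) == .AW_LEN & !grepl("[^ACGT]", seq)
  idx <- which(ok)
  for (i in idx) {
    ch <- substring(seq[i], 1:14, 1:14)
    ok[i] <- all(ch[as.integer(names(.AW_FIXED))] == .AW_FIXED)
  }
  ok
}

#' Enumerate valid insertion offsets of an extra-base AW box
#'
#' A 15-mer is an insertion-variant ("extra base") AW box when deleting
#' exactly one internal base restores the canonical pattern. Insertions
#' falling inside the fixed 5' C or between the bases of the 3' CG anchor
#' are not considered, so valid offsets lie in 2..13. Runs of identical
#' bases make several offsets equivalent; all are returned, in 5'->3'
#' order.
#'
#' @param seq A single 15-mer.
#' @return Integer vector of valid 1-based insertion offsets (possibly
#'   empty).
#' @examples
#' insertionOffsets("CTTTAGGTTATATCG")
#' @export
insertionOffsets <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) != .AW_LEN + 1L)
    stop("insertion-variant boxes are single 15-mers")
  if (grepl("[^ACGT]", seq)) return(integer(0))
  ch <- substring(seq, 1:15, 1:15)
  ok <- integer(0)
  for (d in 2:13) {
    rest <- ch[-d]
    if (all(rest[as.integer(names(.AW_FIXED))] == .AW_FIXED))
      ok <- c(ok, d)
  }
  ok
}

# Vectorised single-strand canonical scan of one character sequence.
# Returns 0-based window starts.
.canonicalStarts <- function(chars) {
  L <- length(chars)
  if (L < .AW_LEN) return(integer(0))
  n <- L - .AW_LEN + 1L
  i <- seq_len(n)
  hasN <- cumsum(c(0L, as.integer(chars == "N")))
  ok <- chars[i] == "C" & chars[i + 2L] == "T" & chars[i + 4L] == "G" &
    chars[i + 12L] == "C" & chars[i + 13L] == "G" &
    (hasN[i + .AW_LEN] - hasN[i]) == 0L
  which(ok) - 1L
}

# Single-strand insertion scan: 15-mer windows admitting >= 1 valid internal
# deletion. Returns data.frame(start0, offset) with the 5'-most valid offset.
.insertionStarts <- function(chars) {
  L <- length(chars)
  if (L < .AW_LEN + 1L) return(data.frame(start0 = integer(0), offset = integer(0)))
  n <- L - .AW_LEN
  i <- seq_len(n)
  hasN <- cumsum(c(0L, as.integer(chars == "N")))
  clean <- (hasN[i + .AW_LEN + 1L] - hasN[i]) == 0L
  best <- rep(NA_integer_, n)
  for (d in 13:2) {  # descending so the final write is the 5'-most offset
    p <- function(s) s + as.integer(s >= d)  # slot -> window position
    ok <- clean &
      chars[i + p(1L) - 1L] == "C" & chars[i + p(3L) - 1L] == "T" &
      chars[i + p(5L) - 1L] == "G" & chars[i + p(13L) - 1L] == "C" &
      chars[i + p(14L) - 1L] == "G"
    best[ok] <- d
  }
  keep <- !is.na(best)
  data.frame(start0 = which(keep) - 1L, offset = best[keep])
}

.emptyHits <- function() {
  data.frame(
    gene_id = character(0), local_start = integer(0), local_end = integer(0),
    tis_start = integer(0), tis_end = integer(0), strand = character(0),
    variant = character(0), insertion_offset = integer(0),
    matched_seq = character(0), stringsAsFactors = FALSE
  )
}

.scanOne <- function(seq, tisIndex, geneId, strands, maxInsertions) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L) return(.emptyHits())
  if (grepl("[^ACGTN]", seq))
    stop("invalid character in promoter sequence for ", geneId)
  rows <- list()
  add <- function(start0, width, strand, variant, offset, matched) {
    if (!length(start0)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = geneId, local_start = start0, local_end = start0 + width,
      tis_start = indexToTis(start0, tisIndex),
      tis_end = indexToTis(start0 + width - 1L, tisIndex),
      strand = strand, variant = variant, insertion_offset = offset,
      matched_seq = matched, stringsAsFactors = FALSE
    )
  }
  scanStrand <- function(s, strand) {
    ch <- substring(s, seq_len(nchar(s)), seq_len(nchar(s)))
    toCoding <- function(j0, w) if (strand == "+") j0 else L - j0 - w
    st <- .canonicalStarts(ch)
    add(toCoding(st, .AW_LEN), .AW_LEN, strand, "canonical", NA_integer_,
        vapply(st, function(j) substr(s, j + 1L, j + .AW_LEN), ""))
    if (maxInsertions >= 1L) {
      ins <- .insertionStarts(ch)
      add(toCoding(ins$start0, .AW_LEN + 1L), .AW_LEN + 1L, strand,
          "insertion", ins$offset,
          vapply(ins$start0, function(j) substr(s, j + 1L, j + .AW_LEN + 1L), ""))
    }
  }
  if (strands %in% c("both", "plus")) scanStrand(seq, "+")
  if (strands %in% c("both", "minus")) scanStrand(revComp(seq), "-")
  if (!length(rows)) return(.emptyHits())
  out <- do.call(rbind, rows)
  out[order(out$local_start, out$strand, out$variant), , drop = FALSE]
}

#' Scan promoter sequences for AW boxes
#'
#' Slides a window over each promoter (and, for minus-strand scanning, over
#' its reverse complement) reporting every match to the canonical pattern
#' CNTNG(N)7CG and, with `maxInsertions = 1`, every 15-mer that matches
#' after deleting one internal base (an "extra base" box). Windows
#' containing 'N' never match. Minus-strand hits report the TIS
#' coordinates of the occupied span on the coding strand, ascending, with
#' `matched_seq` as read 5'->3' on the matched strand.
#'
#' @param x A [PromoterSet-class], named character vector, or single string.
#' @param tisIndex 0-based TIS index (ignored for `PromoterSet`). Defaults
#'   to the sequence length (region ends just 5' of the ATG).
#' @param strands One of "both", "plus", "minus".
#' @param maxInsertions 0 (canonical only) or 1.
#' @param dedupe Collapse plus/minus hits occupying an identical
#'   coding-strand span (near-palindromic sites); both are reported by
#'   default.
#' @return A data.frame with columns `gene_id`, `local_start`/`local_end`
#'   (0-based half-open), `tis_start`/`tis_end` (signed, inclusive,
#'   ascending), `strand`, `variant`, `insertion_offset` (1-based position
#'   of the extra base within the matched span, 5'-most valid), and
#'   `matched_seq`; sorted by `local_start` then strand.
#' @examples
#' scanAWBox("AAAAACCTCGTGCATATCGAAAAA", tisIndex = 24)
#' @export
scanAWBox <- function(x, tisIndex = NULL, strands = c("both", "plus", "minus"),
                      maxInsertions = 0, dedupe = FALSE) {
  strands <- match.arg(strands)
  maxInsertions <- as.integer(maxInsertions)
  if (!maxInsertions %in% c(0L, 1L))
    stop("maxInsertions must be 0 or 1")
  if (is(x, "PromoterSet")) {
    seqs <- as.character(promoterSeqs(x))
    tis <- x@tisIndex
  } else {
    seqs <- toupper(as.character(x))
    if (is.null(names(seqs)))
      names(seqs) <- if (length(seqs) == 1L) "seq" else paste0("seq", seq_along(seqs))
    tis <- rep_len(if (is.null(tisIndex)) nchar(seqs) else as.integer(tisIndex),
                   length(seqs))
  }
  hits <- do.call(rbind, lapply(seq_along(seqs), function(k) {
    .scanOne(seqs[k], tis[k], names(seqs)[k], strands, maxInsertions)
  }))
  if (is.null(hits)) hits <- .emptyHits()
  if (dedupe && nrow(hits)) {
    key <- paste(hits$gene_id, hits$local_start, hits$local_end)
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Gate hits on distance to the TIS (and optionally the 5'-UTR)
#'
#' Active AW boxes lie close to the TIS, typically inside the 5'-UTR; this
#' applies the selection used when choosing motifs for binding assays:
#' a hit passes when the absolute value of its start coordinate is at most
#' `maxDistance` bp (inclusive) and, when `requireUtr5` is set and the
#' promoter carries a 5'-UTR annotation, the whole hit lies within the
#' 5'-UTR.
#'
#' @param hits A hit data.frame from [scanAWBox()] (or any frame with
#'   `tis_start`/`tis_end` columns).
#' @param maxDistance Inclusive distance bound in bp. The default, 500 bp,
#'   is the selection window used for the binding assays; 200 bp is the
#'   stricter literature-derived bound for active boxes.
#' @param requireUtr5 Require hits to lie inside the annotated 5'-UTR.
#' @param utr5Start Negative TIS coordinate of the 5'-UTR start, or NA when
#'   unannotated (the UTR condition is then skipped). Recycled over hits.
#' @return The hits with logical column `pass` and character column
#'   `reason` ("" when passed) appended.
#' @examples
#' h <- data.frame(tis_start = c(-110L, -900L), tis_end = c(-97L, -887L))
#' distanceGate(h, maxDistance = 500)$pass
#' @export
distanceGate <- function(hits, maxDistance = 500, requireUtr5 = FALSE,
                         utr5Start = NA_integer_) {
  maxDistance <- as.integer(maxDistance)
  utr5Start <- rep_len(as.integer(utr5Start), nrow(hits))
  pass <- rep(TRUE, nrow(hits))
  reason <- rep("", nrow(hits))
  far <- abs(hits$tis_start) > maxDistance
  pass[far] <- FALSE
  reason[far] <- sprintf("start %+d exceeds max distance %d bp from the TIS",
                         hits$tis_start[far], maxDistance)
  if (requireUtr5) {
    annotated <- !is.na(utr5Start)
    inUtr <- annotated & hits$tis_start >= utr5Start & hits$tis_end <= -1L
    out <- annotated & !inUtr & pass
    pass[out] <- FALSE
    reason[out] <- "hit not within the annotated 5'-UTR"
  }
  cbind(hits, pass = pass, reason = reason)
}
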