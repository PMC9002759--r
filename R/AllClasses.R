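#' PromoterSet: upstream regions with TIS annotation
#'
#' An S4 container for one or more promoter/upstream regions given on the
#' coding strand 5'->3', each with the promoter-local 0-based index of the
#' first base of its ATG and, optionally, the TIS-relative start of its
#' 5'-UTR (negative, i.e. the transcription start side).
#'
#' @slot sequences A [Biostrings::DNAStringSet] (alphabet ACGTN, uppercase),
#'   names are gene identifiers.
#' @slot tisIndex Integer vector, parallel to `sequences`.
#' @slot utr5Start Integer vector of negative TIS coordinates or NA.
#' @export
setClass("PromoterSet",
  representation(
    sequences = "DNAStringSet",
    tisIndex = "integer",
    utr5Start = "integer"
  )
)

setValidity("PromoterSet", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (is.null(names(object@sequences)) || anyNA(names(object@sequences)) ||
      any(names(object@sequences) == ""))
    msg <- c(msg, "sequences must be named by gene id")
  if (length(object@tisIndex) != n || length(object@utr5Start) != n)
    msg <- c(msg, "tisIndex and utr5Start must parallel sequences")
  else {
    if (anyNA(object@tisIndex) || any(object@tisIndex < 0L) ||
        any(object@tisIndex > Biostrings::width(object@sequences)))
      msg <- c(msg, "tisIndex must satisfy 0 <= tisIndex <= length(seq)")
    bad <- !is.na(object@utr5Start) & object@utr5Start >= 0L
    if (any(bad))
      msg <- c(msg, "utr5Start, when present, must be negative (upstream of TIS)")
  }
  chars <- unique(unlist(strsplit(as.character(object@sequences), "")))
  if (length(setdiff(chars, c("A", "C", "G", "T", "N"))) > 0L)
    msg <- c(msg, "sequence alphabet must be ACGTN (uppercase)")
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterSet
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   of coding-strand upstream sequences.
#' @param tisIndex Integer vector: 0-based index of the A of the ATG in each
#'   sequence (may equal the sequence length when the region stops just
#'   short of the ATG).
#' @param utr5Start Optional integer vector of negative TIS coordinates for
#'   the 5'-UTR start; NA when unannotated.
#' @return A [PromoterSet-class] object.
#' @examples
#' ps <- PromoterSet(c(g1 = "AAACCTCGTGCATATCGAAATG"), tisIndex = 19)
#' ps
#' @export
PromoterSet <- function(sequences, tisIndex, utr5Start = NA_integer_) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  n <- length(sequences)
  obj <- new("PromoterSet",
    sequences = sequences,
    tisIndex = rep_len(as.integer(tisIndex), n),
    utr5Start = rep_len(as.integer(utr5Start), n)
  )
  validObject(obj)
  obj
}

#' @describeIn PromoterSet-class Number of promoters.
#' @param x A `PromoterSet`.
#' @export
setMethod("length", "PromoterSet", function(x) length(x@sequences))

#' Accessors for PromoterSet
#'
#' `geneIds`, `promoterSeqs`, `tisIndex` and `utr5Start` extract the
#' corresponding annotation from a [PromoterSet-class].
#'
#' @param x A `PromoterSet`.
#' @return The requested annotation vector (or `DNAStringSet`).
#' @name promoter-accessors
NULL

#' @rdname promoter-accessors
#' @export
geneIds <- function(x) names(x@sequences)

#' @rdname promoter-accessors
#' @export
promoterSeqs <- function(x) x@sequences

#' @rdname promoter-accessors
#' @export
tisIndex <- function(x) setNames(x@tisIndex, geneIds(x))

#' @rdname promoter-accessors
#' @export
utr5Start <- function(x) setNames(x@utr5Start, geneIds(x))

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet with", length(object), "promoter(s)\n")
  n <- min(length(object), 5L)
  if (n > 0L) {
    w <- Biostrings::width(object@sequences)[seq_len(n)]
    cat(sprintf("  %-14s %6s nt  TIS index %s\n",
                geneIds(object)[seq_len(n)], w,
                object@tisIndex[seq_len(n)]), sep = "")
    if (length(object) > n) cat("  ...\n")
  }
})

#' Position matrices over the 14 AW-box slots
#'
#' `PositionFrequencyMatrix` holds per-slot base counts from an aligned set
#' of canonical 14-mers; `PositionProbabilityMatrix` the (optionally
#' pseudocounted) per-slot base probabilities; `PositionWeightMatrix` the
#' log2-odds of those probabilities against a background base composition.
#' Rows are motif slots 1..14, columns the bases A, C, G, T.
#'
#' @slot counts 14 x 4 nonnegative integer matrix.
#' @slot nSequences Number of sequences tallied.
#' @name PositionMatrices
#' @aliases PositionFrequencyMatrix-class PositionProbabilityMatrix-class
#'   PositionWeightMatrix-class
NULL

#' @export
setClass("PositionFrequencyMatrix",
  representation(counts = "matrix", nSequences = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
  m <- object@counts
  if (!all(dim(m) == c(14L, 4L)))
    return("counts must be a 14 x 4 matrix (slots x ACGT)")
  if (!identical(colnames(m), .BASES))
    return("counts columns must be A, C, G, T")
  if (any(m < 0L))
    return("counts must be nonnegative")
  if (!all(rowSums(m) == object@nSequences))
    return("every slot's counts must sum to nSequences")
  fixed <- as.integer(names(.AW_FIXED))
  for (k in seq_along(fixed)) {
    if (m[fixed[k], .AW_FIXED[k]] != object@nSequences)
      return(sprintf("fixed slot %d must carry all mass on %s",
                     fixed[k], .AW_FIXED[k]))
  }
  TRUE
})

#' @slot probs 14 x 4 matrix of per-slot probabilities (rows sum to 1).
#' @slot pseudocount Pseudocount used in the derivation (>= 0).
#' @rdname PositionMatrices
#' @export
setClass("PositionProbabilityMatrix",
  representation(probs = "matrix", pseudocount = "numeric"))

setValidity("PositionProbabilityMatrix", function(object) {
  m <- object@probs
  if (!all(dim(m) == c(14L, 4L)) || !identical(colnames(m), .BASES))
    return("probs must be a 14 x 4 matrix with columns A, C, G, T")
  if (object@pseudocount < 0)
    return("pseudocount must be >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    return("each slot's probabilities must sum to 1")
  TRUE
})

#' @slot weights 14 x 4 matrix of log2-odds (may contain -Inf).
#' @slot background Length-4 base frequencies summing to 1.
#' @rdname PositionMatrices
#' @export
setClass("PositionWeightMatrix",
  representation(weights = "matrix", background = "numeric"))

setValidity("PositionWeightMatrix", function(object) {
  m <- object@weights
  if (!all(dim(m) == c(14L, 4L)) || !identical(colnames(m), .BASES))
    return("weights must be a 14 x 4 matrix with columns A, C, G, T")
  b <- object@background
  if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-9)
    return("background must be 4 positive frequencies summing to 1")
  TRUE
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat("PositionFrequencyMatrix:", object@nSequences, "sequences\n")
  print(object@counts)
})

setMethod("show", "PositionProbabilityMatrix", function(object) {
  cat("PositionProbabilityMatrix (pseudocount ",
      object@pseudocount, ")\n", sep = "")
  print(round(object@probs, 3))
})

setMethod("show", "PositionWeightMatrix", function(object) {
  cat("PositionWeightMatrix (log2 odds; background ",
      paste(round(object@background, 3), collapse = "/"), ")\n", sep = "")
  print(round(object@weights, 3))
})

#' Forbidden bases and base bias at the variable N positions
#'
#' Per N position (N1..N9): the set of bases with zero count among the
#' training motifs ("forbidden" bases, whose presence predicts
#' non-binding), and the most frequent base(s) with their probability.
#'
#' @slot forbidden Named list (N1..N9) of character vectors of bases.
#' @slot bias Named list (N1..N9); each element a list with `base`
#'   (character vector, all tied argmax bases) and `prob`.
#' @slot nSequences Training-set size.
#' @export
setClass("ForbiddenReport",
  representation(forbidden = "list", bias = "list", nSequences = "integer"))

setValidity("ForbiddenReport", function(object) {
  nm <- paste0("N", 1:9)
  if (!identical(names(object@forbidden), nm) ||
      !identical(names(object@bias), nm))
    return("forbidden and bias must be named N1..N9")
  p <- vapply(object@bias, function(b) b$prob, numeric(1))
  if (any(p <= 0 | p > 1))
    return("bias probabilities must lie in (0, 1]")
  TRUE
})

setMethod("show", "ForbiddenReport", function(object) {
  cat("ForbiddenReport over", object@nSequences, "bound motifs\n")
  for (nm in names(object@forbidden)) {
    fb <- object@forbidden[[nm]]
    b <- object@bias[[nm]]
    cat(sprintf("  %-2s forbidden: %-7s bias: %s (%.2f)\n", nm,
                if (length(fb)) paste(fb, collapse = ",") else "-",
                paste(b$base, collapse = ","), b$prob))
  }
})

#' A fitted WRI1-bindability profile
#'
#' Captures, from a training set of EMSA-bound canonical boxes, the set of
#' bases observed at each N position (complement of the forbidden sets),
#' the N2/N6 bias bases, the distance gate parameters, and a PWM for
#' optional score-threshold classification.
#'
#' @slot allowed Named list (N1..N9) of observed base sets.
#' @slot bias Named list with elements `N2` and `N6` (character vectors).
#' @slot maxDistance Distance gate in bp (inclusive).
#' @slot requireUtr5 Whether hits must lie inside an annotated 5'-UTR.
#' @slot mode One of "strict-forbidden", "allowed-profile", "pwm-threshold".
#' @slot threshold Score threshold in bits (pwm-threshold mode).
#' @slot pwm The training-set [PositionWeightMatrix-class].
#' @slot nSequences Training-set size.
#' @export
setClass("AWBoxProfile",
  representation(
    allowed = "list", bias = "list",
    maxDistance = "integer", requireUtr5 = "logical",
    mode = "character", threshold = "numeric",
    pwm = "PositionWeightMatrix", nSequences = "integer"
  )
)

setValidity("AWBoxProfile", function(object) {
  if (!identical(names(object@allowed), paste0("N", 1:9)))
    return("allowed must be named N1..N9")
  if (any(vapply(object@allowed, length, integer(1)) == 0L))
    return("every N position must allow at least one base")
  if (!object@mode %in% c("strict-forbidden", "allowed-profile", "pwm-threshold"))
    return("unknown classifier mode")
  TRUE
})

setMethod("show", "AWBoxProfile", function(object) {
  cat("AWBoxProfile (", object@mode, " mode; ", object@nSequences,
      " training motifs)\n", sep = "")
  cat("  allowed:",
      paste(sprintf("%s={%s}", names(object@allowed),
                    vapply(object@allowed, paste, "", collapse = "")),
            collapse = " "), "\n")
  cat("  bias: N2=", paste(object@bias$N2, collapse = ","),
      " N6=", paste(object@bias$N6, collapse = ","), "\n", sep = "")
  cat("  distance gate: |start| <= ", object@maxDistance,
      if (object@requireUtr5) " and within 5'-UTR", "\n", sep = "")
})
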