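#' Fit a WRI1-bindability profile from bound canonical boxes
#'
#' Derives, from the EMSA-bound training set, the set of bases observed at
#' each N position (the complement of the forbidden sets), the N2/N6 bias
#' bases, and a PWM; bundles them with the distance-gate parameters into a
#' classifier profile.
#'
#' @param seqs Character vector of bound canonical 14-mers (e.g.
#'   [boundSequences()]).
#' @param maxDistance Inclusive distance gate in bp (see [distanceGate()]).
#' @param requireUtr5 Whether candidates must lie inside the 5'-UTR.
#' @param mode Default decision rule: `strict-forbidden` rejects a box iff
#'   an N position carries a forbidden base (the published mechanism);
#'   `allowed-profile` additionally rejects bases never observed in
#'   training (a strictly more conservative formalisation that folds the
#'   bias in); `pwm-threshold` scores against the PWM.
#' @param threshold Score threshold in bits for pwm-threshold mode.
#' @param pseudocount Pseudocount for the profile's PWM (the forbidden
#'   sets always use raw counts — the zeros are the signal).
#' @param background Background base frequencies for the PWM.
#' @return An [AWBoxProfile-class].
#' @examples
#' prof <- fitProfile(boundSequences())
#' prof
#' @export
fitProfile <- function(seqs, maxDistance = 500, requireUtr5 = FALSE,
                       mode = c("strict-forbidden", "allowed-profile",
                                "pwm-threshold"),
                       threshold = 0, pseudocount = 0.5,
                       background = rep(0.25, 4)) {
  mode <- match.arg(mode)
  if (length(seqs) < 1L) stop("empty training set")
  pfm <- buildPFM(seqs)
  rep <- forbiddenAndBias(pfm)
  allowed <- lapply(rep@forbidden, function(fb) setdiff(.BASES, fb))
  pwm <- buildPWM(buildPPM(pfm, pseudocount), background)
  new("AWBoxProfile",
      allowed = allowed,
      bias = list(N2 = rep@bias$N2$base, N6 = rep@bias$N6$base),
      maxDistance = as.integer(maxDistance),
      requireUtr5 = isTRUE(requireUtr5),
      mode = mode, threshold = as.numeric(threshold),
      pwm = pwm, nSequences = pfm@nSequences)
}

#' Predict WRI1 bindability of a candidate AW box
#'
#' Applies the profile's decision rule to a canonical 14-mer. In
#' `strict-forbidden` mode a candidate is not-bindable iff any N position
#' carries a base that was never observed at that position in the whole
#' training set (a forbidden base); `allowed-profile` mode is identical
#' here by construction of the profile (allowed = not forbidden), and is
#' provided for profiles whose allowed sets were narrowed externally. The
#' distance gate is applied when a TIS start coordinate is supplied.
#' Insertion variants (15-mers) are not forced through the canonical rule:
#' they are flagged non-canonical with bindable precedent.
#'
#' @param profile An [AWBoxProfile-class].
#' @param seq A candidate sequence (14-mer, or 15-mer insertion variant).
#' @param tisStart Optional signed TIS coordinate of the box start.
#' @param utr5Start Optional 5'-UTR start coordinate for the UTR gate.
#' @param mode Override the profile's decision mode.
#' @return A list with `label` ("bindable"/"not-bindable"), `reasons`
#'   (character vector of violations, empty iff bindable in rule modes),
#'   `score` (bits, NA for insertion variants) and `variant`.
#' @examples
#' prof <- fitProfile(boundSequences())
#' predictBinding(prof, "CTTGGAGTACTCCG")$reasons  # forbidden G at N2
#' @export
predictBinding <- function(profile, seq, tisStart = NA_integer_,
                           utr5Start = NA_integer_, mode = NULL) {
  stopifnot(is(profile, "AWBoxProfile"))
  mode <- if (is.null(mode)) profile@mode else
    match.arg(mode, c("strict-forbidden", "allowed-profile", "pwm-threshold"))
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  reasons <- character(0)

  if (nchar(seq) == .AW_LEN + 1L) {
    if (length(insertionOffsets(seq)) == 0L)
      stop("15-mer is not a valid insertion-variant AW box: ", seq)
    variant <- "insertion"
    score <- NA_real_
    reasons <- character(0)  # bindable precedent for extra-base boxes
  } else {
    if (!isCanonicalBox(seq))
      stop("candidate is not a canonical AW box: ", seq)
    variant <- "canonical"
    ch <- substring(seq, 1:14, 1:14)
    score <- scoreSequence(profile@pwm, seq)
    if (mode == "pwm-threshold") {
      if (score < profile@threshold)
        reasons <- sprintf("score %.2f bits below threshold %.2f",
                           score, profile@threshold)
    } else {
      for (k in 1:9) {
        base <- ch[.nSlot(k)]
        if (!base %in% profile@allowed[[paste0("N", k)]])
          reasons <- c(reasons,
                       sprintf("forbidden base %s at N%d", base, k))
      }
    }
  }
  if (!is.na(tisStart)) {
    g <- distanceGate(
      data.frame(tis_start = as.integer(tisStart),
                 tis_end = spanEnd(as.integer(tisStart), nchar(seq))),
      maxDistance = profile@maxDistance,
      requireUtr5 = profile@requireUtr5, utr5Start = utr5Start)
    if (!g$pass) reasons <- c(reasons, g$reason)
  }
  list(label = if (length(reasons)) "not-bindable" else "bindable",
       reasons = reasons, score = score, variant = variant)
}

#' Substitute the base at an N position
#'
#' N positions map to motif slots 2, 4, 6..12 (N1 -> slot 2, N2 -> slot 4,
#' N3..N9 -> slots 6..12). For a 15-mer insertion variant the slots 3' of
#' the inserted base shift by one; supply its offset.
#'
#' @param seq A canonical 14-mer or insertion-variant 15-mer.
#' @param nIndex N position, 1..9.
#' @param base Replacement base.
#' @param insertionOffset 1-based offset of the extra base (15-mers only).
#' @return The mutated sequence.
#' @examples
#' mutateNPosition("CTTAGATTATATCG", 2, "C")  # "CTTCGATTATATCG"
#' mutateNPosition("CTTAGATTATATCG", 3, "G")  # "CTTAGGTTATATCG"
#' @export
mutateNPosition <- function(seq, nIndex, base, insertionOffset = NA) {
  seq <- toupper(as.character(seq))
  base <- toupper(base)
  stopifnot(length(seq) == 1L, base %in% .BASES)
  slot <- .nSlot(as.integer(nIndex))
  if (nchar(seq) == .AW_LEN + 1L) {
    if (is.na(insertionOffset))
      stop("insertionOffset required to mutate a 15-mer")
    if (slot >= insertionOffset) slot <- slot + 1L
  } else if (nchar(seq) != .AW_LEN) {
    stop("sequence must be a 14-mer or a 15-mer insertion variant")
  }
  substr(seq, slot, slot) <- base
  seq
}

#' Substitute the inserted ("extra") base of a 15-mer AW box
#'
#' @param seq A 15-mer insertion-variant box.
#' @param base Replacement base.
#' @param offset 1-based offset of the inserted base. Runs of identical
#'   bases make the offset ambiguous from sequence alone, so it must be
#'   given explicitly; [insertionOffsets()] enumerates the valid choices.
#' @return The substituted 15-mer.
#' @examples
#' substituteInsertedBase("CTTTAGGTTATATCG", "C", offset = 4)
#' @export
substituteInsertedBase <- function(seq, base, offset) {
  seq <- toupper(as.character(seq))
  base <- toupper(base)
  stopifnot(length(seq) == 1L, base %in% .BASES)
  if (nchar(seq) != .AW_LEN + 1L)
    stop("only 15-mer insertion variants carry an inserted base")
  offset <- as.integer(offset)
  if (offset < 2L || offset > 14L)
    stop("inserted base offset must be internal (2..14)")
  substr(seq, offset, offset) <- base
  seq
}

#' Construct a double-stranded EMSA probe around a box
#'
#' Pads the box with flanking context on each side (published probes used
#' 5 bp of context around the 14-bp box, giving 24 bp) and reports both
#' strands as exact reverse complements.
#'
#' @param boxSeq The box sequence.
#' @param flankLength Context length added to each end (>= 0).
#' @param flanks Optional character vector `c(left, right)` of explicit
#'   flanks (each of `flankLength`); when NULL, random flanks are drawn.
#' @param seed Seed for random flanks (required when `flanks` is NULL and
#'   `flankLength > 0`).
#' @return A list with `top`, `bottom` (5'->3') and `length`.
#' @examples
#' buildProbe("CCTCGTGCATATCG", flankLength = 5, seed = 1)$length  # 24
#' @export
buildProbe <- function(boxSeq, flankLength = 5, flanks = NULL, seed = NULL) {
  boxSeq <- toupper(as.character(boxSeq))
  flankLength <- as.integer(flankLength)
  if (flankLength < 0L) stop("flankLength must be >= 0")
  if (flankLength == 0L) {
    left <- right <- ""
  } else if (!is.null(flanks)) {
    stopifnot(length(flanks) == 2L, all(nchar(flanks) == flankLength))
    left <- toupper(flanks[1L]); right <- toupper(flanks[2L])
  } else {
    if (is.null(seed)) stop("seed required for random flanks")
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    left <- paste(sample(.BASES, flankLength, replace = TRUE), collapse = "")
    right <- paste(sample(.BASES, flankLength, replace = TRUE), collapse = "")
  }
  top <- paste0(left, boxSeq, right)
  list(top = top, bottom = revComp(top), length = nchar(top))
}

#' Evaluate a profile against labelled AW-box records
#'
#' Scores every EMSA-tested canonical record labelled bound or unbound,
#' reporting per-record explanations and the resulting confusion counts.
#' Smear records (weak/unstable binding) are never scored; they are listed
#' separately. No single headline accuracy is distilled: unbound boxes
#' without a forbidden base are genuine, documented exceptions whose
#' explanation lies in base combinations beyond the single-position rule,
#' so the full table is the result.
#'
#' @param profile An [AWBoxProfile-class].
#' @param records A fixture data.frame (see [loadAWBoxFixtures()]).
#' @param mode Override the profile's decision mode.
#' @return A list with `table` (per-record label, prediction, score and
#'   reasons), `confusion` (2 x 2 matrix, truth x prediction) and
#'   `smear` (the held-out smear records).
#' @export
evaluateProfile <- function(profile, records, mode = NULL) {
  stopifnot(is(profile, "AWBoxProfile"))
  if (nrow(records) == 0L) stop("empty record list")
  scored <- selectBoxes(records, testedOnly = TRUE,
                        label = c("bound", "unbound"), canonicalOnly = TRUE)
  smear <- selectBoxes(records, testedOnly = TRUE, label = "smear")
  if (nrow(scored) == 0L) stop("no bound/unbound canonical records to score")
  preds <- lapply(seq_len(nrow(scored)), function(r)
    predictBinding(profile, scored$seq[r], mode = mode))
  tab <- data.frame(
    gene_name = scored$gene_name,
    tis_start = scored$tis_start,
    seq = scored$seq,
    emsa_label = scored$emsa_label,
    prediction = vapply(preds, `[[`, "", "label"),
    score = vapply(preds, `[[`, numeric(1), "score"),
    reasons = vapply(preds, function(p) paste(p$reasons, collapse = "; "), ""),
    stringsAsFactors = FALSE
  )
  confusion <- table(
    truth = factor(tab$emsa_label, c("bound", "unbound")),
    prediction = factor(tab$prediction, c("bindable", "not-bindable"))
  )
  list(table = tab, confusion = confusion, smear = smear)
}

#' Serialise / restore a profile as JSON
#'
#' @param profile An [AWBoxProfile-class].
#' @param file JSON path.
#' @return `writeProfileJSON` invisibly returns `file`;
#'   `readProfileJSON` returns the restored [AWBoxProfile-class].
#' @name profile-json
NULL

#' @rdname profile-json
#' @export
writeProfileJSON <- function(profile, file) {
  stopifnot(is(profile, "AWBoxProfile"))
  jsonlite::write_json(list(
    allowed = profile@allowed, bias = profile@bias,
    maxDistance = profile@maxDistance, requireUtr5 = profile@requireUtr5,
    mode = profile@mode, threshold = profile@threshold,
    nSequences = profile@nSequences,
    pwm = list(weights = profile@pwm@weights,
               background = profile@pwm@background)
  ), file, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname profile-json
#' @param file JSON path written by `writeProfileJSON`.
#' @export
readProfileJSON <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  w <- matrix(unlist(x$pwm$weights), nrow = .AW_LEN,
              dimnames = list(paste0("pos", 1:14), .BASES))
  pwm <- new("PositionWeightMatrix", weights = w,
             background = setNames(as.numeric(x$pwm$background), .BASES))
  new("AWBoxProfile",
      allowed = lapply(x$allowed, as.character),
      bias = lapply(x$bias, as.character),
      maxDistance = as.integer(x$maxDistance),
      requireUtr5 = isTRUE(x$requireUtr5),
      mode = x$mode, threshold = as.numeric(x$threshold),
      pwm = pwm, nSequences = as.integer(x$nSequences))
}
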