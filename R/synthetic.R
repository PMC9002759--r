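#' Single-substitution decoy of a bound box
#'
#' Plants a known forbidden base at an N position of a bindable box,
#' producing a pattern-valid negative with a known violation.
#'
#' @param baseBox A canonical 14-mer.
#' @param nIndex N position to poison (1..9).
#' @param base The base to place there (must differ from the current one).
#' @return The decoy 14-mer.
#' @examples
#' makeDecoy("CCTCGTGCATATCG", 2, "G")
#' @export
makeDecoy <- function(baseBox, nIndex, base) {
  baseBox <- toupper(as.character(baseBox))
  if (!isCanonicalBox(baseBox))
    stop("decoys derive from canonical boxes")
  slot <- .nSlot(as.integer(nIndex))
  if (substr(baseBox, slot, slot) == toupper(base))
    stop("substitution equals the original base: not a decoy")
  mutateNPosition(baseBox, nIndex, base)
}

#' Specify a box to plant in simulated promoters
#'
#' @param source One of "bound-pool" (draw from the packaged bound set),
#'   "unbound-pool" (draw from the packaged unbound set), "explicit" (use
#'   `seq`), "forbidden-decoy" (a bound-pool draw poisoned at
#'   `decoyPosition` with `decoyBase`), or "insertion-variant" (the
#'   packaged extra-base box).
#' @param tisDistance A single TIS start coordinate, or a length-2 range
#'   `c(lo, hi)` of (negative) start coordinates to sample from.
#' @param strand "+" or "-".
#' @param seq Explicit box sequence (source = "explicit").
#' @param decoyPosition,decoyBase Decoy parameters (source =
#'   "forbidden-decoy").
#' @return A plant specification list for [simulatePromoters()].
#' @export
plantSpec <- function(source = c("bound-pool", "unbound-pool", "explicit",
                                 "forbidden-decoy", "insertion-variant"),
                      tisDistance = c(-200L, -80L), strand = "+",
                      seq = NULL, decoyPosition = 2L, decoyBase = "G") {
  source <- match.arg(source)
  if (source == "explicit" && is.null(seq))
    stop("explicit plant needs a sequence")
  list(source = source, tisDistance = as.integer(tisDistance),
       strand = match.arg(strand, c("+", "-")), seq = seq,
       decoyPosition = as.integer(decoyPosition),
       decoyBase = toupper(decoyBase))
}

.drawPlantSeq <- function(spec, pools) {
  switch(spec$source,
    "bound-pool" = sample(pools$bound, 1L),
    "unbound-pool" = sample(pools$unbound, 1L),
    "explicit" = toupper(spec$seq),
    "forbidden-decoy" = makeDecoy(sample(pools$bound, 1L),
                                  spec$decoyPosition, spec$decoyBase),
    "insertion-variant" = sample(pools$insertion, 1L)
  )
}

#' Simulate promoter sequences with planted AW boxes
#'
#' Draws background sequence i.i.d. from `baseComposition`, places the TIS
#' so that each region extends `tisOffset` bases past the ATG (mirroring
#' the design of TIS-crossing assay fragments, so that sign-crossing
#' coordinate code is exercised by default), and plants each requested box
#' at its TIS distance by overwriting the background without shifting
#' coordinates. Fully deterministic given `seed`; planted spans must not
#' overlap.
#'
#' @param nPromoters Number of promoters.
#' @param promoterLength Length of each region in bp.
#' @param baseComposition Frequencies of A, C, G, T; must sum to 1.
#' @param planted List of [plantSpec()] items; each is planted once in
#'   every promoter.
#' @param seed Mandatory integer seed; the generator has no hidden
#'   entropy.
#' @param tisOffset Bases of coding sequence retained 3' of the TIS.
#' @param records Fixture records supplying the bound/unbound pools.
#' @return A list with `promoters` (a [PromoterSet-class]) and `truth`
#'   (a data.frame of planted spans: gene_id, seq, strand, tis_start,
#'   tis_end, variant, source).
#' @examples
#' sim <- simulatePromoters(3, 500, planted = list(plantSpec()), seed = 1)
#' sim$truth
#' @export
simulatePromoters <- function(nPromoters, promoterLength,
                              baseComposition = rep(0.25, 4),
                              planted = list(), seed,
                              tisOffset = 51L,
                              records = loadAWBoxFixtures()) {
  if (missing(seed)) stop("seed is mandatory")
  nPromoters <- as.integer(nPromoters)
  promoterLength <- as.integer(promoterLength)
  tisOffset <- as.integer(tisOffset)
  baseComposition <- as.numeric(baseComposition)
  if (length(baseComposition) != 4L || any(baseComposition < 0) ||
      abs(sum(baseComposition) - 1) > 1e-9)
    stop("baseComposition must be 4 frequencies summing to 1")
  if (tisOffset < 0L || tisOffset >= promoterLength)
    stop("tisOffset must lie within the promoter")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  pools <- list(
    bound = unname(boundSequences(records)),
    unbound = selectBoxes(records, testedOnly = TRUE, label = "unbound",
                          canonicalOnly = TRUE)$seq,
    insertion = selectBoxes(records, label = c("bound", "unbound"))$seq
  )
  pools$insertion <- pools$insertion[nchar(pools$insertion) == .AW_LEN + 1L]

  tisIndex <- promoterLength - tisOffset
  seqs <- character(nPromoters)
  truth <- list()
  for (p in seq_len(nPromoters)) {
    gene <- sprintf("sim%03d", p)
    chars <- sample(.BASES, promoterLength, replace = TRUE,
                    prob = baseComposition)
    occupied <- integer(0)
    for (spec in planted) {
      box <- .drawPlantSeq(spec, pools)
      len <- nchar(box)
      dist <- spec$tisDistance
      start <- if (length(dist) == 2L)
        sample(seq(dist[1L], dist[2L]), 1L) else dist[1L]
      checkTisCoord(start)
      i0 <- if (start < 0L) start + tisIndex else start + tisIndex - 1L
      if (i0 < 0L || i0 + len > promoterLength)
        stop("planted box does not fit: ", spec$source, " at ", start)
      span <- seq(i0 + 1L, i0 + len)
      if (any(span %in% occupied))
        stop("planted spans overlap: ", spec$source, " at ", start)
      occupied <- c(occupied, span)
      written <- if (spec$strand == "+") box else revComp(box)
      chars[span] <- substring(written, seq_len(len), seq_len(len))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gene, seq = box, strand = spec$strand,
        tis_start = start, tis_end = spanEnd(start, len),
        variant = if (len == .AW_LEN) "canonical" else "insertion",
        source = spec$source, stringsAsFactors = FALSE
      )
    }
    seqs[p] <- paste(chars, collapse = "")
  }
  names(seqs) <- sprintf("sim%03d", seq_len(nPromoters))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), seq = character(0),
               strand = character(0), tis_start = integer(0),
               tis_end = integer(0), variant = character(0),
               source = character(0))
  list(promoters = PromoterSet(seqs, tisIndex = tisIndex),
       truth = truth)
}

#' Compare scanner hits with the planted truth
#'
#' Background sequence is expected to contain incidental matches (a window
#' with five fixed positions recurs about once per 4^5 ~ 1 kb per strand
#' under uniform composition), so evaluation distinguishes planted from
#' incidental hits rather than asserting zero background matches.
#'
#' @param hits Hits from [scanAWBox()] on the simulated promoters.
#' @param truth The `truth` component of [simulatePromoters()].
#' @return A list with `recall` (fraction of planted spans recovered),
#'   `recovered` (logical per truth row) and `incidental` (hits not in
#'   the truth set).
#' @export
compareToTruth <- function(hits, truth) {
  key <- function(d) paste(d$gene_id, d$tis_start, d$tis_end, d$strand)
  recovered <- key(truth) %in% key(hits)
  list(recall = if (nrow(truth)) mean(recovered) else NA_real_,
       recovered = recovered,
       incidental = hits[!key(hits) %in% key(truth), , drop = FALSE])
}
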