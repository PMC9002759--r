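#' Load the packaged sunflower AW-box inventory
#'
#' Returns the machine-readable transcription of the published sunflower
#' AW-box inventory: every canonical and extra-base box reported upstream
#' of the fatty-acid biosynthesis genes surveyed, with strand, signed
#' TIS-relative span, 5'-UTR membership, whether the box was analysed by
#' EMSA, and the binding outcome (`bound`, `unbound`, `smear`, `untested`).
#' Synthetic mutagenesis probes derived from the KAR1/KAR2 boxes carry a
#' `mutant_of` tag and no genomic span. `smear` is a distinct outcome
#' (weak/unstable binding) and is excluded from the bound training set.
#' One bound member (the KAR1 mut A/C probe) is marked provisional in the
#' `note` column: the published roster of clearly-bound motifs enumerates
#' 17 unambiguously and this package adopts that probe as the 18th.
#'
#' Every record is validated on load: canonical sequences must match
#' CNTNG(N)7CG, insertion variants must match after one internal deletion,
#' and genomic spans must agree with sequence length under the no-zero
#' coordinate convention.
#'
#' @param file Path to an inventory TSV; defaults to the packaged one.
#' @return A data.frame, one row per AW-box record.
#' @examples
#' fx <- loadAWBoxFixtures()
#' table(fx$emsa_label)
#' @export
loadAWBoxFixtures <- function(file = system.file("extdata",
                                                 "awbox_fixtures.tsv",
                                                 package = "awbox")) {
  fx <- read.delim(file, stringsAsFactors = FALSE,
                   colClasses = c(tis_start = "integer",
                                  tis_end = "integer",
                                  insertion_offset = "integer"))
  needed <- c("gene_name", "strand", "seq", "tis_start", "tis_end",
              "in_utr5", "tested_in_emsa", "emsa_label", "variant",
              "insertion_offset", "mutant_of", "note")
  if (!all(needed %in% names(fx)))
    stop("fixture file lacks columns: ",
         paste(setdiff(needed, names(fx)), collapse = ", "))
  for (r in seq_len(nrow(fx))) {
    rec <- fx[r, ]
    where <- sprintf("fixture row %d (%s %s)", r, rec$gene_name, rec$seq)
    if (!rec$emsa_label %in% c("bound", "unbound", "smear", "untested"))
      stop(where, ": unknown emsa_label ", rec$emsa_label)
    if (rec$variant == "canonical" && !isCanonicalBox(rec$seq))
      stop(where, ": canonical record does not match CNTNG(N)7CG")
    if (rec$variant == "insertion" && length(insertionOffsets(rec$seq)) == 0L)
      stop(where, ": insertion record admits no valid internal deletion")
    if (!is.na(rec$tis_start)) {
      if (spanLength(rec$tis_start, rec$tis_end) != nchar(rec$seq))
        stop(where, ": TIS span inconsistent with sequence length")
    }
    if (xor(rec$emsa_label == "untested", !rec$tested_in_emsa))
      stop(where, ": tested_in_emsa inconsistent with emsa_label")
  }
  fx
}

#' Filter AW-box records
#'
#' @param records A fixture data.frame (see [loadAWBoxFixtures()]).
#' @param testedOnly Keep only records analysed by EMSA.
#' @param label Optional label filter: any of "bound", "unbound", "smear",
#'   "untested".
#' @param canonicalOnly Keep only canonical 14-mers.
#' @return The filtered records, order preserved.
#' @examples
#' fx <- loadAWBoxFixtures()
#' nrow(selectBoxes(fx, testedOnly = TRUE, canonicalOnly = TRUE))  # 52
#' @export
selectBoxes <- function(records, testedOnly = FALSE, label = NULL,
                        canonicalOnly = FALSE) {
  keep <- rep(TRUE, nrow(records))
  if (testedOnly) keep <- keep & records$tested_in_emsa
  if (!is.null(label)) {
    bad <- setdiff(label, c("bound", "unbound", "smear", "untested"))
    if (length(bad))
      stop("unknown emsa label: ", paste(bad, collapse = ", "))
    keep <- keep & records$emsa_label %in% label
  }
  if (canonicalOnly) keep <- keep & records$variant == "canonical"
  records[keep, , drop = FALSE]
}

#' Genes carrying at least k bound AW boxes
#'
#' Counts natural (non-mutant) records labelled `bound` per gene; with
#' `k = 2` this recovers the genes with two active boxes in their upstream
#' regions.
#'
#' @param records A fixture data.frame.
#' @param k Minimum number of bound boxes.
#' @return Character vector of gene names, sorted.
#' @examples
#' genesWithBoundBoxes(loadAWBoxFixtures(), k = 2)  # LPD-10g, BCCP-16g
#' @export
genesWithBoundBoxes <- function(records, k) {
  natural <- records[is.na(records$mutant_of), ]
  bound <- natural[natural$emsa_label == "bound", ]
  tab <- table(bound$gene_name)
  sort(names(tab)[tab >= k])
}

#' The canonical bound training set
#'
#' The EMSA-bound canonical 14-mers used to train matrices and the
#' classifier (the "clearly bound" set).
#'
#' @param records A fixture data.frame; defaults to the packaged inventory.
#' @return Character vector of 14-mer sequences (named by gene).
#' @export
boundSequences <- function(records = loadAWBoxFixtures()) {
  b <- selectBoxes(records, testedOnly = TRUE, label = "bound",
                   canonicalOnly = TRUE)
  setNames(b$seq, b$gene_name)
}

#' Export fixture sequences as FASTA
#'
#' @param records A fixture data.frame.
#' @param file Output FASTA path.
#' @return Invisibly, `file`.
#' @export
exportFixturesFASTA <- function(records, file) {
  ids <- sprintf("%s_%s", records$gene_name,
                 ifelse(is.na(records$tis_start),
                        sub("^.*:", "", records$mutant_of),
                        records$tis_start))
  seqs <- Biostrings::DNAStringSet(setNames(records$seq, make.unique(ids)))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
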