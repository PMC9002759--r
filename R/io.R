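#' Read promoters from FASTA plus a TIS sidecar table
#'
#' The sidecar is a tab-separated file with columns `gene_id`, `tis_index`
#' (0-based promoter-local index of the A of the ATG) and, optionally,
#' `utr5_start` (negative TIS coordinate of the 5'-UTR start).
#'
#' @param fasta Path to a FASTA file of coding-strand upstream sequences.
#' @param tisTable Path to the TIS sidecar TSV.
#' @return A [PromoterSet-class].
#' @export
readPromoters <- function(fasta, tisTable) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(tisTable, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tis_index") %in% names(tab)))
    stop("TIS sidecar needs columns gene_id and tis_index")
  miss <- setdiff(names(seqs), tab$gene_id)
  if (length(miss))
    stop("no TIS annotation for: ", paste(miss, collapse = ", "))
  tab <- tab[match(names(seqs), tab$gene_id), ]
  utr <- if ("utr5_start" %in% names(tab)) tab$utr5_start else NA_integer_
  PromoterSet(seqs, tisIndex = tab$tis_index, utr5Start = utr)
}

#' Write a PromoterSet to FASTA plus a TIS sidecar table
#'
#' @param x A [PromoterSet-class].
#' @param fasta,tisTable Output paths.
#' @return Invisibly, the FASTA path.
#' @export
writePromoters <- function(x, fasta, tisTable) {
  Biostrings::writeXStringSet(promoterSeqs(x), fasta)
  tab <- data.frame(gene_id = geneIds(x), tis_index = x@tisIndex,
                    utr5_start = x@utr5Start)
  write.table(tab, tisTable, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' Write scanner hits as TSV or BED6
#'
#' `writeHitsTSV` emits the TIS-relative hit table; `writeHitsBED` emits
#' BED6 in promoter-local 0-based half-open coordinates with
#' `name = gene_id:tis_start`, score 0 and the hit strand.
#'
#' @param hits A hit data.frame from [scanAWBox()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @name hit-export
NULL

#' @rdname hit-export
#' @export
writeHitsTSV <- function(hits, file) {
  cols <- c("gene_id", "tis_start", "tis_end", "strand", "variant",
            "matched_seq")
  write.table(hits[, cols], file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname hit-export
#' @export
writeHitsBED <- function(hits, file) {
  bed <- data.frame(
    chrom = hits$gene_id,
    chromStart = hits$local_start,
    chromEnd = hits$local_end,
    name = sprintf("%s:%d", hits$gene_id, hits$tis_start),
    score = 0L,
    strand = hits$strand
  )
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
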