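#' TIS-relative coordinates with no position zero
#'
#' Motif positions are expressed relative to the translation initiation site
#' (TIS, the ATG codon) using the field's signed convention without a
#' position 0: +1 is the A of the ATG and -1 the base immediately 5' of it.
#' This is the only convention under which published fragment arithmetic
#' holds (a fragment spanning -272..+51 is 323 bp; a 14-bp box starting at
#' -110 ends at -97).
#'
#' @param coord Integer vector of signed TIS coordinates (never 0).
#' @return `checkTisCoord` invisibly returns its (validated) input.
#' @examples
#' checkTisCoord(c(-110L, 1L))
#' @export
checkTisCoord <- function(coord) {
  coord <- as.integer(coord)
  if (anyNA(coord))
    stop("TIS coordinates must not be NA")
  if (any(coord == 0L))
    stop("TIS coordinate 0 does not exist: -1 abuts +1")
  invisible(coord)
}

#' Convert a promoter-local index to a TIS coordinate
#'
#' @param i Promoter-local 0-based index (vectorised).
#' @param tisIndex 0-based index of the first base of the ATG.
#' @param seqLength Optional sequence length for range checking.
#' @return Signed TIS coordinate(s); see [checkTisCoord()].
#' @examples
#' indexToTis(162, tisIndex = 272)  # -110, a box start 110 bp upstream
#' @seealso [tisToIndex()] for the inverse.
#' @export
indexToTis <- function(i, tisIndex, seqLength = NULL) {
  i <- as.integer(i)
  tisIndex <- as.integer(tisIndex)
  if (anyNA(i) || any(i < 0L))
    stop("promoter-local index must be a nonnegative integer")
  if (!is.null(seqLength) && any(i >= seqLength))
    stop("promoter-local index beyond sequence end")
  ifelse(i < tisIndex, i - tisIndex, i - tisIndex + 1L)
}

#' Convert a TIS coordinate back to a promoter-local index
#'
#' @inheritParams indexToTis
#' @param coord Signed TIS coordinate (vectorised, never 0).
#' @return 0-based promoter-local index.
#' @examples
#' tisToIndex(-110, tisIndex = 272)  # 162
#' @export
tisToIndex <- function(coord, tisIndex, seqLength = NULL) {
  coord <- checkTisCoord(coord)
  tisIndex <- as.integer(tisIndex)
  i <- ifelse(coord < 0L, coord + tisIndex, coord + tisIndex - 1L)
  if (any(i < 0L) || (!is.null(seqLength) && any(i >= seqLength)))
    stop("TIS coordinate falls outside the sequence")
  i
}

#' Length of an inclusive TIS-coordinate span
#'
#' Same-sign spans have length `end - start + 1`; spans crossing the TIS
#' have length `(-start) + end` because there is no position 0.
#'
#' @param start,end Signed TIS coordinates, `start <= end`.
#' @return Integer span length in bp.
#' @examples
#' spanLength(-272, 51)   # 323
#' spanLength(-110, -97)  # 14
#' @export
spanLength <- function(start, end) {
  start <- checkTisCoord(start)
  end <- checkTisCoord(end)
  if (any(start > end))
    stop("span start must not exceed span end")
  ifelse(sign(start) == sign(end), end - start + 1L, end - start)
}

#' End coordinate of a span given its start and length
#'
#' @param start Signed TIS coordinate of the first base.
#' @param length Span length in bp (>= 1).
#' @return The unique TIS coordinate `end` with
#'   `spanLength(start, end) == length`.
#' @examples
#' spanEnd(-110, 14)  # -97
#' spanEnd(-1, 2)     # +1 (crossing the TIS)
#' @export
spanEnd <- function(start, length) {
  start <- checkTisCoord(start)
  length <- as.integer(length)
  if (anyNA(length) || any(length < 1L))
    stop("span length must be >= 1")
  end <- start + length - 1L
  # a span beginning upstream that runs past -1 skips the nonexistent 0
  ifelse(start < 0L & end >= 0L, end + 1L, end)
}
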