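## Feature encoders: dot-bracket one-hot matrices and per-base conservation
## vectors. Both operate at nucleotide resolution and feed the SS and EC
## branches of the classifier directly (no tokenization).

.DOTBRACKET <- c(".", "(", ")")

#' One-hot encode a dot-bracket secondary-structure string
#'
#' Maps a structure string s = (r1, ..., rn) over the symbols
#' \code{. ( )} to the n x 3 binary matrix M with M[i, j] = 1 iff r_i is the
#' j-th symbol of \code{c(".", "(", ")")}. Every row sums to exactly 1.
#'
#' @param dotbracket a single structure string.
#' @return an n x 3 integer matrix with columns \code{".", "(", ")"}
#' @examples
#' encodeStructure("(.)")
#' @export
encodeStructure <- function(dotbracket) {
  stopifnot(length(dotbracket) == 1L, !is.na(dotbracket))
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1L]]
  j <- match(ch, .DOTBRACKET)
  if (anyNA(j))
    stop("structure string contains '", ch[which(is.na(j))[1L]],
         "' at position ", which(is.na(j))[1L],
         "; only characters . ( ) are allowed")
  n <- length(ch)
  m <- matrix(0L, nrow = n, ncol = 3L,
              dimnames = list(NULL, .DOTBRACKET))
  if (n > 0L) m[cbind(seq_len(n), j)] <- 1L
  m
}

#' Map conservation track scores onto an interval
#'
#' Produces one floating-point score per base of \code{interval}, in
#' transcribed (5'->3') order: for minus-strand intervals the vector is
#' reversed so it stays positionally aligned with the extracted sequence.
#' Positions with no track data score 0.0; scores are used raw by default
#' (phyloP-style scores may legitimately be negative).
#'
#' @param raw a \code{GRanges} with a numeric \code{score} column, as
#'   returned by [readConservationTrack()]; may be \code{NULL} or empty.
#' @param interval a length-1 \code{GRanges}.
#' @param standardize subtract the track mean and divide by the track sd
#'   (computed over the supplied ranges); off by default.
#' @return numeric vector of length \code{width(interval)}
#' @export
encodeConservation <- function(raw, interval, standardize = FALSE) {
  stopifnot(is(interval, "GRanges"), length(interval) == 1L)
  w <- GenomicRanges::width(interval)
  out <- numeric(w)
  if (!is.null(raw) && length(raw) > 0L) {
    sc <- raw$score
    if (is.null(sc)) stop("conservation track has no 'score' column")
    if (standardize) {
      mu <- sum(sc * GenomicRanges::width(raw)) / sum(GenomicRanges::width(raw))
      sdv <- sqrt(sum(GenomicRanges::width(raw) * (sc - mu)^2) /
                  max(1, sum(GenomicRanges::width(raw)) - 1))
      if (sdv > 0) sc <- (sc - mu) / sdv else sc <- sc - mu
    }
    hits <- GenomicRanges::findOverlaps(raw, interval, ignore.strand = TRUE)
    s0 <- GenomicRanges::start(interval)
    for (h in seq_along(hits)) {
      i <- S4Vectors::queryHits(hits)[h]
      a <- max(GenomicRanges::start(raw)[i], s0)
      b <- min(GenomicRanges::end(raw)[i], GenomicRanges::end(interval))
      out[(a - s0 + 1L):(b - s0 + 1L)] <- sc[i]
    }
  }
  if (as.character(GenomicRanges::strand(interval)) == "-") out <- rev(out)
  out
}
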