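## Attention-based interpretation: take the top-predicted bound sequences,
## extract the fixed-width window of maximal average attention from each,
## and rank the k-mers occurring inside those windows.

#' Select the top predicted-bound samples
#'
#' Ranks the evaluation samples by predicted binding probability, keeps
#' those predicted bound (probability >= \code{threshold}) and returns the
#' \code{n} highest, ties broken by stable input order. If fewer than
#' \code{n} samples are predicted bound, all of them are returned with a
#' warning.
#'
#' @param model an \linkS4class{RBPModel}.
#' @param samples an \linkS4class{RBPSampleSet}.
#' @param n number of samples to keep (50 is the conventional choice).
#' @param threshold predicted-bound cutoff (default 0.5).
#' @return list with \code{samples} (an \linkS4class{RBPSampleSet}, ordered
#'   by descending probability), \code{probability} and \code{index} (into
#'   the input set)
#' @export
selectTopPredictions <- function(model, samples, n = 50L, threshold = 0.5) {
  stopifnot(n >= 1L)
  p <- predict(model, samples)
  bound <- which(p >= threshold)
  if (length(bound) < n)
    warning("only ", length(bound), " samples are predicted bound; ",
            "returning all of them")
  ord <- bound[order(-p[bound], bound)]   # stable: ties keep input order
  take <- ord[seq_len(min(n, length(ord)))]
  list(samples = samples[take], probability = p[take], index = take)
}

#' Window of maximal average attention
#'
#' Scans all width-\code{width} windows of an attention profile and returns
#' the one with the highest mean weight; the leftmost wins ties.
#'
#' @param profile numeric attention profile (nonnegative, summing to 1).
#' @param width window width in nt (20 is the conventional choice).
#' @return list with \code{start}, \code{end} (0-based half-open offsets
#'   into the profile) and \code{mean_attention}
#' @export
maxAttentionWindow <- function(profile, width = 20L) {
  n <- length(profile)
  width <- as.integer(width)
  if (width > n)
    stop("window width (", width, ") exceeds profile length (", n, ")")
  cs <- c(0, cumsum(profile))
  sums <- cs[(width + 1L):(n + 1L)] - cs[1L:(n - width + 1L)]
  ## leftmost maximizer; ties identified up to cumsum rounding noise
  i <- which(sums >= max(sums) - 1e-12)[1L]
  list(start = i - 1L, end = i - 1L + width,
       mean_attention = sums[i] / width)
}

#' Extract maximal-attention regions for the top predictions
#'
#' Convenience pipeline: [selectTopPredictions()], [attentionProfiles()]
#' and [maxAttentionWindow()] per selected sample.
#'
#' @param model an \linkS4class{RBPModel} (S branch required).
#' @param samples evaluation \linkS4class{RBPSampleSet}.
#' @param n,threshold passed to [selectTopPredictions()].
#' @param width window width (nt).
#' @return data.frame with columns index, probability, start, end,
#'   mean_attention, subsequence
#' @export
extractAttentionRegions <- function(model, samples, n = 50L,
                                    threshold = 0.5, width = 20L) {
  top <- selectTopPredictions(model, samples, n = n, threshold = threshold)
  if (length(top$index) == 0L)
    return(data.frame(index = integer(0), probability = numeric(0),
                      start = integer(0), end = integer(0),
                      mean_attention = numeric(0),
                      subsequence = character(0)))
  profs <- attentionProfiles(model, top$samples)
  seqs <- sampleSequences(top$samples)
  rows <- lapply(seq_along(profs), function(i) {
    w <- maxAttentionWindow(profs[[i]], width)
    data.frame(index = top$index[i], probability = top$probability[i],
               start = w$start, end = w$end,
               mean_attention = w$mean_attention,
               subsequence = substr(seqs[i], w$start + 1L, w$end))
  })
  do.call(rbind, rows)
}

#' Count overlapping k-mers in attention regions
#'
#' Counts every overlapping k-mer within each region (never across region
#' boundaries) and returns them in a total order: count descending, then
#' lexicographic.
#'
#' @param regions character vector of subsequences, or the data.frame from
#'   [extractAttentionRegions()] (its \code{subsequence} column is used).
#' @param k k-mer length (6 is the conventional choice).
#' @return data.frame with columns kmer, count (possibly empty)
#' @export
countKmers <- function(regions, k = 6L) {
  if (is.data.frame(regions)) regions <- regions$subsequence
  k <- as.integer(k)
  if (length(regions) == 0L)
    return(data.frame(kmer = character(0), count = integer(0)))
  if (any(nchar(regions) < k))
    stop("k (", k, ") exceeds the width of some region")
  kmers <- unlist(lapply(regions, function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }))
  tab <- table(kmers)
  out <- data.frame(kmer = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Check recovery of a planted motif among top k-mers
#'
#' TRUE iff any of the top \code{topM} k-mers is a substring of the planted
#' consensus or within Hamming distance 1 of some window of it; also
#' reports the best achieving rank.
#'
#' @param report data.frame from [countKmers()].
#' @param motif planted consensus motif (length >= the k-mer length).
#' @param topM how many leading k-mers to consider.
#' @return list with \code{recovered} (logical) and \code{rank} (integer or
#'   NA)
#' @export
motifRecoveryCheck <- function(report, motif, topM = 3L) {
  if (nrow(report) == 0L) return(list(recovered = FALSE, rank = NA_integer_))
  m <- nrow(report)
  hamming_near <- function(kmer) {
    k <- nchar(kmer)
    if (nchar(motif) < k) return(FALSE)
    wins <- substring(motif, seq_len(nchar(motif) - k + 1L),
                      seq_len(nchar(motif) - k + 1L) + k - 1L)
    a <- strsplit(kmer, "", fixed = TRUE)[[1L]]
    any(vapply(wins, function(wn)
      sum(a != strsplit(wn, "", fixed = TRUE)[[1L]]) <= 1L, logical(1)))
  }
  for (i in seq_len(min(topM, m))) {
    if (hamming_near(report$kmer[i]))
      return(list(recovered = TRUE, rank = i))
  }
  list(recovered = FALSE, rank = NA_integer_)
}

#' Map attention windows back to genomic coordinates
#'
#' Window offsets are positions within the recentred 5'->3' sequence; for
#' minus-strand intervals the genomic window is mirrored accordingly.
#'
#' @param regions data.frame from [extractAttentionRegions()].
#' @param samples the \linkS4class{RBPSampleSet} the regions refer to (via
#'   \code{regions$index}).
#' @return a \code{GRanges} of the windows with mcols mean_attention and
#'   probability
#' @export
attentionWindowsToGenomic <- function(regions, samples) {
  gr <- sampleIntervals(samples)[regions$index]
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  gs <- ifelse(neg, e0 - regions$end, s0 + regions$start)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(start = gs + 1L, width = regions$end - regions$start),
    strand = GenomicRanges::strand(gr))
  out$mean_attention <- regions$mean_attention
  out$probability <- regions$probability
  out
}

#' Write attention windows as BED6
#'
#' @param windows \code{GRanges} from [attentionWindowsToGenomic()].
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeAttentionBed <- function(windows, path) {
  df <- .bed0_from_gr(windows)
  score <- if (!is.null(windows$mean_attention))
    windows$mean_attention else 0
  bed <- data.frame(df$chrom, df$start, df$end,
                    name = sprintf("attn%d", seq_len(nrow(df))),
                    score = score, strand = df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
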