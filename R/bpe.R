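## Byte-pair encoding over the nucleotide alphabet.
##
## Training merges the most frequent adjacent token pair, counted within each
## corpus sequence independently (pairs never cross sequence boundaries),
## until the requested vocabulary size k is reached or no pair occurs at
## least twice. Ties on frequency are broken by the lexicographically
## smallest (left, right) pair so training is deterministic.

.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Normalize a nucleotide string for tokenization
#'
#' Uppercases and maps U to T (benchmark FASTA files mix RNA/DNA
#' conventions). Ns are left in place by default and rejected downstream by
#' the tokenizer; with \code{replaceN = TRUE} each N is replaced by a
#' uniformly random base drawn under \code{seed}.
#'
#' @param x character vector of sequences.
#' @param replaceN replace N with a random base instead of keeping it.
#' @param seed RNG seed used when \code{replaceN} is TRUE.
#' @return character vector of normalized sequences
#' @export
normalizeSequence <- function(x, replaceN = FALSE, seed = 1L) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (replaceN && any(grepl("N", x, fixed = TRUE))) {
    x <- .with_seed(seed, vapply(x, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      idx <- which(ch == "N")
      if (length(idx))
        ch[idx] <- sample(.DNA_ALPHABET, length(idx), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  x
}

#' Train a byte-pair-encoding vocabulary
#'
#' Starts from the single-nucleotide tokens found in the corpus (always
#' including A, C, G, T) and repeatedly merges the most frequent adjacent
#' token pair until the vocabulary holds \code{k} tokens or no pair occurs
#' at least twice. Pair frequencies are counted within each sequence
#' independently; frequency ties are broken by the lexicographically
#' smallest pair. Deterministic given the corpus.
#'
#' @param corpus character vector of nucleotide sequences (A/C/G/T; use
#'   [normalizeSequence()] first for mixed-case or RNA input).
#' @param k target vocabulary size; must be at least the alphabet size.
#' @return a \linkS4class{BPEVocabulary}
#' @examples
#' v <- trainBPE(c("ACGTACGTACGT", "ACACACAC"), k = 8)
#' vocabTokens(v)
#' @export
trainBPE <- function(corpus, k) {
  if (length(corpus) == 0L || all(!nzchar(corpus)))
    stop("BPE training corpus is empty")
  k <- as.integer(k)
  alphabet <- .DNA_ALPHABET
  seen <- unique(unlist(strsplit(corpus, "", fixed = TRUE)))
  bad <- setdiff(seen, alphabet)
  if (length(bad))
    stop("corpus contains characters outside the A/C/G/T alphabet: ",
         paste(bad, collapse = ", "))
  if (k < length(alphabet))
    stop("k (", k, ") must be at least the alphabet size (",
         length(alphabet), ")")

  ## flat token stream with sequence ids so pairs never cross boundaries
  toks <- strsplit(corpus[nzchar(corpus)], "", fixed = TRUE)
  stream <- unlist(toks, use.names = FALSE)
  seqid <- rep.int(seq_along(toks), lengths(toks))

  tokens <- alphabet
  merges <- matrix(character(0), ncol = 2L,
                   dimnames = list(NULL, c("left", "right")))

  while (length(tokens) < k) {
    n <- length(stream)
    if (n < 2L) break
    adj <- seqid[-n] == seqid[-1L]
    if (!any(adj)) break
    left <- stream[-n][adj]
    right <- stream[-1L][adj]
    key <- paste(left, right, sep = "\r")
    cnt <- table(key)
    top <- max(cnt)
    if (top < 2L) break
    cand <- sort(names(cnt)[cnt == top])[1L]   # lexicographic tie-break
    pair <- strsplit(cand, "\r", fixed = TRUE)[[1L]]
    merged <- paste0(pair[1L], pair[2L])

    ## merge left-to-right, non-overlapping
    hit <- which(stream[-n] == pair[1L] & stream[-1L] == pair[2L] &
                 seqid[-n] == seqid[-1L])
    if (length(hit) > 1L) {
      keep <- logical(length(hit))
      last <- -1L
      for (i in seq_along(hit)) {
        if (hit[i] > last + 1L) { keep[i] <- TRUE; last <- hit[i] }
      }
      hit <- hit[keep]
    }
    stream[hit] <- merged
    stream <- stream[-(hit + 1L)]
    seqid <- seqid[-(hit + 1L)]

    tokens <- c(tokens, merged)
    merges <- rbind(merges, pair)
  }
  rownames(merges) <- NULL
  new("BPEVocabulary", tokens = tokens, merges = merges, k = k,
      alphabet = alphabet)
}

.vocab_env <- function(vocab) {
  e <- new.env(parent = emptyenv(), size = 2L * length(vocab@tokens))
  for (i in seq_along(vocab@tokens)) assign(vocab@tokens[i], i, envir = e)
  e
}

.tokenize_one <- function(s, env, maxlen, alphabet) {
  n <- nchar(s)
  if (n == 0L)
    return(list(ids = integer(0),
                spans = matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("start", "end"))),
                tokens = character(0)))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% alphabet)
  if (length(bad))
    stop("character '", ch[bad[1L]], "' at position ", bad[1L],
         " is outside the tokenizer alphabet {",
         paste(alphabet, collapse = ","), "}")
  ids <- integer(0)
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  while (pos <= n) {
    len <- min(maxlen, n - pos + 1L)
    while (len > 1L) {
      cand <- substr(s, pos, pos + len - 1L)
      id <- get0(cand, envir = env, inherits = FALSE)
      if (!is.null(id)) break
      len <- len - 1L
    }
    if (len == 1L) id <- get(ch[pos], envir = env, inherits = FALSE)
    ids <- c(ids, id)
    starts <- c(starts, pos - 1L)   # spans reported 0-based half-open
    ends <- c(ends, pos - 1L + len)
    pos <- pos + len
  }
  list(ids = ids,
       spans = cbind(start = starts, end = ends),
       tokens = NULL)
}

#' @describeIn bpeTokenize greedy longest-match tokenization of nucleotide
#'   strings. For each position the longest vocabulary token matching the
#'   remaining suffix is taken, so the token spans tile the sequence exactly
#'   and detokenization is the identity (no unknown tokens can occur).
#' @param vocab a \linkS4class{BPEVocabulary}
#' @param x character vector of sequences over the vocabulary's alphabet
#' @param ... unused
#' @return \code{bpeTokenize}: a list with one element per input sequence;
#'   each element has \code{ids} (vocabulary indices), \code{spans}
#'   (two-column matrix of 0-based half-open nucleotide coordinates) and
#'   \code{tokens} (the token strings).
#' @examples
#' v <- trainBPE(c("ACGTACGTACGT", "ACACACAC"), k = 8)
#' tk <- bpeTokenize(v, "ACGTAC")[[1]]
#' paste(tk$tokens, collapse = "") == "ACGTAC"
#' @export
setMethod("bpeTokenize", "BPEVocabulary", function(vocab, x, ...) {
  env <- .vocab_env(vocab)
  maxlen <- max(nchar(vocab@tokens))
  lapply(x, function(s) {
    r <- .tokenize_one(s, env, maxlen, vocab@alphabet)
    r$tokens <- vocab@tokens[r$ids]
    r
  })
})

#' @describeIn bpeTokenize reassemble a sequence from token ids (the inverse
#'   of tokenization).
#' @param tokens integer vector of vocabulary indices, or the list returned
#'   by \code{bpeTokenize} for one sequence.
#' @export
setMethod("bpeDetokenize", "BPEVocabulary", function(vocab, tokens, ...) {
  if (is.list(tokens)) tokens <- tokens$ids
  paste(vocab@tokens[tokens], collapse = "")
})

#' Serialize a vocabulary to JSON
#'
#' Writes a JSON object with keys \code{tokens}, \code{merges} (a list of
#' two-element arrays) and \code{k}. [loadVocabulary()] validates the class
#' invariants on load.
#'
#' @param vocab a \linkS4class{BPEVocabulary}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
saveVocabulary <- function(vocab, path) {
  m <- vocab@merges
  merges <- if (nrow(m)) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
            else list()
  jsonlite::write_json(
    list(tokens = vocab@tokens, merges = merges, k = vocab@k,
         alphabet = vocab@alphabet),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveVocabulary
#' @export
loadVocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  merges <- obj$merges
  if (is.null(merges) || length(merges) == 0L) {
    merges <- matrix(character(0), ncol = 2L)
  } else if (is.list(merges)) {
    merges <- do.call(rbind, merges)
  }
  colnames(merges) <- c("left", "right")
  alphabet <- if (is.null(obj$alphabet)) .DNA_ALPHABET else obj$alphabet
  new("BPEVocabulary", tokens = obj$tokens, merges = merges,
      k = as.integer(obj$k), alphabet = alphabet)
}
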