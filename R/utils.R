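## Internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so library calls never perturb user-level reproducibility.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## Derive a child seed from (seed, tag) deterministically, staying within the
## 32-bit integer range R requires.
.child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

## Reverse-complement for plain character vectors (DNA alphabet).
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
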