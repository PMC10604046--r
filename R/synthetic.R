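## Synthetic CLIP-like benchmark generator.
##
## Emulates the two benchmark flavours at desk scale: variable-length
## balanced collections ("rbp24-style", native lengths 150-375 nt) and fixed
## 101-nt collections at a 1:4 positive:negative ratio ("rbp31-style").
## Positives carry a planted motif (shared transferable core + per-protein
## flank, mutated per base), negatives are background rejected to not
## contain the exact core consensus, and conservation is Gaussian with an
## elevated mean over motif positions. A genome FASTA and a per-base
## bedGraph track are emitted and read back through the package's own
## loaders, so the real I/O paths are exercised end to end.

#' Create a synthetic benchmark specification
#'
#' Defaults describe the study conditions the generator emulates: four
#' proteins sharing the 6-nt core \code{TGCATG} with distinct 6-nt flanks, a
#' 10\% per-base motif mutation rate, 500 positives per protein (balanced in
#' rbp24-style mode; 1:4 in rbp31-style mode), background conservation
#' N(0, 1) against motif conservation N(2, 0.5).
#'
#' @param nProteins number of synthetic proteins.
#' @param coreMotif shared core motif.
#' @param flankMotifs per-protein flanks; \code{NULL} draws deterministic
#'   6-nt flanks from \code{seed}; \code{""} entries disable the flank.
#' @param motifMutationRate per-base substitution probability in [0,1).
#' @param nPos positives per protein (training + evaluation together).
#' @param negPerPosRatio negatives per positive; \code{NULL} = dialect
#'   default (1 for rbp24-style, 4 for rbp31-style).
#' @param intervalLengthRange native interval lengths; \code{NULL} = dialect
#'   default (150-375 or fixed 101).
#' @param conservation numeric(4): background mean, background sd, motif
#'   mean, motif sd.
#' @param dialect \code{"rbp24-style"} or \code{"rbp31-style"}.
#' @param markovBackground first-order Markov background instead of i.i.d.
#'   uniform.
#' @param plantHairpins give positives a complementary terminal stem so the
#'   structure branch has learnable signal.
#' @param seed generator seed; all outputs are deterministic given it.
#' @return a \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(nProteins = 4, coreMotif = "TGCATG",
                          flankMotifs = NULL, motifMutationRate = 0.1,
                          nPos = 500, negPerPosRatio = NULL,
                          intervalLengthRange = NULL,
                          conservation = c(0, 1, 2, 0.5),
                          dialect = c("rbp24-style", "rbp31-style"),
                          markovBackground = FALSE, plantHairpins = FALSE,
                          seed = 1) {
  dialect <- match.arg(dialect)
  if (is.null(negPerPosRatio))
    negPerPosRatio <- if (dialect == "rbp31-style") 4 else 1
  if (is.null(intervalLengthRange))
    intervalLengthRange <- if (dialect == "rbp31-style") c(101L, 101L)
                           else c(150L, 375L)
  nProteins <- as.integer(nProteins)
  if (is.null(flankMotifs)) {
    flankMotifs <- .with_seed(.child_seed(seed, "flanks"),
      vapply(seq_len(nProteins), function(i)
        paste(sample(.DNA_ALPHABET, 6, replace = TRUE), collapse = ""),
        character(1)))
  }
  nNeg <- as.integer(round(nPos * negPerPosRatio))
  new("SyntheticSpec",
      nProteins = nProteins,
      coreMotif = toupper(coreMotif),
      flankMotifs = toupper(flankMotifs),
      motifMutationRate = motifMutationRate,
      nPos = as.integer(nPos),
      nNeg = nNeg,
      intervalLengthRange = as.integer(intervalLengthRange),
      negPerPosRatio = negPerPosRatio,
      conservation = conservation,
      dialect = dialect,
      markovBackground = markovBackground,
      plantHairpins = plantHairpins,
      seed = as.integer(seed))
}

.rand_seq <- function(n, len, markov = FALSE) {
  ## len may be a vector; returns character vector of background sequences
  vapply(len, function(l) {
    if (!markov) {
      paste(sample(.DNA_ALPHABET, l, replace = TRUE), collapse = "")
    } else {
      ## mild first-order dependence: 40% chance to repeat previous base
      ch <- character(l)
      ch[1L] <- sample(.DNA_ALPHABET, 1L)
      for (i in seq_len(l - 1L) + 1L) {
        ch[i] <- if (runif(1) < 0.4) ch[i - 1L]
                 else sample(.DNA_ALPHABET, 1L)
      }
      paste(ch, collapse = "")
    }
  }, character(1))
}

.mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.DNA_ALPHABET, ch[i]), 1L)
  paste(ch, collapse = "")
}

## Generate one protein's worth of raw samples (in transcript orientation).
.gen_protein_samples <- function(spec, motif, n_pos, n_neg, seed) {
  .with_seed(seed, {
    rng <- spec@intervalLengthRange
    m <- nchar(motif)
    draw_len <- function(n) {
      if (rng[1L] == rng[2L]) rep.int(rng[1L], n)
      else sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
    }
    lens_pos <- draw_len(n_pos)
    lens_neg <- draw_len(n_neg)

    pos_seq <- character(n_pos)
    pos_off <- integer(n_pos)      # 1-based motif start within sequence
    for (i in seq_len(n_pos)) {
      l <- lens_pos[i]
      s <- .rand_seq(1L, l, spec@markovBackground)
      ## uniform placement within the central 50%: a recentred window of
      ## length L >= l/2 is guaranteed to retain the motif
      lo <- l %/% 4L + 1L
      hi <- lo + l %/% 2L - m
      if (hi < lo) { lo <- 1L; hi <- l - m + 1L }
      off <- sample(lo:hi, 1L)
      mut <- .mutate_motif(motif, spec@motifMutationRate)
      substr(s, off, off + m - 1L) <- mut
      if (spec@plantHairpins && l >= 16L) {
        arm <- substr(s, 1L, 6L)
        substr(s, l - 5L, l) <- .revcomp(arm)
      }
      pos_seq[i] <- s
      pos_off[i] <- off
    }
    neg_seq <- character(n_neg)
    core <- spec@coreMotif
    for (i in seq_len(n_neg)) {
      repeat {
        s <- .rand_seq(1L, lens_neg[i], spec@markovBackground)
        if (!grepl(core, s, fixed = TRUE)) break
      }
      neg_seq[i] <- s
    }

    cv <- spec@conservation
    cons_pos <- lapply(seq_len(n_pos), function(i) {
      v <- rnorm(lens_pos[i], cv[1L], cv[2L])
      idx <- pos_off[i]:(pos_off[i] + m - 1L)
      v[idx] <- rnorm(m, cv[3L], cv[4L])
      v
    })
    cons_neg <- lapply(lens_neg, function(l) rnorm(l, cv[1L], cv[2L]))

    list(seq = c(pos_seq, neg_seq),
         cons = c(cons_pos, cons_neg),
         label = rep(c(1L, 0L), c(n_pos, n_neg)),
         motif_off = c(pos_off, rep(NA_integer_, n_neg)))
  })
}

#' Generate a synthetic benchmark collection
#'
#' Emits a synthetic genome FASTA, a per-base conservation bedGraph and
#' per-protein FASTA files whose headers carry genomic coordinates in the
#' dialect's grammar, then loads everything back through the package's own
#' readers ([loadBenchmarkFasta()], [readConservationTrack()]) so the
#' returned manifests exercised the real I/O path. 80\% of each protein's
#' samples are tagged \code{train}, the rest \code{eval}, stratified by
#' label. Fully deterministic under the spec seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created; default a fresh temp directory).
#' @return list with \code{manifests} (named list of
#'   \linkS4class{RBPSampleSet}, one per protein), \code{genome} (FASTA
#'   path), \code{track} (bedGraph path) and \code{dir}
#' @export
generateCollection <- function(spec, dir = tempfile("synthcoll")) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  margin <- 60L
  slot_w <- spec@intervalLengthRange[2L] + 2L * margin
  chrom <- "synth1"

  proteins <- sprintf("RBP%02d", seq_len(spec@nProteins))
  all_seq <- character(0); all_cons <- list(); all_label <- integer(0)
  all_prot <- character(0)
  for (p in seq_len(spec@nProteins)) {
    motif <- paste0(spec@coreMotif, spec@flankMotifs[p])
    raw <- .gen_protein_samples(spec, motif, spec@nPos, spec@nNeg,
                                .child_seed(spec@seed, paste0("prot", p)))
    all_seq <- c(all_seq, raw$seq)
    all_cons <- c(all_cons, raw$cons)
    all_label <- c(all_label, raw$label)
    all_prot <- c(all_prot, rep(proteins[p], length(raw$seq)))
  }
  n_tot <- length(all_seq)
  lens <- nchar(all_seq)

  ## assign strands, splits and genomic slots deterministically
  meta <- .with_seed(.child_seed(spec@seed, "layout"), {
    strand <- sample(c("+", "-"), n_tot, replace = TRUE)
    split <- character(n_tot)
    for (p in unique(all_prot)) for (lb in 0:1) {
      ix <- which(all_prot == p & all_label == lb)
      ntr <- floor(0.8 * length(ix))
      tr <- sample(ix, ntr)
      split[tr] <- "train"
      split[setdiff(ix, tr)] <- "eval"
    }
    list(strand = strand, split = split)
  })

  slot_start0 <- (seq_len(n_tot) - 1L) * slot_w   # 0-based slot origins
  start0 <- slot_start0 + margin
  end0 <- start0 + lens
  genome_len <- n_tot * slot_w

  ## genomic-orientation sequence and conservation per sample
  gseq <- all_seq
  gcons <- all_cons
  neg_strand <- meta$strand == "-"
  if (any(neg_strand)) {
    gseq[neg_strand] <- .revcomp(gseq[neg_strand])
    gcons[neg_strand] <- lapply(gcons[neg_strand], rev)
  }

  ## assemble the chromosome slot by slot: left margin, sample (genomic
  ## orientation), right filler up to the slot width
  chrom_seq <- .with_seed(.child_seed(spec@seed, "filler"), {
    pieces <- vapply(seq_len(n_tot), function(i) {
      right <- slot_w - margin - lens[i]
      paste0(.rand_seq(1L, margin), gseq[i], .rand_seq(1L, right))
    }, character(1))
    paste(pieces, collapse = "")
  })
  genome_fa <- file.path(dir, "genome.fa")
  gss <- Biostrings::DNAStringSet(chrom_seq)
  names(gss) <- chrom
  Biostrings::writeXStringSet(gss, genome_fa)

  ## per-base conservation bedGraph over the sample intervals
  track_path <- file.path(dir, "conservation.bedGraph")
  pos0 <- unlist(lapply(seq_len(n_tot), function(i) start0[i]:(end0[i] - 1L)))
  val <- unlist(gcons)
  writeLines(sprintf("%s\t%d\t%d\t%.4f", chrom, pos0, pos0 + 1L, val),
             track_path)

  ## per-protein FASTA files in the dialect's header grammar
  hdr <- if (spec@dialect == "rbp31-style")
    function(i) sprintf("%s,%d,%d,%s", chrom, start0[i], end0[i],
                        meta$strand[i])
  else
    function(i) sprintf("%s:%d-%d(%s)", chrom, start0[i], end0[i],
                        meta$strand[i])
  fasta_files <- list()
  for (p in proteins) {
    for (sp in c("train", "eval")) for (lb in c(1L, 0L)) {
      ix <- which(all_prot == p & all_label == lb & meta$split == sp)
      f <- file.path(dir, sprintf("%s.%s.%s.fa", p, sp,
                                  if (lb == 1L) "pos" else "neg"))
      ss <- Biostrings::DNAStringSet(all_seq[ix])
      names(ss) <- vapply(ix, hdr, character(1))
      Biostrings::writeXStringSet(ss, f)
      fasta_files[[p]] <- rbind(fasta_files[[p]],
                                data.frame(file = f, label = lb, split = sp))
    }
  }

  track <- readConservationTrack(track_path)
  manifests <- lapply(proteins, function(p) {
    ft <- fasta_files[[p]]
    man <- loadBenchmarkFasta(ft$file, ft$label, protein = p,
                              dialect = spec@dialect, split = ft$split)
    man@structure <- getStructure(sampleSequences(man))
    attachConservation(man, track)
  })
  names(manifests) <- proteins
  list(manifests = manifests, genome = genome_fa, track = track_path,
       dir = dir)
}

#' Attach conservation scores to a whole sample set at once
#'
#' Vectorised equivalent of calling [encodeConservation()] per sample:
#' every base of every interval receives the overlapping track score (0
#' where the track is silent), reversed for minus-strand intervals.
#'
#' @param x an \linkS4class{RBPSampleSet}.
#' @param track \code{GRanges} with a \code{score} column.
#' @return \code{x} with the conservation slot populated
#' @export
attachConservation <- function(x, track) {
  gr <- sampleIntervals(x)
  n <- length(gr)
  w <- GenomicRanges::width(gr)
  offs <- c(0L, cumsum(w))
  out <- numeric(sum(w))
  ov <- GenomicRanges::findOverlaps(track, gr, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    a <- pmax(GenomicRanges::start(track)[q], GenomicRanges::start(gr)[s])
    b <- pmin(GenomicRanges::end(track)[q], GenomicRanges::end(gr)[s])
    len <- b - a + 1L
    rel <- a - GenomicRanges::start(gr)[s] + offs[s]   # 0-based into out
    idx <- sequence(len, from = rel + 1L)
    out[idx] <- rep.int(track$score[q], len)
  }
  cons <- lapply(seq_len(n), function(i) {
    v <- out[(offs[i] + 1L):offs[i + 1L]]
    if (as.character(GenomicRanges::strand(gr)[i]) == "-") rev(v) else v
  })
  x@conservation <- IRanges::NumericList(cons)
  validObject(x)
  x
}

#' Generate a transfer family: baseline proteins plus a held-out protein
#'
#' All proteins share the core motif; the held-out protein (the last one)
#' carries a flank never seen by the baseline proteins, so a base model
#' pretrained on the baseline has transferable but incomplete knowledge of
#' the held-out binding rule.
#'
#' @param spec a \linkS4class{SyntheticSpec} with \code{nProteins >= 2}.
#' @param dir output directory.
#' @return list with \code{baseline} (list of manifests), \code{heldout}
#'   (one manifest), \code{genome}, \code{track}, \code{dir}
#' @export
generateTransferFamily <- function(spec, dir = tempfile("synthfam")) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nProteins < 2L)
    stop("a transfer family needs at least 2 proteins")
  ## make the held-out flank distinct from every baseline flank
  nb <- spec@nProteins - 1L
  fl <- spec@flankMotifs
  if (fl[spec@nProteins] %in% fl[seq_len(nb)]) {
    fl[spec@nProteins] <- .with_seed(.child_seed(spec@seed, "heldflank"), {
      repeat {
        cand <- paste(sample(.DNA_ALPHABET, 6, replace = TRUE), collapse = "")
        if (!cand %in% fl[seq_len(nb)]) break
      }
      cand
    })
    spec@flankMotifs <- fl
  }
  coll <- generateCollection(spec, dir)
  n <- length(coll$manifests)
  list(baseline = coll$manifests[seq_len(n - 1L)],
       heldout = coll$manifests[[n]],
       genome = coll$genome, track = coll$track, dir = coll$dir)
}
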