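## Interval arithmetic, strand-aware sequence extraction, conservation-track
## I/O and the secondary-structure adapter.
##
## Intervals live in GRanges (1-based, closed). The centering arithmetic is
## defined on the 0-based half-open convention used at the BED/header
## boundary: c = floor((start0 + end0) / 2), window = [c - floor(L/2),
## c - floor(L/2) + L). For even L the extra base falls 3' of the center.

#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps resize
#' @importFrom IRanges IRanges
NULL

#' Recenter genomic intervals to a fixed length
#'
#' Every output interval has length exactly \code{L} and shares its midpoint
#' with the input under the convention above, which makes the operation
#' idempotent and keeps midpoints identical across different \code{L}
#' (so interval-length sweeps stay comparable by construction). Windows that
#' would underflow the chromosome start (or overflow a known chromosome end)
#' are shifted minimally to fit, with a warning; a chromosome shorter than
#' \code{L} is an error.
#'
#' @param x a \code{GRanges}.
#' @param L target length in nucleotides (default 150, the standard
#'   recentred site length).
#' @return a \code{GRanges} of width \code{L}
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 145), "+")
#' recenterIntervals(gr, 150)  # 0-based [100,145) -> [47,197)
#' @export
recenterIntervals <- function(x, L = 150L) {
  stopifnot(is(x, "GRanges"))
  L <- as.integer(L)
  if (L < 1L) stop("target length L must be >= 1")
  s0 <- start(x) - 1L       # 0-based inclusive start
  e0 <- end(x)              # 0-based exclusive end
  ctr <- (s0 + e0) %/% 2L
  ns0 <- ctr - L %/% 2L
  shifted <- FALSE
  under <- ns0 < 0L
  if (any(under)) { ns0[under] <- 0L; shifted <- TRUE }
  sl <- GenomeInfoDb::seqlengths(x)[as.character(seqnames(x))]
  known <- !is.na(sl)
  if (any(known & sl < L))
    stop("chromosome shorter than L = ", L, " nt: ",
         paste(unique(as.character(seqnames(x))[known & sl < L]), collapse = ", "))
  over <- known & (ns0 + L > sl)
  if (any(over)) { ns0[over] <- sl[over] - L; shifted <- TRUE }
  if (shifted)
    warning("some recentred windows were shifted to fit chromosome bounds")
  out <- x
  GenomicRanges::ranges(out) <- IRanges(start = ns0 + 1L, width = L)
  out
}

#' Extract strand-aware sequences for intervals
#'
#' Returns the forward-strand substring for each interval,
#' reverse-complemented for minus-strand intervals, so the result reads
#' 5'->3' along the transcribed strand.
#'
#' @param genome a FASTA file path, an \code{Rsamtools::FaFile} or a named
#'   \code{DNAStringSet}. A missing FASTA index is created on the fly.
#' @param x a \code{GRanges}.
#' @return character vector of sequences, one per interval
#' @export
extractSequences <- function(genome, x) {
  stopifnot(is(x, "GRanges"))
  if (is.character(genome)) {
    if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
    genome <- Rsamtools::FaFile(genome)
  }
  if (is(genome, "FaFile")) {
    seqinfo <- Rsamtools::seqinfo(genome)
    missing <- setdiff(unique(as.character(seqnames(x))),
                       GenomeInfoDb::seqnames(seqinfo))
    if (length(missing))
      stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
    lens <- GenomeInfoDb::seqlengths(seqinfo)[as.character(seqnames(x))]
    if (any(start(x) < 1L) || any(end(x) > lens))
      stop("interval out of chromosome bounds")
    return(unname(as.character(Biostrings::getSeq(genome, x))))
  }
  if (is(genome, "DNAStringSet")) {
    nm <- as.character(seqnames(x))
    missing <- setdiff(unique(nm), names(genome))
    if (length(missing))
      stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
    if (any(start(x) < 1L) || any(end(x) > Biostrings::width(genome)[match(nm, names(genome))]))
      stop("interval out of chromosome bounds")
    seqs <- as.character(Biostrings::subseq(genome[nm], start = start(x), end = end(x)))
    neg <- as.character(strand(x)) == "-"
    if (any(neg)) seqs[neg] <- .revcomp(seqs[neg])
    return(unname(seqs))
  }
  stop("genome must be a FASTA path, FaFile or DNAStringSet")
}

#' Read a per-base conservation track
#'
#' Accepts wiggle fixedStep, wiggle variableStep and bedGraph dialects
#' (auto-detected from the file content) and returns a \code{GRanges} with a
#' numeric \code{score} column. Wiggle's 1-based starts and bedGraph's
#' 0-based half-open intervals are both mapped onto the internal 1-based
#' closed convention on read.
#'
#' @param path track file path.
#' @param region optional \code{GRanges}; only ranges overlapping it are
#'   returned.
#' @return \code{GRanges} with a \code{score} column
#' @export
readConservationTrack <- function(path, region = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  fmt <- if (any(grepl("^(fixedStep|variableStep)", head_lines))) "wig"
         else "bedGraph"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse ", fmt, " track '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  gr <- GenomicRanges::GRanges(gr)   # drop UCSCData subclass
  if (!is.null(region))
    gr <- IRanges::subsetByOverlaps(gr, region, ignore.strand = TRUE)
  gr
}

#' Write a score track as bedGraph
#'
#' @param track \code{GRanges} with a \code{score} column.
#' @param path output path.
#' @return \code{path}, invisibly
#' @export
writeBedGraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Secondary-structure sources
## ---------------------------------------------------------------------------

#' Secondary-structure sources
#'
#' Three interchangeable ways to obtain a dot-bracket string for a sequence:
#' \describe{
#'   \item{\code{structureStub()}}{a deterministic in-package fold used for
#'     testing and synthetic data: if the longest run of Watson-Crick
#'     complementary prefix/suffix positions is at least \code{minStem}, that
#'     terminal stem is paired and the rest left unpaired; otherwise the
#'     string is all dots.}
#'   \item{\code{structureFile(path)}}{precomputed structures from a
#'     two-column TSV (sequence, dot-bracket).}
#'   \item{\code{structureExternal(command)}}{shells out to an RNA-folding
#'     executable (\code{RNAfold}-compatible: reads a sequence on stdin,
#'     prints the dot-bracket line second) and parses its output.}
#' }
#'
#' @slot mode one of "stub", "precomputed-file", "external-folder".
#' @slot parameters mode-specific parameter list.
#' @export
setClass("StructureSource",
         representation(mode = "character", parameters = "list"))

setValidity("StructureSource", function(object) {
  if (!object@mode %in% c("stub", "precomputed-file", "external-folder"))
    "mode must be stub, precomputed-file or external-folder" else TRUE
})

setMethod("show", "StructureSource", function(object) {
  cat("StructureSource <", object@mode, ">\n", sep = "")
})

#' @rdname StructureSource-class
#' @param minStem minimum complementary terminal run to pair (stub mode).
#' @export
structureStub <- function(minStem = 3L) {
  new("StructureSource", mode = "stub",
      parameters = list(minStem = as.integer(minStem)))
}

#' @rdname StructureSource-class
#' @param path TSV file with columns sequence, structure.
#' @export
structureFile <- function(path) {
  new("StructureSource", mode = "precomputed-file",
      parameters = list(path = path))
}

#' @rdname StructureSource-class
#' @param command folding executable (default \code{"RNAfold"}).
#' @export
structureExternal <- function(command = "RNAfold") {
  new("StructureSource", mode = "external-folder",
      parameters = list(command = command))
}

.stub_fold_one <- function(s, min_stem) {
  n <- nchar(s)
  if (n == 0L) return("")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  m <- 0L
  while (m < n %/% 2L && !is.na(comp[m + 1L]) &&
         comp[m + 1L] == ch[n - m]) m <- m + 1L
  if (m >= min_stem)
    paste0(strrep("(", m), strrep(".", n - 2L * m), strrep(")", m))
  else
    strrep(".", n)
}

#' Obtain dot-bracket structure for sequences
#'
#' Dispatches on the configured \linkS4class{StructureSource}; the returned
#' string always has the same length as its input sequence.
#'
#' @param sequence character vector of nucleotide sequences.
#' @param source a \linkS4class{StructureSource}; default is the
#'   deterministic stub.
#' @return character vector of dot-bracket strings
#' @examples
#' getStructure("GGGGAAAACCCC")  # "((((....))))"
#' @export
getStructure <- function(sequence, source = structureStub()) {
  stopifnot(is(source, "StructureSource"))
  out <- switch(source@mode,
    "stub" = vapply(sequence, .stub_fold_one,
                    character(1), min_stem = source@parameters$minStem,
                    USE.NAMES = FALSE),
    "precomputed-file" = {
      tab <- utils::read.table(source@parameters$path, header = FALSE,
                               sep = "\t", col.names = c("sequence", "structure"),
                               colClasses = "character")
      idx <- match(sequence, tab$sequence)
      if (anyNA(idx))
        stop("no precomputed structure for ", sum(is.na(idx)), " sequence(s)")
      tab$structure[idx]
    },
    "external-folder" = {
      cmd <- source@parameters$command
      if (Sys.which(cmd) == "")
        stop("external folding tool '", cmd, "' not found on PATH; ",
             "use structureStub() or structureFile() instead")
      vapply(sequence, function(s) {
        res <- system2(cmd, args = "--noPS", input = s, stdout = TRUE)
        db <- sub("^([.()]+).*$", "\\1", res[length(res)])
        if (nchar(db) != nchar(s))
          stop("could not parse dot-bracket output of '", cmd, "'")
        db
      }, character(1), USE.NAMES = FALSE)
    })
  stopifnot(all(nchar(out) == nchar(sequence)))
  out
}

## ---------------------------------------------------------------------------
## Header/BED coordinate conversion helpers (0-based half-open boundary)
## ---------------------------------------------------------------------------

## 0-based half-open (chrom, start, end, strand) -> GRanges
.gr_from_bed0 <- function(chrom, start0, end0, strand) {
  GRanges(chrom, IRanges(start = as.integer(start0) + 1L,
                         end = as.integer(end0)),
          strand = strand)
}

## GRanges -> data.frame in 0-based half-open coordinates
.bed0_from_gr <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L,
             end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}
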