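#' @import methods
#' @importFrom stats predict rnorm runif setNames quantile
#' @importFrom Rcpp evalCpp
#' @useDynLib rbptl, .registration = TRUE
NULL

#' @export
setGeneric("bpeTokenize", function(vocab, x, ...) standardGeneric("bpeTokenize"))

#' @export
setGeneric("bpeDetokenize", function(vocab, tokens, ...) standardGeneric("bpeDetokenize"))

#' @export
setGeneric("sampleIntervals", function(x) standardGeneric("sampleIntervals"))

#' @export
setGeneric("sampleSequences", function(x) standardGeneric("sampleSequences"))

#' @export
setGeneric("sampleStructures", function(x) standardGeneric("sampleStructures"))

#' @export
setGeneric("sampleConservation", function(x) standardGeneric("sampleConservation"))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setGeneric("sampleProteins", function(x) standardGeneric("sampleProteins"))

#' @export
setGeneric("sampleSplit", function(x) standardGeneric("sampleSplit"))

#' @export
setGeneric("trainingSet", function(x) standardGeneric("trainingSet"))

#' @export
setGeneric("evaluationSet", function(x) standardGeneric("evaluationSet"))

#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' @export
setGeneric("vocabMerges", function(x) standardGeneric("vocabMerges"))

#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))
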