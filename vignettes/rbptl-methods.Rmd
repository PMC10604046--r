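---
title: "Predicting RBP target sites with transfer learning: models and methods"
author: "rbptl maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RBP target sites with transfer learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

RNA-binding proteins (RBPs) recognise short, degenerate sequence and
structure elements on transcripts. CLIP-seq experiments yield a set of
genomic intervals supported as bound (positives) and, after suitable
negative construction, intervals assumed unbound. For most RBPs the number
of experimentally supported sites is far too small to train a deep
classifier from scratch. `rbptl` implements a transfer-learning answer: a
base model (BS) is pretrained on the merged sites of many proteins to learn
features shared across RBPs, then fine-tuned (TL) on the — possibly tiny —
dataset of a single protein, and compared against the same architecture
trained from scratch (SCR).

## Input features and their encodings

Each candidate site is a genomic interval recentred to a fixed length
(default 150 nt; the interval-length sweep covers 100–300 nt in 50-nt
steps). The recentring convention, on 0-based half-open coordinates, is
`c = floor((start + end) / 2)`, window `[c - floor(L/2), c - floor(L/2) + L)`;
for even `L` the extra base falls 3' of the centre. This makes recentring
idempotent, and windows at different `L` share midpoints, so sweep results
are comparable by construction. Internally intervals live in `GRanges`
(1-based closed, the Bioconductor convention); the 0-based half-open form
appears only at BED/header/bedGraph boundaries.

Three parallel per-site features feed the classifier:

* **S — sequence.** Byte-pair encoding over {A, C, G, T}: the vocabulary is
  grown by merging the most frequent adjacent token pair until `k` tokens
  exist (supported sizes 16, 32, 64). Pair frequencies are counted within
  each corpus sequence independently — pairs never span a sequence
  boundary; whether the original tokenizers counted across boundaries is
  unknowable from their description, so the local rule was fixed and
  documented. Frequency ties break toward the lexicographically smallest
  pair, making training deterministic. Tokenization is greedy
  longest-match, which cannot produce unknown tokens; detokenization is the
  identity. Us are mapped to Ts and input is uppercased; Ns are rejected by
  default (an opt-in flag replaces them with seeded random bases).
* **SS — secondary structure.** A dot-bracket string of the same length,
  one-hot encoded as an n×3 matrix with fixed column order `.`, `(`, `)`.
  Structures come from one of three interchangeable sources: an external
  folding executable (`RNAfold`-compatible), a precomputed table, or a
  deterministic in-package stub that pairs the longest Watson–Crick
  complementary terminal run (minimum stem 3) and otherwise returns all
  dots. The stub exists so every downstream stage is testable without an
  external folder; it is not a thermodynamic model.
* **EC — evolutionary conservation.** One floating-point score per base,
  taken raw from a wiggle/bedGraph track (phyloP-style scores are
  legitimately negative, so no clipping or normalisation is applied by
  default; an optional standardisation flag exists). Positions without
  track data score 0.

All three features are ordered 5'→3' along the transcribed strand: sequences
are reverse-complemented and conservation vectors reversed for minus-strand
intervals, keeping the three branches positionally aligned. Whether the
original pipelines reversed minus-strand conservation is not documented
anywhere we could verify; the alignment choice here is the package's own.

## The three-branch classifier

The S branch embeds token ids (dimension 16–128), applies a 1D convolution
(kernel 5, stride 1, same padding, ReLU), a bidirectional GRU (64–512 units
per direction) and an additive attention layer
(`e_t = v' tanh(W h_t + b)`, masked softmax over positions, context
`sum_t alpha_t h_t`). The SS (n×3) and EC (n×1) branches apply 2–3 residual
blocks — two 1D convolutions (kernel 3) with batch normalisation and ReLU
plus an identity skip, a 1×1 projection where channel counts differ —
followed by global average pooling. Branch outputs are concatenated and
passed through 2–3 fully connected layers (width 128, ReLU, dropout 0.2)
and a sigmoid unit.

The attention variant, kernel sizes, pooling, head width and dropout are
fixed constants of this package (centralised in `nnConstants()`), chosen as
the standard options of the CNN–RNN–attention hybrid family; they are not
claims about any other implementation. Attention weights are exported per
token and mapped to nucleotides by dividing each token's weight equally
among its bases, the minimal assumption that turns token-level scores into
the nucleotide-resolution profiles interpretation needs.

The network, backpropagation and the Adam optimiser are implemented in the
package itself (R assembly over compiled Armadillo kernels in
`src/kernels.cpp`), with analytic gradients verified against numerical
differentiation in the test suite. Inference is deterministic: dropout is
off and batch normalisation uses running statistics, so batched and
single-sample predictions agree and checkpoints reproduce predictions
bit for bit.

## Training protocols

* **BS** pretrains on the merged "baseline": all proteins' training samples
  are pooled, negatives overlapping (≥1 shared base, same chromosome and —
  by default — strand) any included protein's binding site are removed,
  and uniformly random positives are removed to restore the pre-merge
  positive:negative ratio. Evaluation sets are never merged or altered.
  One protein can be excluded wholesale to act as truly unseen data.
* **SCR** trains the same architecture from random initialisation on a
  single protein.
* **TL** initialises every parameter from a BS checkpoint and fine-tunes
  all layers (no freezing by default; a freeze-list exists for ablations) at
  a 10× smaller learning rate.

Defaults, fixed in `trainSpec()`: Adam, learning rate 1e-3 (BS/SCR) or
1e-4 (TL), batch 64, early stopping on validation AUC with patience 5, at
most 100 epochs, best-validation checkpoint returned. Training/validation
splits are 9:1, stratified by (protein, label) with largest-remainder
allocation so small strata never vanish from validation. Class weighting is
off by default even for 1:4 collections, with inverse-frequency weights
behind a flag.

Evaluation is the rank-based ROC AUC — the Mann–Whitney statistic with ties
counted one half, the quantity all comparator tools report. The printed
closed forms of this statistic vary across sources (and are frequently
garbled in typesetting); the rank definition is unambiguous and is verified
against an exhaustive pairwise oracle to 1e-12.

`planExperiments()` reproduces the full benchmark matrix: one BS per
collection plus one SCR and one TL per protein — 2 + 55 + 55 = 112 jobs for
collections of 24 and 31 proteins. `nestedSubsample()` builds the
100/250/500/1000/5000/10000/25000-per-class ladder in which every smaller
rung is a subset of every larger one, and `runSubsampleExperiment()`
averages TL and SCR over replicate trainings per rung.

## Staged hyperparameter optimisation

The search space (defaults in `searchSpace()`) is explored in four
stages following the network's structure: (1) BiGRU units × embedding
dimension (16 combinations), (2) tokenizer size (3) — a dimension plain
random search cannot tune, because tokenization happens before training,
(3) convolution filters × residual blocks (6), shared between the SS and EC
branches since they share one architecture, (4) dense layer count (2).
Every candidate is scored by mean AUC over a stratified 10-fold
cross-validation; each stage's winner is frozen into all later stages, so
the default space costs 16 + 3 + 6 + 2 = 27 evaluated configurations
instead of the 576-point grid. Ties break toward the smaller model, then
option order. `downsampleForHPO()` shrinks very large training sets
(e.g. to 1/4) per class while preserving the ratio. The random-search
baseline (`runRandomSearch()`, 27 trials to match) shares the identical
cross-validated scoring path, so comparisons isolate the search strategy.
During HPO, candidate fits use a shortened budget (patience 3, at most 30
epochs); the winning configuration is meant to be retrained with the full
`trainSpec()` afterwards. Wall-clock timings are hardware-bound and are
reported only informationally.

## Attention interpretation

For a trained model, the 50 highest-probability predicted-bound evaluation
sequences (probability ≥ 0.5; both values configurable) are selected, the
20-nt window of maximal average attention extracted from each (leftmost on
ties), and all overlapping 6-mers within the windows counted, ordered by
count then lexicographically. On synthetic data,
`motifRecoveryCheck()` asks whether any top-3 k-mer lies within the planted
consensus (substring or Hamming distance ≤ 1), turning "the model looked at
the motif" into a testable property. Windows map back to strand-aware
genomic coordinates for BED export.

## The synthetic benchmark generator

`syntheticSpec()`/`generateCollection()` emulate the two benchmark
flavours: variable-length balanced collections (native lengths 150–375 nt)
and fixed 101-nt collections at a 1:4 positive:negative ratio. Each
"protein" plants a motif composed of a shared 6-nt core (`TGCATG` by
default — a classic compact RBP recognition element) plus a protein-specific
6-nt flank, mutated at 10% per base by default; positives place the motif
uniformly within the central 50% of the interval, negatives are background
rejected only for the exact core consensus. Conservation is Gaussian —
N(0, 1) background against N(2, 0.5) over motif positions — stored
unclipped since real conservation scores can be negative. Background
sequence is i.i.d. uniform by default (an optional first-order Markov
background exists); structure strings come from the deterministic stub,
optionally with planted terminal hairpins to give the SS branch learnable
signal. The generator emits a genome FASTA, a per-base bedGraph track and
per-protein FASTA files with coordinate-carrying headers, then reads
everything back through the package's own loaders, so the returned
manifests have exercised the real I/O path. Every output is deterministic
given the spec seed. 80% of each protein's samples are tagged `train`, the
rest `eval`, stratified by label.

What the generator does **not** emulate: genomic base composition and
repeat structure, CLIP crosslink biases, read-pileup-derived negative
construction, overlapping sites between proteins, and real secondary
structure. Passing the end-to-end tests therefore demonstrates that the
implementation learns and transfers planted signal under controlled
conditions — not that it reproduces published benchmark accuracies on real
CLIP data.

`generateTransferFamily()` scaffolds the transfer experiment: baseline
proteins share the core, the held-out protein combines the core with a
flank never seen in the baseline, so a base model carries transferable but
incomplete knowledge — the regime in which fine-tuning should beat training
from scratch at small sample sizes.

## Desk-scale experiment sizes

The bundled experiments (`runSolvabilityExperiment()`,
`runTransferFamilyExperiment()`, also driven by `scripts/acceptance.R`) use
sizes chosen so a complete run finishes in minutes on one CPU while leaving
the tested effects clearly resolvable: a single-protein zero-noise
collection with 500 training samples per class for the solvability check
(training budget 8 epochs, patience 3 — validation AUC saturates within the
first few epochs on noise-free data); a four-protein family with 500
positives per protein for base-model pretraining (8 epochs, patience 3);
and five replicate seeds of TL-vs-SCR at 100 held-out samples per class
(12 epochs, patience 4). The directional claims — transfer strictly beats
scratch at 100 samples per class, and attention recovers the planted core —
are the desk-scale analogues of the published large-data observations;
their magnitudes are not comparable to results on the real collections.

## Numerical choices and degenerate inputs

* BPE stops early (|tokens| < k) when no pair occurs twice; tokenizing an
  empty string returns empty tokens and spans.
* Recentred windows that would underflow position 0 (or overflow a known
  chromosome end) are shifted minimally to fit, with a warning — dropping
  samples would silently change dataset sizes; a chromosome shorter than
  the window is an error.
* Batch normalisation uses eps 1e-5 and running-average momentum 0.9;
  Glorot-uniform initialisation throughout; all randomness (initialisation,
  shuffling, dropout, subsampling, splits) flows from explicit seeds, and
  library calls restore the caller's RNG state.
* The maximal-attention window scan uses cumulative sums; ties (and
  float-noise near-ties below 1e-12) resolve to the leftmost window.
* Padded token positions are masked out of attention (−Inf before softmax),
  and the backward GRU direction processes each sequence reversed within
  its own length, so padding never leaks into valid positions — this is
  what makes batched and single-sample predictions agree.
* `evaluateAUC()` refuses single-class inputs rather than returning NaN.

## Known limitations

* The secondary-structure stub is deliberately naive; for real analyses an
  `RNAfold`-compatible executable or precomputed structures should be used.
* Minimum-free-energy structure, in vivo probing data and liftover between
  genome builds are out of scope; users supply tracks matched to their
  genome build.
* The pure-desk-scale network (compiled kernels, one CPU) is sized for
  hundreds of thousands of training samples at most; it is not a GPU
  training framework.
* Negative construction by coordinate shuffling within bound genes is
  emulated only by the synthetic generator's rejection sampling, not
  re-derived for real data.
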