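---
title: "Promoter classification with triplet-embedded Bi-LSTMs and motif-preserving negatives"
author: "promForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter classification with triplet-embedded Bi-LSTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Eukaryotic promoters are the non-coding regions around a gene's
transcription start site (TSS) that initiate and regulate transcription.
A subset carries a TATA-box roughly 25-30 bp upstream of the TSS;
CAAT-box and GC-box elements occur further upstream (around -80..-70 and
-110..-80). Classifiers that must decide whether a fixed-length DNA
window contains a promoter face a subtle training-data problem: if the
negatives are drawn from distal genomic regions, they lack promoter
motifs entirely, the classification task becomes trivially easy, and the
resulting model degenerates into a motif detector that misfires on any
genomic window that happens to contain a TATA-like hexamer.

promForge implements the pipeline built around the answer to that
problem: *artificial* non-promoters constructed from the promoters
themselves, so that the negatives retain local motif content and the
model is forced to learn positional and long-range structure.

## Artificial negatives by block recombination

Each 300 nt promoter is split into 20 blocks of 15 nt. Eight block
indices are selected uniformly at random ("substitutional"); the
remaining twelve ("conservative") stay in place. The selected blocks are
re-assigned to the vacated positions by a uniform permutation, and the
blocks are re-joined. Consequences that the test suite checks
exhaustively:

* the block multiset is conserved, so the mononucleotide composition of
  the negative is *exactly* that of its template;
* trinucleotide content changes only in windows spanning block
  junctions (at most 2 x 19 triplet windows per sequence);
* motifs survive in the negative, usually displaced.

Two details are genuinely open in this construction and were fixed as
follows. First, the permutation may have fixed points (a selected block
can land back in its own slot); only the full identity outcome is
rejected, by redrawing the permutation up to `maxResample` times when
`forbidIdentity = TRUE`. A template whose eight selected blocks are all
identical in content can never produce a non-identical recombinant and
raises a construction error rather than looping forever. Second,
per-sequence seeds are derived from the master seed as
`seed_i = (master * 48271 + i) mod (2^31 - 1)` (one multiplicative
congruential step), so a subset of a corpus reproduces its negatives
independently of the rest — convenient both for parallel work and for
auditing single sequences. The full trace (selected indices,
permutation, seed) is recorded per negative and exported by the CLI.

## Triplet index encoding

A width-3 window slides along the sequence with step 1, so a 300 nt
window yields 298 overlapping triplets; each is looked up in a fixed
index table. The table orders the 64 A/C/G/T triplets lexicographically
(AAA = 1, ..., TTT = 64) and reserves index 0 for triplets containing N
and for right-padding in batch matrices. The choice of bijection is
immaterial for a freshly trained model, but fixing and exporting it
(`exportIndexTable()`) makes encodings reproducible across runs and
machines. N-containing windows map to the unknown index rather than
being dropped, which preserves the positional register of the encoding.
Encoding and decoding are exact inverses on N-free input, which the
suite property-tests over random sequences.

## Model

The classifier is, per sequence of `T = 298` indices:

1. **Embedding** (65 tokens -> 64 dims), giving a 298 x 64 matrix.
2. **Batch normalisation** over the 64 embedding features, statistics
   pooled across batch and sequence positions (the standard treatment of
   a (batch, position, feature) tensor); eps 1e-5, running-statistics
   momentum 0.1, inference uses running statistics.
3. **A single bidirectional LSTM layer**, 128 hidden units per
   direction, concatenated per position to a 298 x 256 matrix. One layer
   is the only depth consistent with that output shape.
4. **Flatten** to 76288 features (position-major; forward block then
   backward block per position).
5. **FC1** (76288 -> 128) with leaky-ReLU activation (slope 0.01), then
   **FC2** (128 -> 1) with a sigmoid, yielding a promoter probability.

The loss is mean binary cross-entropy with probabilities clipped to
`[1e-7, 1 - 1e-7]`. Decision threshold is 0.5 by default, with ties
(probability exactly equal to the threshold) classified positive; the
`>=` convention is documented and tested rather than left to chance.

The network, backpropagation through time and the Adam optimiser
(beta1 0.9, beta2 0.999, eps 1e-8) are implemented in compiled code
(RcppArmadillo) and run in single precision — the conventional precision
for this class of model, and about twice the throughput of double
precision on CPU. The compiled forward pass is verified in the suite
against an independent pure-R re-implementation of the layer stack, and
training is verified behaviourally (a separable toy problem is solved;
the synthetic benchmark below is separated at AUCROC >= 0.95).

Training hyperparameters: Adam at learning rate 0.001 (the optimiser's
conventional default; nothing in the architecture suggests another
choice), mini-batches of 64 with the last incomplete batch kept, the
training order reshuffled each epoch. Training always runs the full
epoch budget and afterwards restores the parameters of the epoch with
minimum validation loss (ties resolve to the earliest); validation loss
is computed on the full validation set after each epoch. Everything is
deterministic given the seeds: the `TrainConfig` master seed is split
into an initialisation seed and a shuffle seed by the same mixing rule
used for negatives.

## Coordinate convention

Biological promoter coordinates place the TSS at +1 with no position 0,
under which a "-249..+50" window nominally spans 299 positions — one
short of the stated 300 bp. Internally everything is therefore 0-based:
the TSS sits at index 249 of the 300 nt window, and a TSS-relative
position p maps to index 249 + p. Motif windows quoted in biological
coordinates are mapped through the same rule (TATA-box -30 gives index
219), which removes the off-by-one ambiguity while preserving the
geometry.

## The synthetic benchmark

Real promoter corpora (e.g. the Eukaryotic Promoter Database) are
deliberately out of scope; the simulator exists so every pipeline stage
is testable from code alone. Promoter-like positives are i.i.d. draws
from a background composition (uniform by default) with consensus
elements planted left-anchored at their canonical windows: TATAAA at
-30, GGCCAATCT at -80, GGGCGG at -110 (consensus strings follow standard
promoter-element descriptions; the coordinates fix only windows, so the
anchoring is a documented simulator choice, with jitter deliberately
omitted). Each consensus position is independently re-drawn from the
background with probability `mutationProb` (default 0.1), so the
expected per-position match rate has the closed form
`(1 - p) + p * q(letter)`, which the suite checks by simulation. The
"nonTATA" class plants only CAAT and GC boxes.

`generateBenchmark()` mirrors the benchmark design of the training
scheme: training negatives are block recombinations of the training
positives (1:1), while validation and test negatives are background
draws standing in for real non-promoters. All splits are balanced, and
splitting is stratified so a balanced input stays 1:1 in every split.

What passing on this benchmark shows — and does not show. Background
negatives contain no planted motifs, so held-out separation (the suite
requires AUCROC >= 0.95 at 1000 sequences per class, 8 training epochs,
fixed seeds; a run at these sizes takes a few minutes on one CPU)
demonstrates that the trained network recovers planted positional
signal through the full encode/train/evaluate path. It does not
demonstrate performance on real genomes: real backgrounds are not
i.i.d., real promoters vary in motif presence, spacing and strength,
and real negatives can be promoter-adjacent. The simulator is a
controllable separability knob, not a genome model.

## Metrics

Balanced accuracy, sensitivity, specificity, precision, F1 and the
Matthews correlation coefficient are computed from the confusion counts
in their standard forms. Zero-denominator cases (empty classes, no
positive calls) return 0, keeping each metric inside its nominal range;
this sentinel choice is documented because published formulas are
silent about it. The ROC area is trapezoidal over the full threshold
sweep, which equals the tie-corrected pairwise concordance probability —
the suite proves the identity against a brute-force pair count on
hundreds of random instances, and against an independent library
implementation. The PR area uses the step-wise average-precision rule
(no interpolation), under which an all-tied score vector yields the
class prevalence. Reports round to 2 decimals for display; full
precision is kept internally.

## Numerical and degenerate-input choices

* Single-precision network arithmetic; double precision at the R
  boundary. Determinism holds per machine for fixed seeds.
* BCE clipping eps 1e-7; batchnorm eps 1e-5, momentum 0.1 with biased
  variance throughout.
* `nSubstitutional = 1` is rejected at configuration time: a single
  relocated block can only return to its own slot, so the construction
  is either the identity or impossible.
* Sequences shorter than 3 nt cannot be encoded and error out;
  `encodeBatch` refuses rows longer than its padding width instead of
  truncating.
* `splitDataset` errors when any split would lose a class entirely
  rather than silently producing an unevaluable split.

## Problem sizes used by the shipped checks

The test suite runs its exhaustive structural checks at 1000
constructions/sequences and its end-to-end training check at 1000
sequences per class with an 0.8/0.1/0.1 split (1600 training records)
for 8 epochs — sizes at which the full pipeline completes in a few
minutes on a single CPU while leaving the statistical assertions
well-powered. The acceptance script (`scripts/acceptance.R`) re-runs the
same pipeline from scratch at the same sizes.

## Known limitations

* No real-data ingestion beyond plain FASTA; no redundancy filtering
  (CD-HIT-style identity clustering would be an external preprocessing
  step), no genome scanning, and no handling of soft-masked repeats
  beyond uppercasing.
* Only k = 3 encodings; no reverse-complement canonicalisation.
* One bidirectional LSTM layer; no dropout, attention or convolutional
  branches.
* The simulator's i.i.d. background understates the difficulty of real
  negative sets; reported synthetic metrics are upper bounds on realism.
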