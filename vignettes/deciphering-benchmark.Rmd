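---
title: "Measuring how much data a neural decoder needs to crack the genetic code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring how much data a neural decoder needs to crack the genetic code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The benchmark problem

The standard genetic code is a fixed many-to-one map from the 64 RNA codons
to 20 amino acids plus a stop mark (`*`), 21 target classes in all.
`codonDecipher` treats *re-discovering* this map as a supervised benchmark: a
neural network is shown (codon, amino-acid) pairs harvested from open reading
frames and their translated proteins, and we measure the cumulated number of
training pairs that must be presented before the network's decoded table is
**unequivocally complete** — every one of the 64 codons assigned its correct
class by argmax, with no exact probability tie, rare stop codons included.

The interesting quantity is not classification accuracy (any decoder reaches
~100% accuracy quickly, because frequent codons dominate the pair stream) but
this *data efficiency*: accuracy is frequency-weighted, while table
completeness is gated by the rarest classes — the three stop codons occur
roughly once per four hundred pairs, and their learning dynamics dominate the
metric.

## The synthetic corpus generator

`generate_corpus()` synthesizes mature coding sequences with the structure of
real ORFs:

* each record starts with `AUG`, ends with exactly one stop codon, has a
  length divisible by three and no internal in-frame stop;
* body codons are drawn i.i.d. from a codon-usage table restricted and
  renormalized to the 61 sense codons; the terminal stop is drawn from the
  table's stop-codon mass (in the bundled table UGA is the most frequent
  stop, as in human genes);
* codon counts per ORF follow a log-normal length model, median 400 codons
  (≈1,200 nucleotides, a typical mature transcript), log-sd 0.45 for the
  right skew of real transcript length distributions, clamped to [10, 3000].

The bundled usage table (`default_codon_usage()`) carries standard published
human codon frequencies; its most frequent codon is GAG even though the most
frequent amino acid in the resulting proteins is leucine — the mismatch
between source-language and target-language word frequencies that motivates
class weighting.  The table is an editable TSV, so any organism or protein
family can be emulated.

What the generator does *not* emulate: UTRs, introns, alternative splicing,
programmed frameshifts, sequencing noise, and — importantly — the long-range
composition structure of real transcriptomes.  Pairs are conditionally
independent draws given the usage table.  Tests passing on this corpus
demonstrate the machinery and the metric; absolute pair counts on real,
messier transcriptomes can be substantially larger.

## Decoders

All models map one codon to a point on the 21-class probability simplex:

* **Linear MLPs** (`MLP-LINEAR`) on 64-bit one-hot codons or 12-bit
  (3 × 4 bit) nucleotide-concatenation inputs, with zero, one or two hidden
  layers and *no* activation anywhere except the final softmax.  Deciphering
  is a linear problem — the whole network collapses to a single 64 → 21
  affine map, which a test verifies numerically.
* **Embedding MLPs** (`MLP-EMBED`): a learnable dense 64 × d codon embedding
  (d = 2 or 10 in the benchmark grid) feeding ReLU or tanh hidden layers.
  Synonymous codons acquire nearby embeddings as training progresses;
  `synonymy_clustering_score()` quantifies this.
* **Recurrent readers** (`RNN`, `GRU`, `LSTM`): two stacked tanh cells read
  the codon as three nucleotide timesteps from a freshly initialized hidden
  state and emit a single output after the third step.  Per-timestep input
  width is 4 (one nucleotide), so a codon is "12 bits read sequentially".

Weight matrices are initialized (semi-)orthogonally — exactly orthogonal for
the square recurrent state-transition matrices, the usual guard against
vanishing and exploding gradients — biases at zero, embeddings i.i.d. normal
with sd 1/√d.  All initialization is a pure function of the model seed.

Nucleotide one-hot vectors use the basis order A, U, C, G; 64-vectors are
indexed by the lexicographic codon order (A < C < G < U); target classes are
the 20 amino-acid letters alphabetically plus `*` at index 21.  The two
ordering conventions are independent and tested independently.

## Training and the epoch convention

Training minimizes multinomial cross-entropy (optionally class-weighted) with
Adam, batch 64, learning rate 0.05 for the MLP families and 0.005 for the
recurrent ones; Adam's moment parameters stay at their conventional defaults
(0.9, 0.999, 1e-8), there is no learning-rate schedule and no gradient
clipping; a non-finite loss aborts the run with a diagnostic.  Predicted
probabilities are guarded by 1e-12 inside the log.

An *epoch* is one pass over a fixed-size random subsample of training pairs —
561,600 pairs (8,775 batches) by default, resampled each epoch — rather than
a full pass over the corpus, so a 40-epoch cap corresponds to 22,464,000
cumulated pairs regardless of corpus size.  The 90/10 train/test split is
performed at ORF level so no sequence contributes pairs to both sides.

Class weights (`class_weights()`) are inversely proportional to the
amino-acid frequency distribution of the training proteins, floored at 1e-6
and normalized to mean 1 (the normalization only changes the effective
learning rate, not the relative penalties).  On human-like corpora the stop
mark receives a weight near 10 while leucine sits near 0.5, so stop-codon
errors are penalized about twenty-fold relative to the most common class.

## The deciphering verdict and its cadence

`decode_table()` feeds all 64 codons directly to the model and tabulates the
softmax rows.  This *direct enumeration* is a deliberate choice over
harvesting whichever codons happen to occur in a training batch: it is exact,
removes batch-composition noise from the verdict, and makes the metric a
property of the model alone.  A row counts as deciphered only if its argmax
matches the standard code and its maximum is attained by a single class;
exact ties (e.g. a codon split 50/50 between the stop mark and tryptophan)
are never unequivocal, whichever side the lowest-index tie-break would pick.
No minimum probability margin is imposed; margins are exported in the
snapshot CSVs so users can apply their own.

The table is checked every `check_every` iterations (default 50, i.e. every
3,200 pairs) and once at iteration 0; `data_efficiency()` reports the
cumulated pairs at the earliest unequivocal check.  Two consequences are
worth keeping in mind:

* the metric is resolved at the cadence granularity, and because completeness
  can flicker at a learning rate of 0.05 — a rare class's logit can dip
  briefly after being overtaken — refining the cadence can only find an
  earlier or equal deciphering point (a property the tests verify);
* comparative experiments must use a cadence finer than the effect they
  measure.  On the clean synthetic corpus the shallow width-64 linear MLP
  deciphers within a few thousand pairs, *below* the default 3,200-pair
  cadence, so the weighted-versus-unweighted comparison is run at batch-level
  cadence (`check_every = 1`, 64-pair resolution); at the default cadence
  both arms would be censored at the very first checkpoint and the
  comparison would be meaningless.

## What the benchmark shows at this scale

On the reference corpus (5,000 ORFs ≈ 2.2 million pairs, seeds fixed in the
test suite), the deep two-hidden-layer linear MLP reaches 100% test-set
translation accuracy and a complete unequivocal table within a few tens of
thousands of pairs — orders of magnitude inside the published bounds for this
task on real transcriptome-scale data, as expected for a clean i.i.d. corpus
with an exact enumerated verdict.  Inverse-frequency weighting consistently
accelerates stop-codon resolution for the small-capacity shallow decoder
(every matched seed pair we ran), though the 3-seed median-ratio summary
statistic is noisy: across corpus seeds it ranges from roughly 10% to 75%
reduction around a typical 40-50%.

One published ordering does **not** reproduce under these conditions: with
i.i.d. pair subsampling, one-hot inputs and Adam's per-parameter step
normalization, the *shallow* linear decoder is the most data-efficient
variant — each codon's input row is updated essentially independently — while
depth adds shared-layer interference and typically costs a factor of two to
ten in pairs-to-deciphering.  The deep-beats-shallow phenomenon reported on
real transcriptome-scale experiments evidently depends on conditions this
synthetic benchmark deliberately simplifies away (sequence-contiguous
batches, corpus-scale epochs, batch-harvested verdicts).  The corresponding
acceptance test is left failing rather than adjusted, as an honest record of
the discrepancy.

## Embedding geometry

`synonymy_clustering_score()` summarizes whether synonymous codons cluster in
embedding space: the mean silhouette width of the 64 embedding rows grouped
by amino-acid class under Euclidean distance, excluding singleton classes
(methionine and tryptophan have one codon each).  Perfectly collapsed synonym
groups score 1; a fully degenerate embedding (all rows identical) is defined
as 0.  Note that the *null* is not 0: forcing arbitrary group labels onto
unstructured i.i.d. normal points yields slightly negative mean silhouettes
(Monte-Carlo: ≈ −0.23 at d = 10, ≈ −0.48 at d = 2), because a point's own
forced group is on average no tighter than its nearest other group.  Positive
scores therefore indicate genuine learned synonym structure.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 5,000-ORF corpora
(≈2.2 million pairs), 90/10 splits, batch 64 and the default epoch
convention; at these sizes the full suite runs in well under a minute of
compute on one CPU, with the MLP training loop implemented in C++
(RcppArmadillo) and verified against a pure-R reference implementation to
machine precision, and the recurrent backward passes verified against
numerical gradients.  Every stochastic step — corpus synthesis, ORF split,
weight initialization, epoch subsampling — is governed by an explicit seed,
and identical seeds reproduce traces bit-for-bit.

## Known limitations

* Absolute pair counts from synthetic corpora are lower bounds in spirit:
  real transcriptomes add noise, composition structure and annotation
  artifacts that slow rare-class resolution.
* The recurrent families run in plain R and are sized for correctness tests,
  not for large-scale benchmarking.
* Non-standard genetic codes (mitochondrial, selenocysteine recoding) are out
  of scope; the reference is always the standard code.
* The dynamic-heatmap videos of the original experiment are replaced by
  per-checkpoint CSV + PNG snapshots (`export_snapshots()`).
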