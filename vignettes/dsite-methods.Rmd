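---
title: "Predicting dihydrouridine sites: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dihydrouridine sites: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsite)
```

## The problem and the data model

Dihydrouridine (D) is a reduced uridine, among the most abundant
post-transcriptional modifications of tRNA, enriched at conserved D-loop
positions in eukaryotes, bacteria and some archaea. Because experimental
mapping is laborious, candidate sites are ranked by sequence-based
classifiers. The data unit here is a fixed-length, U-centred RNA window: by
default 41 nt with the candidate uridine at position 21 (1-based), labelled
1 for a validated D site and 0 for a non-modified U. The reference
composition this package emulates pools 550 such windows from five species
(29/68, 13/48, 9/38, 91/93 and 34/127 positive/negative windows for
*H. sapiens*, *M. musculus*, *D. melanogaster*, *S. cerevisiae* and
*E. coli* respectively — 176 positives against 374 negatives overall).
Redundancy removal is assumed to have been applied upstream by the data
source; `dsite` does not re-cluster sequences.

Two container classes carry the analysis: `DSiteDataset` (a
`Biostrings::RNAStringSet` with species and class labels, a single window
length, and unique record ids) and `FeatureMatrix` (an encoded
samples-by-features matrix carrying its generating encoder specification).
Sequences are normalized on input — uppercased, `T` mapped to `U` — since
benchmark files in this field are frequently distributed in the DNA
alphabet. A centre base other than U is reported by `validateDataset()` at
warning level rather than rejected: negative windows are biologically
candidate U sites, but not every input source guarantees the centring, and
a hard failure would refuse legitimate files.

## Feature encodings

Eleven schemes convert a window of length $N$ into a numeric vector. All
are *sample-local*: no training-set statistic enters any encoding, so
encoding commutes with data splitting (the pipeline still encodes after
splitting to keep the no-leakage argument structural rather than
analytical).

* **NCP** (3N): each nucleotide contributes (ring, functional group,
  hydrogen bond) bits — purines {G, A}, amino bases {C, A} and weak-bond
  bases {U, A} score 1 — giving A = (1,1,1), C = (0,1,0), G = (1,0,0),
  U = (0,0,1). These four codes follow directly from the chemistry
  groupings; published listings of this scheme occasionally transpose the
  C and G rows, which is inconsistent with the underlying property table
  and is not followed here.
* **BINARY** (4N): one-hot per position in the scheme's conventional base
  order A, G, C, U. One-hot distinctness forces C = (0,0,1,0); the worked
  string for `GAGACU`, `01001000…0001`, is consistent with that choice.
* **ENAC** (4(N−w+1)): window-local base frequencies, window w = 5
  (the scheme's conventional default) sliding 5′→3′ with step 1.
* **Kmer / NAC / DNC / TNC** (4^k): overlapping k-mer frequencies in
  lexicographic order over A < C < G < U. The default denominator is the
  number of k-mer positions $L-k+1$ (entries sum to 1, matching the
  behaviour of the standard encoder toolkits this field uses); a literal
  $N(m)/L$ mode is retained as `denom = "seq_length"` for fidelity to the
  textbook formula. Default k = 3 for the generic Kmer/RCKmer encoders.
* **RCKmer** (10 for k = 2, 32 for k = 3): k-mer counts pooled by the
  lexicographic minimum of each k-mer and its RNA reverse complement
  (A↔U, C↔G), making the encoding strand-symmetric.
* **ANF** (N): entry $i$ is the count of $s_i$ within $s_{1..i}$ divided by
  $i$ — a positional density profile.
* **EIIP / PseEIIP** (N / 64): electron-ion interaction potentials
  A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335 (U inherits the T value;
  the constants live in one editable table, `eiipTable()`); PseEIIP weights
  each trinucleotide frequency by its summed EIIP constants.

Feature names encode position/window/k-mer identity, so serialized
matrices are self-describing. Every encoder validates the A/C/G/U alphabet
and reports the offending position; batch encoding reports the offending
record id.

## Rebalancing by probabilistic oversampling

The benchmark's positive class is under-represented (176/550). After the
train/test partition, each positive **training** record is duplicated with
independent probability p = 0.5 in each of two passes, so the added
duplicate count is Binomial(2·n⁺, 0.5) with mean n⁺ — the positive class
roughly doubles in expectation while the class-conditional sequence
distribution is unchanged. Duplicates carry provenance ids
(`origid#dup<pass>`), which makes two guarantees mechanical: removing
duplicates recovers the input exactly, and the leakage guard can trace any
test id back through its ancestor. Oversampling is only ever applied to a
training side — `independentTest()` refuses any test set whose ids (or
ancestors) intersect the training ids, and cross-validation duplicates
rows inside each training fold only.

## Classifiers

Five families sit behind one interface, with the established R
implementations as backends: `randomForest` (RF), `e1071::svm` (SVM),
`class::knn` (KNN), `glmnet` (LR) and `nnet` (MLP). Protocol-stated
choices are fixed: the SVM uses the RBF kernel; the MLP uses logistic
(sigmoid) activation; hard labels come from thresholding the
positive-class score at 0.5. Hyperparameters the protocol leaves unstated
are set to documented defaults and are all overridable:

| family | defaults |
|---|---|
| RF | 100 trees, `floor(sqrt(d))` candidate features per split |
| SVM | cost 1, gamma 1/d, Platt-style probability scores |
| KNN | K selected from {1, 3, 5, 7, 9} by 5-fold CV inside the training data (ties → smallest K) |
| LR | ridge penalty at fixed strength λ = 1/n |
| MLP | one hidden layer of 100 units, weight decay 1e-4, 200 iterations |

Two defaults deserve their rationale. The logistic regression is fitted as
ridge-penalized `glmnet` at a fixed small λ = 1/n rather than by
unpenalized maximum likelihood: the benchmark's strongest encodings make
training folds nearly separable, where the unpenalized fit diverges; the
fixed ridge matches the "default-strength L2" convention of mainstream ML
toolkits and keeps fits deterministic. The SVM is run without internal
rescaling because every encoding already lives in [0, 1] on a common
scale, and rescaling would crash on constant columns (e.g. the centre-U
positions). Class weights are uniform throughout — imbalance is the
oversampling module's job, not the loss function's.

Every fit is seeded, and `predictScores()` returns positive-class scores
in [0, 1] from all five families (for RF: the fraction of trees voting
positive), so ROC analysis is uniform.

## Evaluation

Metrics are computed from the four confusion counts in their count-based
form — Sn = 1 − N⁻⁺/N⁺, Sp = 1 − N⁺⁻/N⁻, Acc = 1 − (N⁻⁺+N⁺⁻)/(N⁺+N⁻) —
together with MCC in the standard correlation form, precision and F1. The
test suite proves the count-based family equal (to 1e-12) to the
conventional TP/TN/FP/FN formulation on 1,000 random confusion matrices;
this dual-route check is the guard against misreading the count-based
notation, whose printed forms are easily garbled. Conventions for
degenerate cases: a zero denominator in MCC or precision yields 0 with a
warning; Sn/Sp are refused (error) when a class is absent, since no
convention is defensible there.

ROC curves sweep the score thresholds from (0,0) to (1,1) and AUC is the
trapezoid integral; an independent Mann-Whitney pair-counting
implementation (ties at one half) is exported separately, and their
equality is asserted on random tied score vectors, with `pROC` as an
external reference.

Cross-validation is stratified 5-fold, repeated 5 times, with repeat $r$
shuffling under seed `seed + r − 1` (recorded for replay). Rows are first
put into canonical id order, which makes the entire CV a deterministic
function of (ids, labels, seed) — bit-identical under any permutation of
the input. Stratification is the default because unstratified folds can
lose a class entirely in the small species (9 positives in
*D. melanogaster*), which is an error rather than a silent degeneracy.

## Experiment designs

* `gridBenchmark()` — encoder × classifier grids over one shared partition
  (comparability across cells), optional oversampling, confusion counts
  reported per cell. Whether oversampling is active is an explicit,
  logged parameter: whether rebalancing belongs in a given comparison is a
  study-design choice, so the grid never assumes it silently.
* `partitionRateStudy()` — the 30/20/10% test-rate ladder under a common
  seed policy. No monotonicity in the rate is asserted anywhere: the
  benefit of smaller test rates is an empirical training-size effect, not
  a law.
* `experimentOne()` — train on one species (default *S. cerevisiae*, the
  largest contributor), CV within it, independent test on the pooled rest.
* `experimentTwo()` — leave-one-species-out, one metric set per species.
* `experimentThree()` — the full species × species accuracy matrix, rows
  training and columns testing, with within-species stratified CV on the
  diagonal. Species whose smallest class falls below k fall back to
  `k = min(k, class size)` with a warning.

Every driver embeds its full configuration (specs and seeds) in its
result, re-running from which reproduces all numbers to 1e-12, and every
train/test boundary passes through the mechanical disjointness check.

## The synthetic generator

`generateDataset()` emulates the benchmark's shape: exact per-species
positive/negative counts (the five-species table above), 41-nt windows, U
forced at the centre of *both* classes. Negatives are i.i.d. draws from
the background composition (uniform by default; configurable to skewed
backgrounds for k-mer stress tests). Positives share the background except
on the ten positions flanking the centre (offsets ±1..±5), where a fixed
preferred-base profile is tilted with log-odds `effectSize`: the
probability of base $b$ is proportional to
$\mathrm{bg}_b\,e^{\text{effect}\cdot[b=\text{pref}]}$. A *positional*
motif was chosen deliberately: it is visible both to position-aware
encoders (NCP, BINARY, ENAC) and, through induced composition shifts, to
the k-mer family, so a single construction exercises every scheme.

Parameter choices, made once: `effectSize = 0` is the null (classes
identically distributed by construction); the documented reference
"strong" value is `effectSize = 2`, i.e. a preferred-base probability of
$e^2/(e^2+3) \approx 0.71$ on uniform background — a strong but not
deterministic motif, qualitatively like a conserved structural context. An
optional `divergentSpecies` plants its positives on the complemented
profile, giving cross-species experiments a species that genuinely
generalizes badly.

What the generator does *not* emulate: tRNA secondary structure and real
D-loop motifs, phylogenetic correlation between species, composition bias
of real transcriptomes, and near-duplicate sequences below a similarity
threshold. Passing tests on synthetic data therefore validate the
*machinery* — encodings, rebalancing, model plumbing, evaluation and the
experiment harness — not biological performance on real windows, which
must be measured on the downloadable benchmark itself.

## Validation strategy and problem sizes

The test suite works at three levels. Worked toy values (the `GAGACU`
vectors, homopolymers, reverse-complement pairs, the 41-nt dimension
formulas 123/164/148/4/16/64/10/32/41/41/64) are frozen as golden
expectations. Properties run over generated cases under fixed seeds:
brute-force k-mer counting against the encoders, metric- and
AUC-formulation equivalences, oversampling's binomial law (at the
benchmark's 91 *S. cerevisiae* positives: 1,000 seeds, mean within three
standard errors of 91), split bijectivity and determinism. End-to-end
checks run the full pipeline on benchmark-shaped data: repeated 5-fold CV
of RF + NCP reaches AUC ≥ 0.95 at the reference effect size and sits
within 0.5 ± 0.1 at effect 0 (a 550-window dataset in both cases), and
the cross-species matrix reproduces its diagonal from independent CV runs.

One test construction differs from the benchmark composition by design:
the planted-divergence property ("the divergent species has the lowest
row and column means") is asserted on a class-balanced five-species
dataset (40/40 per species). Under the benchmark's own imbalance a
majority-class predictor scores ≈ 0.79 accuracy on the divergent species'
column, which masks divergence in an accuracy matrix; balance makes the
property identifiable. The matrix's shape, diagonal and leakage guards
are still checked on the exact benchmark composition.

Problem sizes throughout (550-sample datasets, 5 × 5-fold CV, 100-tree
forests, 1,000-seed oversampling batches) were chosen as the smallest
sizes at which the statistical assertions have comfortable margins.

## Known limitations

* Real-benchmark metrics depend on the original study's unpublished split
  draws and hyperparameters; identical numbers should not be expected even
  on the original data, only comparable ones.
* KNN scores are vote fractions over at most 9 neighbours, so its ROC
  curves are coarse.
* The MLP backend (`nnet`) uses full-batch BFGS rather than stochastic
  optimizers; with the default 100 hidden units on 123-dimensional inputs
  it is the slowest family by a wide margin.
* The oversampling rule duplicates records rather than synthesising new
  ones; it reshapes class frequency, not feature-space coverage.
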