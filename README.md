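# dsite

Prediction of dihydrouridine (D) modification sites in RNA from sequence
alone.

Dihydrouridine is a reduced uridine and one of the most abundant
post-transcriptional tRNA modifications, concentrated at conserved positions
of the tRNA D-loop across eukaryotes, bacteria and archaea. Experimental
mapping of D sites is slow and laborious, so sequence-based classifiers are
used to prioritise candidate sites. `dsite` is aimed at computational
epitranscriptomics: it implements the full benchmark pipeline around the
five-species D-site data — 550 U-centred 41-nt windows (176 positive / 374
negative) pooled from *H. sapiens*, *M. musculus*, *D. melanogaster*,
*S. cerevisiae* and *E. coli* — as a tested R library plus a small command
line tool.

## What it computes

A window `s = s_1 … s_41` with the candidate U at position 21 is encoded by
one of eleven schemes into a feature vector `R = (r_1, …, r_d)`:

* **NCP** — 3 chemistry bits per position (ring structure, functional group,
  hydrogen bond): A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1);
  d = 3N = 123.
* **BINARY** — one-hot per position in base order A, G, C, U; d = 4N = 164.
* **ENAC** — sliding-window (w = 5, step 1) nucleotide frequencies;
  d = 4(N−w+1) = 148.
* **Kmer / NAC / DNC / TNC** — k-mer frequencies
  `f(m) = N(m) / (L−k+1)` in lexicographic order (a literal `N(m)/L`
  denominator mode is also provided); d = 4^k.
* **RCKmer** — k-mer counts pooled with their RNA reverse complements
  (A↔U, C↔G); d = 10 (k = 2) or 32 (k = 3).
* **ANF** — accumulated nucleotide frequency, the density of `s_i` within
  the prefix `s_1..s_i`; d = N.
* **EIIP / PseEIIP** — electron-ion interaction potentials per position, and
  trinucleotide frequencies weighted by summed EIIP constants; d = N / 64.

Class imbalance is handled by the benchmark's oversampling rule: after the
train/test partition, each **positive training** window is duplicated with
independent probability 0.5 in each of two passes (so the expected positive
count doubles; the test side is never touched). Five classifier families
(random forest, RBF-kernel SVM, KNN, ridge logistic regression, sigmoid
MLP) sit behind one fit/score interface, and evaluation uses the count-based
metric family

    Sn = 1 − N⁻⁺/N⁺,  Sp = 1 − N⁺⁻/N⁻,  Acc = 1 − (N⁻⁺+N⁺⁻)/(N⁺+N⁻),  MCC,

plus ROC/AUC, under repeated stratified 5-fold cross-validation and
leakage-guarded independent tests. Three cross-species designs probe
generalization: train on one species, leave one species out, and the full
species-by-species accuracy matrix with within-species CV on its diagonal.

A synthetic generator emulates the benchmark's exact composition with a
tunable positional motif, so the whole pipeline is testable offline; see
`vignette` sources under `vignettes/` for the model and its assumptions.

## Worked example

```r
library(dsite)

d <- generateDataset(syntheticConfig(seed = 7))   # benchmark-shaped data
d
#> DSiteDataset: 550 records, 41 nt window (centre position 21)
#>   176 positive / 374 negative across 5 species
datasetSummary(d)
#>          species positive negative total
#> 1      H.sapiens       29       68    97
#> 2     M.musculus       13       48    61
#> 3 D.melanogaster        9       38    47
#> 4   S.cerevisiae       91       93   184
#> 5         E.coli       34      127   161

part  <- partitionDataset(d, splitSpec(0.10, seed = 7))     # 10% test split
train <- oversamplePositives(d[part$train_ids], oversampleSpec(seed = 7))
train
#> DSiteDataset: 642 records, 41 nt window (centre position 21)
#>   301 positive / 341 negative across 5 species

fitted <- fitModel(modelSpec("RF", seed = 7),
                   encodeDataset(train, "NCP"), siteLabels(train))
independentTest(fitted, encodeDataset(d[part$test_ids], "NCP"),
                siteLabels(d[part$test_ids]))
#> Sn=0.9091  Sp=1.0000  Acc=0.9636  MCC=0.9258  precision=1.0000  F1=0.9524  AUC=0.9883

crossValidate(encodeDataset(d, "NCP"), siteLabels(d),
              modelSpec("RF", seed = 7), k = 5, repeats = 5, seed = 7,
              oversample = oversampleSpec(seed = 7))
#> 5 x 5-fold cross-validation [RF]
#>          Sn     Sp    Acc    MCC precision     F1    AUC
#> mean 0.8078 0.9722 0.9196 0.8133    0.9330 0.8651 0.9742
#> sd   0.0466 0.0163 0.0190 0.0456    0.0372 0.0337 0.0119
```

The oversampling step has expanded the 495 training windows to 642 by
adding 147 positive duplicates across the two passes (154 original
training positives became 301); the held-out 55 windows were never
oversampled. The independent test says
the forest recovers 90.9% of true D windows (Sn) at perfect specificity on
this split; the cross-validated AUC of 0.974 summarises ranking quality
over all 25 folds. On real benchmark FASTA files
(`>id|species|label` headers, label 1/0), `readFastaDataset()` replaces the
generator and everything downstream is identical.

The same pipeline is scriptable from a shell via the installed `dsite`
executable (`dsite simulate`, `encode`, `train`, `predict`, `eval`,
`benchmark`, `crossspecies`; see `dsite --help`).

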