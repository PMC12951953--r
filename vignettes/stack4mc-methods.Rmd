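---
title: "Methods: dynamic feature selection and stacked deep ensembles for 4mC prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic feature selection and stacked deep ensembles for 4mC prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

DNA N4-methylcytosine (4mC) is a cytosine modification common in
prokaryotes, where it participates in restriction–modification defence,
and comparatively rare in eukaryotes. Experimental profiling (SMRT, ONT)
is expensive, so sequence-based classifiers that predict whether the
cytosine at the centre of a 41-bp window is methylated are widely used.
`stack4mc` implements such a classifier as a three-stage system:

1. **Feature encoding.** Fourteen nucleotide encoding schemes turn a
   41-bp window into a numeric vector: positional schemes (Binary
   one-hot, NCP chemical properties, EIIP pseudopotentials, ANF
   accumulated frequencies, ENAC sliding-sub-window composition),
   composition schemes (NAC, Kmer, TNC, reverse-complement-collapsed
   RCKmer, gapped-pair CKSNAP, EIIP-weighted PseEIIP), and
   physicochemical-correlation schemes (TAC auto-covariance, parallel-
   and series-correlation pseudo trinucleotide composition).
2. **Dynamic feature selection (DFS).** For a given species and model
   architecture, every encoding is scored by its own fivefold
   cross-validated accuracy
   $\mathrm{Acc}(s,k,f_i) = \frac{1}{N}\sum_m I(y_m = \hat y_m)$,
   encodings are ranked by that score, and the nested prefix unions
   $F_n = \bigcup_{i \le n} f_{(i)}$ are evaluated in turn; the smallest
   $n^\* = \arg\max_n \mathrm{Acc}(F_n)$ wins. The search space is
   exactly 14 nested subsets, never $2^{14}$.
3. **Stacked probabilistic ensemble.** Three small deep models — a CNN
   (256 width-1 kernels, a separable convolution with 128 width-3
   filters, global max pooling, L2 $\lambda = 10^{-3}$, dropout 0.3), a
   two-layer bidirectional LSTM (128 then 64 units per direction,
   recurrent dropout 0.1, batch normalisation) and a Transformer encoder
   (2 heads, 64-unit feed-forward sublayers, layer-norm
   $\varepsilon = 10^{-6}$) — emit per-window probabilities. Two
   gradient-boosted tree learners (500 rounds at depth 7; 300 leaf-wise
   rounds with L1 term 0.2) re-process the 3-probability vector, and an
   elastic-net logistic metalearner (L1 ratio 0.5, C = 0.6) fuses the
   resulting 5-value meta feature into the final probability.

All models are optimised with Adam (initial learning rate $10^{-3}$,
exponential decay 0.9, gradient-norm clipping at 1.0) and a sigmoid
output, under stratified fivefold cross-validation.

## Windows and preprocessing

Input sequences of any length are normalised to 41-bp windows
(`extract_windows()`): exact-length sequences pass through, shorter ones
are symmetrically padded with `N` (the extra `N` goes right when the
deficit is odd, so a length-38 input becomes `N...NN`), and longer ones
are cut into overlapping sliding windows with a configurable stride
(default 1). The centre of a 41-mer is 1-based position 21, i.e.
$(41+1)/2$; `require_center_c` restricts output to windows with a C
there. Duplicate removal is a plain exact-string filter
(`deduplicate_windows()`); similarity-threshold clustering is out of
scope.

`N` handling is uniform across encoders: an `N` contributes an all-zero
one-hot/NCP column and EIIP value 0, is excluded from k-mer and pair
counts (denominators count only fully determined k-mers), and is skipped
in ANF prefix counts. Degenerate windows (homopolymers, all-`N`) yield
zero correlation factors rather than errors, so batch encoding never
aborts.

## Encoding parameters

Defaults: ENAC sub-window $w = 5$; Kmer $k = 2$ (TNC fixes $k = 3$);
RCKmer $k = 3$ (32 canonical classes); CKSNAP gaps $0..5$ (96 values);
PCPseTNC/SCPseTNC $\lambda = 2$, weight $w = 0.1$; TAC lag 2. The
correlation encoders need a numeric property per trinucleotide; the
package default is a 64 × 2 matrix of two transparently defined scales —
summed EIIP of the three bases and G+C count — z-standardised over the
64 trimers (`default_trinucleotide_properties()`). These are
package-defined defaults, not a published reference set; any 64 × P
matrix can be supplied through the scheme parameters and flows through
`encoder_spec()` into every correlation encoder.

Fused matrices (`encode_windows()`) concatenate the selected blocks in
the order given — the DFS ranking order in the full pipeline — so the
spatial layout seen by the convolutional model is deterministic, and the
attached block map records every scheme's column span.

## The deep models and how the feature vector enters them

The published architecture description leaves open how a heterogeneous
fused feature vector is arranged spatially. Treating it as a length-$d$
sequence with one channel makes recurrent backpropagation scale with
$d \approx 900$ timesteps, which is computationally prohibitive for a
128-unit bidirectional LSTM on one CPU. The package therefore reshapes
the vector into a short sequence of fixed-width *frames*: `frames`
timesteps (default 16 for the CNN and Transformer, 8 for the BiLSTM),
each holding $\lceil d/\mathrm{frames} \rceil$ feature channels,
zero-padded at the tail. Width-1 convolutions remain per-frame feature
transforms, the separable convolution and the attention span neighbouring
frames, and recurrent cost becomes independent of $d$. The frame count
is an `architecture_config()` parameter.

Other choices the published description leaves open, fixed here as
defaults and all configurable: sinusoidal positional encodings and model
width 32 with 2 encoder layers for the Transformer; batch normalisation
after the second recurrent layer in the BiLSTM; epochs 30 and batch size
256 with early stopping (patience 5) as the nominal training protocol;
classification threshold 0.5. The learning-rate *decay cadence* is not
stated with the rate; per-epoch decay from $10^{-3}$ drops the rate
below $10^{-4}$ within ~22 epochs, before these models converge, so the
default applies the 0.9 factor every second epoch
(`lr_decay_every = 2`).

The implementation is a self-contained, BLAS-backed training core with
hand-derived backpropagation for every layer (separable convolution,
LSTM gates, multi-head attention, layer and batch normalisation). Its
gradients are verified against central finite differences in the test
suite, and training is deterministic given the protocol seed on
single-threaded BLAS.

## Cross-validation, early stopping and leakage control

Fold assignment is stratified by label and fixed by the protocol seed;
the same folds are reused for single-encoding scoring, prefix
evaluation, and every stacking tier. Early stopping monitors an inner
15 % stratified split of the *training* part of each fold — never the
held-out fold — so out-of-fold probabilities remain clean. Per-feature
min–max scaling is fitted on training rows only and replayed on
validation and test rows.

Stacking uses out-of-fold discipline at every tier: tier-II learners are
trained on out-of-fold tier-I probabilities, their own training
predictions for the meta feature are again out-of-fold (nested reuse of
the same folds), and base models are refit on all training data only for
inference. A naive refit-on-all mode is available behind
`fit_stacked(oof = FALSE)` for comparison; it is flagged in the fitted
object because stacking without this discipline overfits. The
label-shuffle control in the acceptance suite checks the whole pipeline
sits at chance AUC when the labels carry no signal.

The joint objective over species–model pairs is additive, so optimising
each pair independently already maximises it; `joint_objective()` simply
reports the sum of per-pair optima.

## The surrogate classifier

DFS logic is independent of which classifier produces the accuracy
cells. `surrogate_classifier()` — a deterministic ridge-penalised
logistic regression honouring the same fit/predict contract — makes the
selection mechanics testable in seconds and exact against an exhaustive
prefix oracle. Deep-mode DFS (scoring all 14 encodings with the actual
architectures) is the intended configuration for real studies; the
benchmark-scale runs in this package's tests and acceptance script use
surrogate scoring to pick encoder sets and reserve the deep training
budget for the stacked evaluation itself.

## The synthetic study and what it does (and does not) show

`synthetic_spec()` defines the study conditions: balanced 41-bp windows
with a C pinned at position 21 in *both* classes (so the anchor base
carries no label information), positives carrying the degenerate
consensus `GGCCA` planted at a uniformly drawn offset from the range
16–22 — restricted to starts that either miss the centre or put a
consensus C on it — with per-base mutation probability 0.1, uniform
background, 1000 + 1000 windows, seed 7. `synth_species_family()`
derives multiple "species": half share Hamming-near variants of one
motif, half carry an unrelated motif, which is what makes within-group
versus cross-group zero-shot transfer measurable.

These conditions produce a deliberately hard, information-limited task.
An exact likelihood-ratio computation over the planting model bounds the
Bayes AUC near 0.96: a mutated 5-mer at four possible offsets against a
uniform background simply does not separate further. At benchmark scale
(fivefold evaluation over the 2000 windows, epochs 12, batch 64) the
deep base models reach out-of-fold AUCs of roughly 0.85–0.90, the
stacked ensemble about 0.90, the stacking gain over the best base model
is positive, the transfer gap between shared- and unrelated-motif
species exceeds 0.1 AUC, and the label-shuffle control sits at chance.
Passing these checks shows the pipeline's plumbing, anti-leakage
discipline and relative ordering are right; it says nothing about
absolute performance on real genomes, where signal strength, class
balance, sequence redundancy and species idiosyncrasies differ
substantially from a uniform-background planted-motif model.

## Evaluation metrics

`compute_metrics()` implements accuracy, sensitivity, specificity, the
Matthews correlation coefficient, F1 and AUC from a 0.5-threshold
confusion table. F1 uses the standard form $2TP/(2TP+FP+FN)$. AUC is the
Mann–Whitney rank statistic with midrank tie handling, identical to the
trapezoidal area under the ROC curve. Zero-denominator metrics are
reported as 0 with a `degenerate` flag and a warning so reports stay
machine-readable. The k-mer enrichment harness compares pooled k-mer
counts between two groups with a two-sided two-proportion z-test and
Benjamini–Hochberg correction within each k family; the per-group mean
per-sequence frequencies and their difference drive the ranking.

## Problem sizes used by the tests and acceptance script

Unit tests run on miniature layer sizes (the gradient checks use 4–8
unit layers) and datasets of 40–500 windows. The benchmark-scale runs
use the full default synthetic study (2000 windows) with the reduced
protocol — epochs 12, batch 64, patience 3 — and the transfer study uses
four species of 600 windows each at epochs 8. These sizes are the
package's chosen desk-scale study conditions; larger runs only require
raising the protocol parameters.

## Known limitations

* The deep models are faithful small implementations, but training at
  the published scale (tens of thousands of windows, 30+ epochs) is slow
  in pure R; the architecture is the contribution here, not throughput.
* The tier-II leaf-wise learner reproduces the stated hyperparameters
  (300 rounds, 31 leaves, L1 0.2) via loss-guided growth in xgboost; it
  is not the LightGBM codebase.
* Sequence redundancy filtering is exact-match only.
* The synthetic generator plants a single motif per positive window on a
  uniform background; real 4mC contexts are more heterogeneous, and
  conclusions from the synthetic study transfer only qualitatively.
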