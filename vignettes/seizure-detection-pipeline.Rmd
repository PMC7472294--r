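---
title: "Seizure detection from single-channel EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection from single-channel EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiged)
```

## The problem and the pipeline

Epileptic seizures show up in scalp EEG as runs of high-amplitude activity
with frequent transient spikes, against a lower-amplitude, broadly 1/f-like
background between seizures. `epiged` implements a frame-based binary
classifier for this contrast on single-channel recordings. The stages are:

1. **Framing** — a segment is cut into fixed-length frames (default 10 s at
   50% overlap). A 23.6 s segment at 173.61 Hz — the Bonn archive format —
   yields three hop-aligned frames plus one frame anchored to the segment
   end, i.e. 4 frames per segment and 400 per 100-segment set.
2. **Subband decomposition** — each frame is split by an L-level discrete
   wavelet transform (db4, L = 4 by default) into L detail bands and one
   approximation band, each *reconstructed back to the time domain* so that
   the L + 1 subband signals sum to the frame. The fullband frame is kept
   as an additional signal.
3. **Features** — seven statistics per signal: three spike descriptors
   (SODP ellipse area `Ae`, squared coefficient of variation of the
   absolute series `Vsc`, fluctuation index `Fi`) and four entropies
   (permutation `pE`, approximate `apE`, order-2 Rényi spectral `enE`,
   bispectral phase `phE`). With L = 4 this gives a
   (L + 2) × 7 = 42-dimensional feature vector per frame.
4. **Selection** — features are ranked by a graph eigen decomposition
   (GED): vertices are features, the adjacency mixes a rank-1
   relevance kernel (normalized Fisher scores × normalized mutual
   information) with a pairwise dispersion matrix, and the absolute
   principal eigenvector supplies the weights. The top k = 16 features are
   kept by default.
5. **Classification** — a single-hidden-layer feedforward network (tanh
   hidden units, default 10; two-unit softmax output) evaluated by
   stratified 5-fold cross-validation with accuracy, sensitivity and
   specificity reported per fold and as means.

```{r pipeline, eval = FALSE}
frames <- gen_dataset(n_per_class = 400, seed = 1)
feats  <- extract_features(frames)               # 800 x 42 (+ metadata)
fit    <- ged_select(feats, k = 16)              # ranking, for inspection
res    <- kfold_evaluate(feats, k_features = 16, folds = 5, seed = 1)
glance(res)
```

## Framing conventions

Sample indexing is 0-based and frames are half-open ranges
`[start, start + n_frame)` with `n_frame = round(frame_len_s * fs)` (1736
samples for 10 s at 173.61 Hz). The hop is
`round(n_frame * (1 - overlap))`. Hop-aligned framing alone yields only 3
full 10 s frames from a 23.6 s segment; to match the 4-frames-per-segment
accounting of the Bonn framing we append one frame anchored to end at the
final sample whenever the hop grid falls short (`end_anchor = TRUE`,
exposed in the config). The anchored frame overlaps its predecessor more
than 50%; it is never duplicated when the grid already reaches the end.
No rescaling, detrending or filtering is applied at read time — the Bonn
recordings are already band-passed at acquisition.

## The wavelet transform and its boundary handling

The multilevel DWT is implemented in the package (analysis/synthesis with
Daubechies filters db1–db10; the highpass filter is the quadrature mirror
of the stored scaling filter). We use **periodized (circular) boundary
handling**: at each level the analysis operator consists of shift-by-2
circulant rows, so it is exactly orthogonal, synthesis is its transpose,
and two identities hold that the tests rely on:

* *additivity* — the L + 1 band-limited reconstructions sum to the input
  frame to machine precision, for every frame length;
* *Parseval* — subband energies sum to the frame energy to machine
  precision whenever every level has even input length, i.e. the frame
  length is divisible by 2^L.

Symmetric half-sample extension — the common alternative — loses exact
orthogonality at the boundaries (energy discrepancies around 10^-4 to
10^-2 relative for 10 s frames), which is why periodization was chosen.
When a level has odd input length (the Bonn frame length 1736 = 8 × 217
hits this at level 4) the signal is padded by repeating its last sample;
reconstruction stays exact, and the energy identity degrades gracefully to
roughly 10^-4 relative. Circular wraparound can smear energy of strongly
non-periodic frames across the band edges by a few samples' worth; with
1736-sample frames this is negligible relative to the db4 rolloff overlap
itself. Reported cutoff frequencies are the ideal dyadic edges
(43.4–86.8, 21.7–43.4, 10.85–21.7, 5.43–10.85 and 0–5.43 Hz at 173.61 Hz,
L = 4); the actual filter rolloff overlaps them and no compensation is
attempted.

## Feature definitions and numerical choices

All entropies are reported in **nats**. Degenerate inputs map to defined
defaults — a constant signal gives `Ae = Vsc = Fi = apE = 0`; an all-zero
signal additionally gives `enE = phE = 0` — so feature vectors are always
finite.

* **SODP pairing.** The second-order difference plot pairs successive
  first differences `y1(n) = x(n+1) - x(n)` with `y2(n) = y1(n+1)`; only
  N − 2 points pair up. The moment normalizer is kept at 1/(N − 1) with
  sums over the N − 2 pairs, matching the conventional presentation of the
  95% confidence ellipse area. The minor-radius radicand is clamped at 0:
  finite samples can push it a hair negative.
* **Permutation entropy** (embedding 3, lag 1 by default): ties within a
  window are ranked by temporal order (stable sort). The bound
  `pE <= log(embed!)` holds for every input.
* **Approximate entropy** (embedding 2, tolerance 0.2 × sd): Chebyshev
  distance, self-matches included — the standard Pincus convention, which
  keeps every correlation integral positive. The O(n²) template matching
  is the pipeline hot spot and is implemented in C++.
* **Rényi spectral entropy** (order 2): normalized power over the
  positive-frequency bins `1..floor(N/2)`, DC excluded so that amplitude
  offsets carry no spectral "information".
* **Phase entropy**: the bispectrum is estimated from the single frame
  (no segment averaging — the feature is per-frame by construction), over
  the bifrequency grid `f1, f2 = 1..F` with cells `f1 + f2 > F` carrying
  no mass. For a single-frame estimate the squared bispectrum magnitude
  reduces to a product of three power-spectrum values, which is how it is
  computed; the tests verify equality against a literal complex-valued
  transcription. The ~F²/2 admissible cells (≈376k for 10 s frames) are
  enumerated densely.

## GED selection choices

Several details of the selection stage are underdetermined by its usual
presentation; the package fixes them as follows and exposes each in the
configuration:

* **Normalization** of the Fisher and mutual-information score vectors is
  min–max over the M features; a constant score vector maps to all 0.5 so
  the rank-1 kernel never collapses to zero. The dispersion matrix
  `rho[i,j] = max(sigma_i, sigma_j)` is likewise min–max rescaled into
  [0, 1] before mixing.
* **Loading coefficient** `gamma` defaults to 0.5 — equal weight to the
  relevance kernel and the dispersion matrix absent any stated value.
* **Mutual information estimator**: equal-width histogram with 10 bins
  over the observed range of each feature. Fisher scores use population
  (1/n) class moments with a 1e-12 variance guard.
* **Symmetrization**: the kernel `Theta = D R^T` is asymmetric although
  the graph is treated as undirected, so the eigendecomposition operates
  on `(U + U^T)/2`, guaranteeing a real spectrum.
* **Degenerate spectra**: if several eigenvalues tie at the maximum
  magnitude, weights are the square roots of the diagonal of the projector
  onto the tied eigenspace — basis-invariant, reducing to `|v0|` in the
  simple case and to the uniform vector for `U = I`. Ranking ties break
  toward the lower feature index.
* k = 16 selected features is the default operating point.

Selection is supervised, so inside cross-validation it is refitted per
fold on the training rows only; applying a fitted ranking to held-out rows
touches no labels (the suite asserts this by label shuffling).

## Classifier

The network is deliberately small: input = selected features
(z-scored with training-fold statistics), one tanh hidden layer (10 units
by default), two softmax outputs one-hot encoding non-seizure/seizure. A
two-unit softmax is mathematically a logistic output; it is kept as two
units to match the softmax formulation. Training minimises mean
cross-entropy with a small L2 penalty (1e-4, which keeps weights finite on
linearly separable folds) by BFGS with analytic gradients and seeded
uniform initialisation, making every fit bit-reproducible given its seed.
Any other classifier can be dropped into the cross-validation driver
through `classifier_hook()` (the suite demonstrates a nearest-centroid
model); probability ties at exactly 0.5 predict class 0.

Folds are stratified by class — plain K-fold can starve a fold of one
class and destabilise sensitivity/specificity. Whether frames from the
same parent segment should be grouped into the same fold is a real
ambiguity for overlapping frames; the package evaluates frames
independently, and segment-grouped splitting can be emulated by
evaluating per-segment feature tables.

## The synthetic generator

`gen_frame()` emulates exactly the contrast the features target, nothing
more: the non-seizure class is band-limited 1/f noise (spectral exponent
1, amplitude scale 50 arbitrary units); the seizure class multiplies the
same background by a burst gain (1.6) and adds a Poisson train
(0.8 events/s) of biphasic Gaussian-derivative spikes, ~70 ms wide — wide
enough to land energy across the middle subbands — at 4× the background
scale with random polarity and ±30% amplitude jitter. Both classes share
a lognormal per-frame gain spread (sd 0.4 on the log scale) so that
amplitude alone does not separate them cleanly. The defaults were fixed
once so that the default pipeline clears 95% mean CV accuracy without
saturating at 100%, keeping sensitivity and specificity informative;
with the spike rate at 0 and the burst gain at 1 the two classes are
generated by an identical process and accuracy collapses to chance.

What passing on this generator does **not** show: robustness to real EEG
nonstationarity, artifacts, inter-subject variability, or recording
montage effects. The generator exists so that every stage is testable
without any recordings; conclusions about clinical data require clinical
data.

## Problem sizes used in the checks

The test suite and the acceptance script exercise the pipeline at the
study's structural operating point — 1736-sample frames, 42 features,
top-16 selection, 5 folds — with 400 frames per class for the end-to-end
benchmark (the size of one two-set comparison) and 100 per class for the
null control, sizes at which the stochastic contracts are stable across
seeds while the whole suite runs in minutes on one core. Feature-level
oracle comparisons use length-50 sequences, where the literal
O(n²)–O(n⁴) brute-force transcriptions are affordable.

## Known limitations

* Single channel only; no EDF/BDF readers, no montages, no artifact
  rejection.
* The printed dyadic cutoffs extend to fs/2 even when the recording was
  antialias-filtered well below it; band labels describe the filter bank,
  not the physical content.
* The bispectral phase entropy from one frame carries no true phase
  information (magnitudes only); it is retained in this per-frame form by
  construction of the feature set.
* Mutual information via fixed equal-width binning is biased for heavily
  skewed features; ranks, not absolute MI values, are what the selection
  consumes.
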