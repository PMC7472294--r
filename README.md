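# epiged

Seizure / non-seizure classification of single-channel EEG in R:
wavelet-subband spike and entropy features, graph-eigen-decomposition (GED)
feature selection, and a small feedforward network evaluated by stratified
K-fold cross-validation.

## What it does

Ictal (seizure) EEG differs from interictal EEG in amplitude fluctuation
and signal complexity. `epiged` turns each 10 s frame of a recording into a
42-dimensional feature vector and classifies it:

1. **Framing**: fixed-length frames (default 10 s, 50% overlap,
   end-anchored so a 23.6 s Bonn-format segment yields 4 frames).
2. **Subbands**: an L-level db4 DWT (L = 4) reconstructs L + 1 time-domain
   subband signals per frame — nominal bands 43.4–86.8, 21.7–43.4,
   10.85–21.7, 5.43–10.85 and 0–5.43 Hz at 173.61 Hz — plus the fullband
   frame.
3. **Features**, seven per signal, (L + 2) × 7 = 42 per frame:
   - `Ae` — area of the 95% confidence ellipse of the second-order
     difference plot, `Ae = pi * alpha * beta` with radii from the RMS and
     cross-moments of successive increments;
   - `Vsc = sigma^2 / mu^2` — variance over squared mean absolute
     amplitude;
   - `Fi` — mean absolute first difference;
   - `pE` — permutation entropy (embedding 3, lag 1);
   - `apE` — approximate entropy (embedding 2, tolerance 0.2 sd);
   - `enE` — order-2 Rényi entropy of the normalized power spectrum;
   - `phE` — Shannon entropy of the normalized squared bispectrum.
4. **GED selection**: with per-feature Fisher scores `D` and
   feature–label mutual informations `R` (both min–max normalized) and
   per-feature dispersions `sigma`, the feature graph's adjacency is
   `U = gamma * D R^T + (1 - gamma) * rho`, `rho_ij = max(sigma_i,
   sigma_j)` rescaled to [0, 1]. Features are ranked by the absolute
   principal eigenvector of `(U + U^T)/2`; the top k = 16 are kept.
5. **Classifier**: single hidden layer (10 tanh units), two-unit softmax,
   trained by BFGS; stratified 5-fold CV reports
   `ACC = 100 (TP + TN) / N`, `SEN = 100 TP / (TP + FN)`,
   `SPE = 100 TN / (TN + FP)` per fold and as means.

A built-in generator produces labeled synthetic frames (1/f background vs.
amplified background plus biphasic spike trains), so the entire pipeline
runs and is tested without any EEG recordings. Recordings in the
one-sample-per-line Bonn text dialect are read with `read_eeg_segment()`.

## Worked example

```r
library(epiged)

frames <- gen_dataset(n_per_class = 400, seed = 1)   # 800 labeled frames
feats  <- extract_features(frames)                   # 800 x 42 features
res    <- kfold_evaluate(feats, k_features = 16, folds = 5, seed = 1)
glance(res)
#> # A tibble: 1 x 7
#>   folds k_features classifier mean_acc mean_sen mean_spe  seed
#>   <dbl>      <dbl> <chr>         <dbl>    <dbl>    <dbl> <int>
#> 1     5         16 ffnn-10        98.6       98     99.2     1
```

98.6% of held-out frames are classified correctly; 98% of seizure frames
are caught (sensitivity) and 99.2% of non-seizure frames are passed
(specificity), averaged over the 5 folds (640 training / 160 validation
frames each). Inspect or plot the feature ranking with

```r
fit <- ged_select(feats, k = 16)
tidy(fit)       # per-feature Fisher score, MI, weight, rank
autoplot(fit)   # weight bar chart, selected features highlighted
```

A command-line interface wraps the same functions
(`exec/epiged simulate|extract|select|evaluate|sweep`), and
`sweep_levels()` / `sweep_grid()` reproduce the tuning experiments
(accuracy vs. decomposition level; selected-feature count × hidden-unit
grid). See `vignettes/seizure-detection-pipeline.Rmd` for the methods and
design notes.

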