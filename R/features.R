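# The seven per-signal features: three spike descriptors (SODP ellipse
# area, squared coefficient of variation of the absolute series,
# fluctuation index) and four entropies (permutation, approximate, order-2
# Renyi spectral, bispectral phase). All entropies are reported in nats.
# Degenerate inputs (constant or all-zero signals) map to 0, never NaN.

#' Paired successive increments for the second-order difference plot
#'
#' The second-order difference plot (SODP) scatters consecutive first
#' differences against each other: `y1(n) = x(n+1) - x(n)` against
#' `y2(n) = x(n+2) - x(n+1)`. Since `y2` is `y1` shifted by one sample, only
#' `N - 2` points pair up for a series of length `N`.
#'
#' @param x Numeric vector, length >= 3.
#' @return A tibble with columns `y1` and `y2`, `length(x) - 2` rows.
#' @examples
#' sodp_pairs(c(0, 1, 3, 6))
#' @export
sodp_pairs <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("`x` must have at least 3 samples")
  d <- diff(x)
  tibble::tibble(y1 = d[-(n - 1)], y2 = d[-1])
}

#' SODP 95% confidence ellipse area
#'
#' Area of the 95% confidence ellipse covering the second-order difference
#' plot, `Ae = pi * alpha * beta`, where the radii derive from the root mean
#' squares `k1`, `k2` of the paired increment series and their mean cross
#' product `k12`:
#' `delta = sqrt((k1^2 + k2^2)^2 - 4 (k1^2 k2^2 - k12^2))`,
#' `alpha = sqrt(3 (k1^2 + k2^2 + delta))`,
#' `beta  = sqrt(3 (k1^2 + k2^2 - delta))`.
#' The moments use the conventional `1/(N-1)` normalizer over the `N - 2`
#' paired points; the `beta` radicand is clamped at 0 against roundoff.
#' Spiky, rapidly fluctuating signals spread the SODP cloud and inflate
#' `Ae`; a constant signal gives 0 and `Ae` scales as `c^2` under `x -> c x`.
#'
#' @param x Numeric vector, length >= 3.
#' @return Ellipse area (squared amplitude units).
#' @export
ellipse_area <- function(x) {
  p <- sodp_pairs(x)
  n <- length(x)
  k1sq <- sum(p$y1^2) / (n - 1)
  k2sq <- sum(p$y2^2) / (n - 1)
  k12 <- sum(p$y1 * p$y2) / (n - 1)
  delta <- sqrt(max((k1sq + k2sq)^2 - 4 * (k1sq * k2sq - k12^2), 0))
  alpha <- sqrt(3 * (k1sq + k2sq + delta))
  beta <- sqrt(3 * max(k1sq + k2sq - delta, 0))
  pi * alpha * beta
}

#' Squared coefficient of variation of the absolute series
#'
#' `Vsc = sigma^2 / mu^2` with `mu` the mean absolute amplitude and
#' `sigma^2` the population variance of the signal about its mean. The ratio
#' is scale invariant and grows with spiky, heavy-tailed amplitude
#' fluctuation. Returns 0 for the all-zero signal (`mu = 0`).
#'
#' @param x Numeric vector, length >= 2.
#' @return Dimensionless ratio >= 0.
#' @export
squared_cv_abs <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) abort("`x` must have at least 2 samples")
  mu <- mean(abs(x))
  if (mu == 0) return(0)
  sigma2 <- mean((x - mean(x))^2)
  sigma2 / mu^2
}

#' Fluctuation index
#'
#' Mean absolute first-order increment,
#' `Fi = mean(|x(n+1) - x(n)|)` over the `N - 1` increments. Measures how
#' frequently and strongly the amplitude changes; scales as `|c|` under
#' `x -> c x`.
#'
#' @param x Numeric vector, length >= 2.
#' @return Mean absolute increment (amplitude units).
#' @export
fluctuation_index <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) abort("`x` must have at least 2 samples")
  mean(abs(diff(x)))
}

#' Permutation entropy of ordinal patterns
#'
#' Shannon entropy (nats) of the relative frequencies of ordinal patterns in
#' sliding embedding windows `[x(k), x(k+lag), ..., x(k+(embed-1) lag)]`.
#' Equal values within a window are ranked by temporal order (stable ties).
#' Bounded by `log(embed!)`; a strictly monotone series has a single pattern
#' and entropy 0.
#'
#' @param x Numeric vector.
#' @param embed Embedding dimension (default 3).
#' @param lag Time lag between window elements (default 1).
#' @return Entropy in nats, in `[0, log(factorial(embed))]`.
#' @export
permutation_entropy <- function(x, embed = 3, lag = 1) {
  x <- as.numeric(x)
  stopifnot(embed >= 2, lag >= 1)
  n <- length(x)
  nw <- n - (embed - 1) * lag
  if (nw < 2) abort("`x` too short for this embedding")
  w <- matrix(0, nw, embed)
  for (j in seq_len(embed)) w[, j] <- x[seq_len(nw) + (j - 1) * lag]
  # rank of element i within its window, ties broken by temporal order:
  # rank_i = 1 + #{j : x_j < x_i, or x_j == x_i and j < i}
  ranks <- matrix(1L, nw, embed)
  for (i in seq_len(embed)) {
    for (j in seq_len(embed)) {
      if (i == j) next
      beats <- w[, j] < w[, i] | (w[, j] == w[, i] & j < i)
      ranks[, i] <- ranks[, i] + beats
    }
  }
  code <- as.vector(ranks %*% (embed + 1)^(seq_len(embed) - 1))
  p <- tabulate(match(code, unique(code)))
  p <- p / nw
  -sum(p * log(p))
}

#' Approximate entropy
#'
#' Pincus' regularity statistic: the mean log correlation integral of
#' Chebyshev-distance template matches at embedding dimension `embed` minus
#' the same at `embed + 1`, with tolerance `tol_factor` times the (population)
#' standard deviation of the series. Self-matches are included. A constant
#' series is perfectly regular and returns 0.
#'
#' @param x Numeric vector, length >= `embed + 2`.
#' @param embed Embedding dimension (default 2).
#' @param tol_factor Tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Approximate entropy in nats, >= 0 up to roundoff.
#' @export
approximate_entropy <- function(x, embed = 2, tol_factor = 0.2) {
  x <- as.numeric(x)
  stopifnot(embed >= 1, tol_factor > 0)
  if (length(x) < embed + 2) abort("`x` too short for approximate entropy")
  r <- tol_factor * sqrt(mean((x - mean(x))^2))
  .apen_cpp(x, as.integer(embed), r)
}

#' Order-alpha Renyi entropy of the power spectrum
#'
#' The power spectral density over the positive-frequency bins
#' `f = 1..floor(N/2)` (DC excluded) is normalized to a probability vector
#' `p_f` and summarised by `enE = log(sum(p_f^alpha)) / (1 - alpha)` in
#' nats. The default order 2 gives `-log(sum(p_f^2))`. A spectrally flat
#' signal attains the maximum `log(F)`; a single-bin spectrum gives 0.
#' The all-zero signal returns 0 by convention.
#'
#' @param x Numeric vector, length >= 4.
#' @param order Renyi order alpha (default 2, must differ from 1).
#' @return Entropy in nats, in `[0, log(floor(length(x)/2))]`.
#' @export
renyi_entropy <- function(x, order = 2) {
  x <- as.numeric(x)
  if (length(x) < 4) abort("`x` must have at least 4 samples")
  if (order == 1) abort("`order` must differ from 1")
  f <- floor(length(x) / 2)
  pw <- Mod(fft(x))^2
  pw <- pw[2:(f + 1)]
  tot <- sum(pw)
  if (tot == 0) return(0)
  p <- pw / tot
  log(sum(p^order)) / (1 - order)
}

#' Bispectral phase entropy
#'
#' Shannon entropy (nats) of the normalized squared bispectrum magnitude
#' over the bifrequency grid `f1, f2 = 1..F`, `F = floor(N/2)`, estimated
#' from the single frame as `B(f1,f2) = X(f1) X(f2) X*(f1+f2)` with cells
#' whose harmonic `f1 + f2` exceeds `F` carrying no probability mass.
#' Broadband signals spread mass over the whole admissible triangle (entropy
#' near `log` of the cell count); strong quadratic phase coupling
#' concentrates it. The all-zero signal returns 0 by convention.
#'
#' @param x Numeric vector, length >= 8.
#' @return Entropy in nats, >= 0.
#' @export
phase_entropy <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 8) abort("`x` must have at least 8 samples")
  f <- floor(length(x) / 2)
  # |B|^2 depends on the magnitude spectrum only: |X(f1) X(f2) X*(f1+f2)|^2
  m <- Mod(fft(x))^2
  mf <- m[2:(f + 1)]
  grid <- .bifreq_grid(f)
  q <- mf[grid$i] * mf[grid$j] * mf[grid$harm]
  tot <- sum(q)
  if (tot == 0) return(0)
  p <- q / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

# admissible (f1, f2) cells (f1 + f2 <= F) and their harmonic index; cached
# per F because frames share a common length
.bifreq_grid <- function(f) {
  key <- as.character(f)
  hit <- .epiged_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- sequence(f - seq_len(f - 1), from = 1)       # f1 for each admissible cell
  j <- rep.int(seq_len(f - 1), f - seq_len(f - 1))  # f2
  grid <- list(i = i, j = j, harm = i + j)
  .epiged_cache[[key]] <- grid
  grid
}

#' Feature parameter bundle
#'
#' Collects the tunable parameters of the seven features with the pipeline
#' defaults: permutation entropy embedding 3 / lag 1, approximate entropy
#' embedding 2 / tolerance 0.2 sd, Renyi order 2.
#'
#' @param pe_embed,pe_lag Permutation entropy embedding dimension and lag.
#' @param ape_embed,ape_tol Approximate entropy embedding dimension and
#'   tolerance factor (times sd).
#' @param renyi_order Renyi entropy order.
#' @return A named list of class `feature_params`.
#' @export
feature_params <- function(pe_embed = 3, pe_lag = 1, ape_embed = 2,
                           ape_tol = 0.2, renyi_order = 2) {
  structure(list(pe_embed = pe_embed, pe_lag = pe_lag,
                 ape_embed = ape_embed, ape_tol = ape_tol,
                 renyi_order = renyi_order),
            class = "feature_params")
}

.feature_names <- c("Ae", "Vsc", "Fi", "pE", "apE", "enE", "phE")

# the seven features of one signal, in fixed order
.signal_features <- function(x, params) {
  c(Ae = ellipse_area(x),
    Vsc = squared_cv_abs(x),
    Fi = fluctuation_index(x),
    pE = permutation_entropy(x, params$pe_embed, params$pe_lag),
    apE = approximate_entropy(x, params$ape_embed, params$ape_tol),
    enE = renyi_entropy(x, params$renyi_order),
    phE = phase_entropy(x))
}

#' Per-frame feature vector from a subband set
#'
#' Computes the seven features `Ae, Vsc, Fi, pE, apE, enE, phE` for each of
#' the `levels + 2` signals of a subband set (subbands `Sb1..Sb(levels+1)`
#' then the fullband `S`) and concatenates them in that order, giving a
#' `(levels + 2) * 7`-dimensional named vector — 42 values for the default
#' 4-level decomposition. Names follow `"{signal}:{feature}"`.
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @param params A [feature_params()] bundle.
#' @return Named numeric vector of length `(levels + 2) * 7`; all values
#'   finite.
#' @export
extract_feature_vector <- function(sb, params = feature_params()) {
  stopifnot(inherits(sb, "subband_set"))
  out <- unlist(lapply(names(sb$signals), function(nm) {
    v <- .signal_features(sb$signals[[nm]], params)
    names(v) <- paste0(nm, ":", names(v))
    v
  }))
  stopifnot(all(is.finite(out)))
  out
}

#' Feature table for a set of frames
#'
#' Maps the full decomposition + feature-extraction stage over a frame
#' tibble: each frame is decomposed with [dwt_decompose()] and summarised by
#' [extract_feature_vector()]. This is the interchange table between the
#' feature, selection and classification stages.
#'
#' @param frames Frame tibble from [frame_signal()], [gen_dataset()] or
#'   [read_frames_csv()].
#' @param levels Decomposition depth (default 4).
#' @param wavelet Wavelet name (default `"db4"`).
#' @param params A [feature_params()] bundle.
#' @return A tibble with `source_id`, `frame`, `label` and one column per
#'   feature (`(levels + 2) * 7` feature columns, e.g. `Sb1:Ae` .. `S:phE`).
#' @examples
#' frames <- gen_dataset(3, seed = 1)
#' feats <- extract_features(frames, levels = 2)
#' dim(feats)
#' @export
extract_features <- function(frames, levels = 4, wavelet = "db4",
                             params = feature_params()) {
  check_frames(frames)
  rows <- purrr::map(seq_len(nrow(frames)), function(i) {
    sb <- dwt_decompose(frames$samples[[i]], levels = levels,
                        wavelet = wavelet, fs = frames$fs[[i]])
    as.list(extract_feature_vector(sb, params))
  })
  dplyr::bind_cols(
    tibble::tibble(source_id = frames$source_id,
                   frame = frames$frame,
                   label = frames$label),
    dplyr::bind_rows(rows)
  )
}

#' Feature-matrix view of a feature table
#'
#' Splits a feature table into the numeric matrix of feature columns and the
#' label vector.
#'
#' @param features Feature tibble from [extract_features()].
#' @return List with `x` (numeric matrix, named columns) and `label`
#'   (integer vector, possibly NA).
#' @export
feature_matrix <- function(features) {
  meta <- intersect(c("source_id", "frame", "start_index", "label"),
                    names(features))
  cols <- setdiff(names(features), meta)
  x <- as.matrix(features[, cols, drop = FALSE])
  if (!is.numeric(x)) abort("non-numeric feature columns")
  list(x = x,
       label = if ("label" %in% names(features))
         as.integer(features$label) else rep(NA_integer_, nrow(x)))
}
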