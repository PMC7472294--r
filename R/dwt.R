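# Orthogonal multilevel DWT with periodized (circular) boundary handling.
#
# The periodized transform is exactly orthogonal: the analysis operator at
# each level is a pair of shift-by-2 circulant rows built from a quadrature
# mirror filter pair, so synthesis is its transpose and reconstruction is
# exact for every input length. When a level has odd input length the signal
# is padded by repeating its last sample before filtering and the pad is
# dropped on reconstruction; reconstruction stays exact, while Parseval
# holds to machine precision only for lengths divisible by 2^levels.

# Daubechies scaling (lowpass decomposition) filters, db1..db10.
.db_filters <- list(
  db1 = c(7.0710678118654757e-01, 7.0710678118654757e-01),
  db2 = c(-1.2940952255126037e-01, 2.2414386804201339e-01,
          8.3651630373780794e-01, 4.8296291314453416e-01),
  db3 = c(3.5226291885709533e-02, -8.5441273882026658e-02,
          -1.3501102001025458e-01, 4.5987750211849154e-01,
          8.0689150931109255e-01, 3.3267055295008263e-01),
  db4 = c(-1.0597401785069032e-02, 3.2883011666885197e-02,
          3.0841381835560764e-02, -1.8703481171909309e-01,
          -2.7983769416859854e-02, 6.3088076792985892e-01,
          7.1484657055291567e-01, 2.3037781330889651e-01),
  db5 = c(3.3357252854737712e-03, -1.2580751999081999e-02,
          -6.2414902127982744e-03, 7.7571493840045719e-02,
          -3.2244869584638375e-02, -2.4229488706638203e-01,
          1.3842814590132074e-01, 7.2430852843777294e-01,
          6.0382926979718965e-01, 1.6010239797419293e-01),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03,
          5.5384220116149613e-04, -3.1582039317486030e-02,
          2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01,
          3.1525035170919763e-01, 7.5113390802109536e-01,
          4.9462389039845306e-01, 1.1154074335010947e-01),
  db7 = c(3.5371379997452024e-04, -1.8016407040474908e-03,
          4.2957797292136651e-04, 1.2550998556099840e-02,
          -1.6574541630666881e-02, -3.8029936935014413e-02,
          8.0612609151083078e-02, 7.1309219266830259e-02,
          -2.2403618499387498e-01, -1.4390600392856498e-01,
          4.6978228740519312e-01, 7.2913209084623509e-01,
          3.9653931948191729e-01, 7.7852054085009184e-02),
  db8 = c(-1.1747678412476953e-04, 6.7544940645056933e-04,
          -3.9174037337694705e-04, -4.8703529934515741e-03,
          8.7460940474057766e-03, 1.3981027917398282e-02,
          -4.4088253930794755e-02, -1.7369301001807547e-02,
          1.2874742662047847e-01, 4.7248457391328279e-04,
          -2.8401554296154691e-01, -1.5829105256349306e-02,
          5.8535468365420673e-01, 6.7563073629728976e-01,
          3.1287159091429995e-01, 5.4415842243104008e-02),
  db9 = c(3.9347320316271603e-05, -2.5196318894271012e-04,
          2.3038576352319597e-04, 1.8476468830562265e-03,
          -4.2815036824634303e-03, -4.7232047577513972e-03,
          2.2361662123679096e-02, 2.5094711483145197e-04,
          -6.7632829061329974e-02, 3.0725681479333380e-02,
          1.4854074933810638e-01, -9.6840783222976456e-02,
          -2.9327378327917492e-01, 1.3319738582500756e-01,
          6.5728807805130052e-01, 6.0482312369011115e-01,
          2.4383467461259034e-01, 3.8077947363878345e-02),
  db10 = c(-1.3264202894521244e-05, 9.3588670320069592e-05,
           -1.1646685512928545e-04, -6.8585669495971162e-04,
           1.9924052951850561e-03, 1.3953517470529011e-03,
           -1.0733175483330575e-02, 3.6065535669561697e-03,
           3.3212674059341002e-02, -2.9457536821875813e-02,
           -7.1394147166397082e-02, 9.3057364603572348e-02,
           1.2736934033579325e-01, -1.9594627437737705e-01,
           -2.4984642432731538e-01, 2.8117234366057747e-01,
           6.8845903945360354e-01, 5.2720118893172563e-01,
           1.8817680007769150e-01, 2.6670057900555554e-02)
)

#' Decomposition filter pair of an orthogonal wavelet
#'
#' Returns the lowpass (scaling) and highpass (wavelet) analysis filters.
#' The highpass filter is the quadrature mirror of the lowpass one:
#' `g(k) = (-1)^k h(L - 1 - k)`.
#'
#' @param wavelet Wavelet name; Daubechies `"db1"` (Haar) through `"db10"`
#'   are built in, `"haar"` is an alias for `"db1"`.
#' @return A list with numeric vectors `lo` and `hi`.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  if (identical(wavelet, "haar")) wavelet <- "db1"
  lo <- .db_filters[[wavelet]]
  if (is.null(lo))
    abort(paste0("unknown wavelet: ", wavelet,
                 " (available: haar, ", paste(names(.db_filters),
                                              collapse = ", "), ")"))
  k <- seq_along(lo) - 1
  hi <- rev(lo) * (-1)^k
  list(lo = lo, hi = hi)
}

# One analysis step: circular filtering + dyadic downsampling.
# a[k] = sum_m lo[m] x[(2(k-1) + m) mod n + 1]; odd n is padded by repeating
# the last sample (pad recorded by the caller through the stored length).
.dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  fl <- length(filt$lo)
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), 0:(fl - 1L), "+") %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% filt$lo), d = drop(xm %*% filt$hi))
}

# One synthesis step (transpose of the analysis operator), truncated to the
# original (possibly odd) length.
.idwt_step <- function(a, d, filt, out_len) {
  half <- length(a)
  n <- 2L * half
  fl <- length(filt$lo)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in 0:(fl - 1L)) {
    pos <- (base + m) %% n + 1L
    contrib <- a * filt$lo[m + 1L] + d * filt$hi[m + 1L]
    x[pos] <- x[pos] + contrib
  }
  x[seq_len(out_len)]
}

# Multilevel analysis: returns detail coefficients d1..dL (fine to coarse),
# the final approximation aL, and the per-level input lengths needed to undo
# odd-length padding on synthesis.
.wavedec <- function(x, levels, filt) {
  stopifnot(levels >= 1)
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(a)
    st <- .dwt_step(a, filt)
    details[[l]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a, lens = lens)
}

# Synthesis from a coefficient set in which any bands may be zeroed.
.waverec <- function(details, approx, lens, filt) {
  a <- approx
  for (l in rev(seq_along(details))) {
    a <- .idwt_step(a, details[[l]], filt, lens[l])
  }
  a
}

#' Nominal dyadic subband cutoff frequencies
#'
#' The ideal band edges of an `levels`-level dyadic filter bank at sampling
#' rate `fs`: detail band `l` spans `(fs/2^(l+1), fs/2^l)` and the final
#' approximation spans `(0, fs/2^(levels+1))`. At the Bonn rate of 173.61 Hz
#' with 4 levels these are the familiar 43.4-86.8, 21.7-43.4, 10.85-21.7,
#' 5.43-10.85 and 0-5.43 Hz bands. Actual Daubechies rolloff overlaps these
#' edges; the nominal values are reported as-is.
#'
#' @param fs Sampling rate in Hz.
#' @param levels Number of decomposition levels (>= 1).
#' @return A tibble with columns `subband` (`Sb1` finest detail ..
#'   `Sb(levels+1)` approximation), `low_hz`, `high_hz`.
#' @examples
#' subband_cutoffs(173.61, 4)
#' @export
subband_cutoffs <- function(fs, levels) {
  stopifnot(fs > 0, levels >= 1)
  l <- seq_len(levels)
  tibble::tibble(
    subband = paste0("Sb", c(l, levels + 1)),
    low_hz = c(fs / 2^(l + 1), 0),
    high_hz = c(fs / 2^l, fs / 2^(levels + 1))
  )
}

#' Decompose a frame into time-domain subband signals
#'
#' Runs an `levels`-level discrete wavelet transform and reconstructs one
#' time-domain signal per coefficient band by zeroing all other bands before
#' inverse transformation: `Sb1` (finest detail) .. `Sb(levels)` (coarsest
#' detail), `Sb(levels+1)` (approximation). The untouched fullband frame is
#' appended as `S`, giving `levels + 2` signals, each of frame length. By
#' linearity of the synthesis operator the `levels + 1` reconstructed
#' subbands sum to the original frame exactly (numerical tolerance).
#'
#' @param frame A numeric vector, a one-row slice of a frame tibble, or an
#'   `eeg_segment`.
#' @param levels Decomposition depth L (default 4, giving 5 subbands).
#' @param wavelet Orthogonal wavelet name (default `"db4"`); see
#'   [wavelet_filters()].
#' @param fs Sampling rate in Hz, used only to report nominal cutoffs
#'   (default 173.61).
#' @return An object of class `subband_set`: list with `signals` (named list
#'   of `levels + 2` numeric vectors ending in the fullband `S`), `cutoffs`
#'   (tibble from [subband_cutoffs()]), `wavelet`, `levels` and `fs`.
#' @examples
#' sb <- dwt_decompose(rnorm(256), levels = 4)
#' names(sb$signals)
#' max(abs(Reduce(`+`, sb$signals[1:5]) - sb$signals$S))
#' @export
dwt_decompose <- function(frame, levels = 4, wavelet = "db4", fs = 173.61) {
  x <- frame_samples(frame)
  if (inherits(frame, "eeg_segment")) fs <- frame$fs
  if (is.data.frame(frame) && "fs" %in% names(frame)) fs <- frame$fs[[1]]
  stopifnot(levels >= 1)
  if (length(x) < 2^levels)
    abort(sprintf("frame of length %d too short for %d-level decomposition",
                  length(x), levels))
  filt <- wavelet_filters(wavelet)
  dec <- .wavedec(x, levels, filt)
  zero_details <- lapply(dec$details, function(d) numeric(length(d)))
  zero_approx <- numeric(length(dec$approx))
  signals <- vector("list", levels + 2)
  for (l in seq_len(levels)) {
    det <- zero_details
    det[[l]] <- dec$details[[l]]
    signals[[l]] <- .waverec(det, zero_approx, dec$lens, filt)
  }
  signals[[levels + 1]] <- .waverec(zero_details, dec$approx, dec$lens, filt)
  signals[[levels + 2]] <- x
  names(signals) <- c(paste0("Sb", seq_len(levels + 1)), "S")
  structure(
    list(signals = signals,
         cutoffs = subband_cutoffs(fs, levels),
         wavelet = wavelet, levels = levels, fs = fs),
    class = "subband_set"
  )
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %s, %d levels, %d signals of length %d\n",
              x$wavelet, x$levels, length(x$signals),
              length(x$signals[[1]])))
  print(x$cutoffs)
  invisible(x)
}

#' Subband signals of one frame as a long tibble
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @return A tibble with columns `subband`, `t` (sample index, 1-based) and
#'   `value`, suitable for ggplot2 faceting or CSV export.
#' @export
subbands_tbl <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  purrr::imap_dfr(sb$signals, function(v, nm)
    tibble::tibble(subband = nm, t = seq_along(v), value = v))
}

# extract a plain numeric sample vector from whatever holds one
frame_samples <- function(frame) {
  if (is.numeric(frame)) return(as.numeric(frame))
  if (inherits(frame, "eeg_segment")) return(frame$samples)
  if (is.data.frame(frame) && "samples" %in% names(frame)) {
    if (nrow(frame) != 1)
      abort("expected a single frame (one-row tibble)")
    return(as.numeric(frame$samples[[1]]))
  }
  if (is.list(frame) && is.numeric(frame[[1]])) return(as.numeric(frame[[1]]))
  abort("cannot interpret `frame` as a sample vector")
}
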