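# Synthetic single-channel EEG with the statistical structure the spike and
# entropy features target: both classes share a band-limited 1/f-like
# background; the seizure class is additionally amplified (burst gain) and
# carries a Poisson train of biphasic transient spikes. This emulates the
# amplitude-fluctuation contrast between ictal and interictal EEG, not the
# physiology (no neural mass dynamics, no artifacts, no nonstationarity
# beyond the spikes).

#' Synthetic EEG generator configuration
#'
#' Defaults emulate the framing of the Bonn recordings (173.61 Hz, 10 s
#' frames) with a 1/f background of ~50 amplitude units and, for the
#' seizure class, a 0.8 events/s train of biphasic (Gaussian-derivative)
#' spikes of ~70 ms width at 4x the background scale plus a 1.6x amplitude
#' burst gain. A lognormal per-frame gain spread (sd 0.4 on the log scale,
#' both classes) provides inter-frame amplitude variability so the classes
#' overlap rather than separate on a single threshold.
#'
#' @param fs Sampling rate in Hz.
#' @param frame_len_s Frame length in seconds.
#' @param bg_exponent Spectral exponent of the 1/f^a background (power).
#' @param bg_scale Background amplitude scale (standard deviation).
#' @param spike_rate Seizure spike rate, events per second (> 0; 0 disables
#'   spikes).
#' @param spike_amp Spike peak amplitude as a multiple of `bg_scale`.
#' @param spike_width_ms Full spike width in milliseconds (the biphasic
#'   pulse spans about 6 Gaussian sigmas).
#' @param burst_gain Amplitude multiplier of the seizure-class background.
#' @param gain_jitter_sd Lognormal sd of the per-frame gain (both classes).
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(fs = 173.61, frame_len_s = 10, bg_exponent = 1,
                         bg_scale = 50, spike_rate = 0.8, spike_amp = 4,
                         spike_width_ms = 70, burst_gain = 1.6,
                         gain_jitter_sd = 0.4) {
  stopifnot(fs > 0, frame_len_s > 0, bg_scale > 0, spike_rate >= 0,
            spike_amp > 0, spike_width_ms > 0, burst_gain > 0,
            gain_jitter_sd >= 0)
  structure(list(fs = fs, frame_len_s = frame_len_s,
                 bg_exponent = bg_exponent, bg_scale = bg_scale,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 spike_width_ms = spike_width_ms, burst_gain = burst_gain,
                 gain_jitter_sd = gain_jitter_sd),
            class = "synth_config")
}

# band-limited 1/f^a noise of unit variance via spectral shaping
.gen_background <- function(n, exponent) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # symmetric bin distance from DC
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# biphasic spike: first derivative of a Gaussian, peak amplitude 1
.spike_shape <- function(sigma_samples) {
  half <- max(ceiling(3 * sigma_samples), 2)
  t <- seq(-half, half)
  s <- -t * exp(-t^2 / (2 * sigma_samples^2))
  s / max(abs(s))
}

#' Generate one synthetic EEG frame
#'
#' Deterministic given `seed`: the non-seizure class is 1/f background
#' only; the seizure class is the background times the burst gain plus a
#' Poisson spike train of biphasic pulses with random polarity and mild
#' amplitude jitter.
#'
#' @param class `"seizure"` or `"nonseizure"` (aliases `1`/`0`).
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return Numeric vector of `round(fs * frame_len_s)` samples.
#' @examples
#' x <- gen_frame("seizure", seed = 3)
#' length(x)
#' @export
gen_frame <- function(class = c("nonseizure", "seizure"),
                      cfg = synth_config(), seed = 1L) {
  if (is.numeric(class)) class <- if (class >= 1) "seizure" else "nonseizure"
  class <- match.arg(class)
  n <- round(cfg$fs * cfg$frame_len_s)
  withr_seed(seed, {
    gain <- exp(stats::rnorm(1, 0, cfg$gain_jitter_sd))
    x <- .gen_background(n, cfg$bg_exponent) * cfg$bg_scale * gain
    if (class == "seizure") {
      x <- x * cfg$burst_gain
      n_spk <- stats::rpois(1, cfg$spike_rate * cfg$frame_len_s)
      if (n_spk > 0) {
        sigma <- cfg$spike_width_ms / 1000 * cfg$fs / 6
        shape <- .spike_shape(sigma)
        half <- (length(shape) - 1) / 2
        centers <- sample.int(n, n_spk, replace = TRUE)
        amps <- cfg$spike_amp * cfg$bg_scale * gain *
          stats::runif(n_spk, 0.7, 1.3) *
          sample(c(-1, 1), n_spk, replace = TRUE)
        for (i in seq_len(n_spk)) {
          pos <- (centers[i] - half):(centers[i] + half)
          ok <- pos >= 1 & pos <= n
          x[pos[ok]] <- x[pos[ok]] + amps[i] * shape[ok]
        }
      }
    }
    x
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' `n_per_class` frames of each class, shuffled, with per-frame seeds drawn
#' from the master seed so the dataset is reproducible as a whole.
#'
#' @param n_per_class Frames per class (>= 1).
#' @param cfg A [synth_config()].
#' @param seed Master integer seed.
#' @return A frame tibble (see [frame_signal()]) with `label` 1 for
#'   seizure and 0 for non-seizure frames.
#' @examples
#' frames <- gen_dataset(5, seed = 1)
#' table(frames$label)
#' @export
gen_dataset <- function(n_per_class, cfg = synth_config(), seed = 1L) {
  stopifnot(n_per_class >= 1)
  n_tot <- 2L * n_per_class
  plan <- withr_seed(seed, {
    frame_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    ord <- sample.int(n_tot)
    list(frame_seeds = frame_seeds, ord = ord)
  })
  labels <- rep(c(0L, 1L), each = n_per_class)
  cls_idx <- c(seq_len(n_per_class), seq_len(n_per_class))
  samples <- lapply(seq_len(n_tot), function(i)
    gen_frame(labels[i], cfg, plan$frame_seeds[i]))
  tbl <- tibble::tibble(
    source_id = sprintf("syn_%s_%03d",
                        ifelse(labels == 1, "seiz", "bg"), cls_idx),
    frame = seq_len(n_tot),
    start_index = 0L,
    fs = cfg$fs,
    label = labels,
    samples = samples
  )
  tbl <- tbl[plan$ord, ]
  tbl$frame <- seq_len(n_tot)
  tbl
}
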