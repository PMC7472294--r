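#' Read a single-channel EEG segment from a plain-text file
#'
#' Reads the one-sample-per-line ASCII dialect used by the Bonn EEG archive
#' (one integer or float per line), or a generic single-column CSV whose
#' optional header is `value`. No rescaling, detrending or filtering is
#' applied: samples are returned exactly as stored.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz (the Bonn recordings use 173.61 Hz).
#' @param source_id Free-text identifier for the segment; defaults to the
#'   file name without extension.
#' @param set_label Optional class tag (e.g. `"A"`..`"E"` for the Bonn sets,
#'   or a synthetic class name).
#'
#' @return An object of class `eeg_segment`: a list with elements `samples`
#'   (numeric vector), `fs`, `source_id` and `set_label`.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("12", "-3", "41"), tf)
#' seg <- read_eeg_segment(tf, fs = 173.61)
#' seg$samples
#' @export
read_eeg_segment <- function(path, fs, source_id = NULL, set_label = NULL) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort("`fs` must be a positive sampling rate in Hz")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) && identical(tolower(lines[1]), "value")) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) abort(paste0("empty segment: ", path))
  samples <- suppressWarnings(as.numeric(lines))
  if (anyNA(samples)) {
    bad <- line_no[which(is.na(samples))[1]]
    abort(paste0("parse error in ", path, " at line ", bad,
                 ": not a numeric sample"))
  }
  if (!all(is.finite(samples))) abort(paste0("non-finite sample in ", path))
  new_eeg_segment(samples, fs,
                  source_id = source_id %||%
                    sub("\\.[^.]*$", "", basename(path)),
                  set_label = set_label)
}

#' Construct an EEG segment in memory
#'
#' @param samples Numeric sample vector (finite, non-empty).
#' @param fs Sampling rate in Hz.
#' @param source_id Free-text identifier.
#' @param set_label Optional class tag.
#' @return An `eeg_segment`.
#' @export
new_eeg_segment <- function(samples, fs, source_id = "segment",
                            set_label = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, all(is.finite(samples)),
            fs > 0)
  structure(
    list(samples = as.numeric(samples), fs = fs,
         source_id = source_id, set_label = set_label),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s: %d samples @ %.2f Hz (%.2f s)%s\n",
              x$source_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$set_label)) "" else
                paste0(", set ", x$set_label)))
  invisible(x)
}

#' Write samples in the Bonn-style single-column text dialect
#'
#' One sample per line, so that [read_eeg_segment()] round-trips the file.
#'
#' @param samples Numeric vector of samples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_segment <- function(samples, path) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  writeLines(format(samples, scientific = FALSE, trim = TRUE, digits = 15),
             path)
  invisible(path)
}

#' Cut an EEG segment into fixed-length overlapping frames
#'
#' Frames of `frame_len_s` seconds are taken every
#' `hop = round(frame_len_s * fs * (1 - overlap))` samples from the start of
#' the segment, for as long as a full frame fits. With `end_anchor = TRUE`
#' (the default) one extra frame ending exactly at the last sample is
#' appended whenever the hop-aligned frames do not reach the segment end;
#' a 23.6 s Bonn segment framed at 10 s / 50% overlap then yields 4 frames
#' instead of 3, so a 100-segment set yields 400 frames.
#'
#' @param seg An `eeg_segment` (see [read_eeg_segment()]), or a plain numeric
#'   vector together with `fs`.
#' @param frame_len_s Frame length in seconds (default 10).
#' @param overlap Fractional overlap between consecutive frames in `[0, 1)`
#'   (default 0.5).
#' @param end_anchor Append a final frame anchored to the segment end when
#'   the hop grid falls short (default `TRUE`).
#' @param fs Sampling rate, only needed when `seg` is a bare numeric vector.
#' @param label Optional binary class label (1 = seizure, 0 = non-seizure)
#'   attached to every emitted frame.
#'
#' @return A tibble with one row per frame: `source_id`, `frame`,
#'   `start_index` (0-based sample offset), `fs`, `label`, and `samples`
#'   (list-column of numeric vectors, each of length
#'   `round(frame_len_s * fs)`).
#' @examples
#' seg <- new_eeg_segment(sin(seq_len(4097)), fs = 173.61)
#' frame_signal(seg)          # 4 frames
#' @export
frame_signal <- function(seg, frame_len_s = 10, overlap = 0.5,
                         end_anchor = TRUE, fs = NULL, label = NULL) {
  if (is.numeric(seg)) {
    if (is.null(fs)) abort("`fs` is required when `seg` is a numeric vector")
    seg <- new_eeg_segment(seg, fs)
  }
  stopifnot(inherits(seg, "eeg_segment"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  n_seg <- length(seg$samples)
  n_frame <- round(frame_len_s * seg$fs)
  if (n_frame < 1) abort("`frame_len_s` too small for this sampling rate")
  if (n_frame > n_seg) abort("segment shorter than frame")
  hop <- max(1L, round(n_frame * (1 - overlap)))
  starts <- seq.int(0L, n_seg - n_frame, by = hop)
  if (end_anchor) {
    last_start <- n_seg - n_frame
    if (starts[length(starts)] != last_start)
      starts <- c(starts, last_start)
  }
  samples <- lapply(starts, function(s) seg$samples[(s + 1):(s + n_frame)])
  tibble::tibble(
    source_id = seg$source_id,
    frame = seq_along(starts),
    start_index = as.integer(starts),
    fs = seg$fs,
    label = if (is.null(label)) NA_integer_ else as.integer(label),
    samples = samples
  )
}

#' Write / read a frame table as plain CSV
#'
#' One row per frame: `source_id`, `start_index`, `label`, then the samples
#' `s1..sn`. Intended for fixture exchange, not bulk storage.
#'
#' @param frames A frame tibble from [frame_signal()] or [gen_dataset()].
#' @param path CSV file path.
#' @return `path` (write) or a frame tibble (read), invisibly for the writer.
#' @export
write_frames_csv <- function(frames, path) {
  check_frames(frames)
  n <- lengths(frames$samples)
  if (length(unique(n)) != 1) abort("frames must share a common length")
  mat <- do.call(rbind, frames$samples)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  df <- cbind(
    data.frame(source_id = frames$source_id,
               start_index = frames$start_index,
               fs = frames$fs,
               label = frames$label),
    as.data.frame(mat)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  scols <- grep("^s[0-9]+$", names(df))
  if (!length(scols)) abort("no sample columns s1..sn found")
  mat <- as.matrix(df[, scols, drop = FALSE])
  tibble::tibble(
    source_id = as.character(df$source_id),
    frame = seq_len(nrow(df)),
    start_index = as.integer(df$start_index),
    fs = as.numeric(df$fs),
    label = as.integer(df$label),
    samples = lapply(seq_len(nrow(mat)), function(i) unname(mat[i, ]))
  )
}

check_frames <- function(frames) {
  if (!is.data.frame(frames) ||
      !all(c("samples", "fs", "label") %in% names(frames)))
    abort("expected a frame tibble with `samples`, `fs` and `label` columns")
  invisible(frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
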