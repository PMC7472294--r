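# Whole-pipeline configuration and the run_* entry points behind the
# command-line tool (exec/epiged). Exit-code conventions of the CLI:
# 0 success, 2 configuration error, 3 data error.

#' Pipeline configuration
#'
#' Aggregates every tunable stage parameter with the pipeline defaults:
#' 10 s frames at 50% overlap (end-anchored), db4 4-level decomposition,
#' permutation entropy embedding 3 / lag 1, approximate entropy embedding
#' 2 / 0.2 sd tolerance, Renyi order 2, GED with gamma 0.5 / 10 MI bins /
#' 16 selected features, a 10-hidden-unit network and 5-fold CV. Round-trips
#' through YAML unchanged ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param framing,subbands,features,selection,classifier,cv Named lists
#'   overriding individual fields of the corresponding stage.
#' @return A nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function(framing = list(), subbands = list(),
                            features = list(), selection = list(),
                            classifier = list(), cv = list()) {
  cfg <- list(
    framing = list(frame_len_s = 10, overlap = 0.5, end_anchor = TRUE,
                   fs = 173.61),
    subbands = list(levels = 4L, wavelet = "db4"),
    features = list(pe_embed = 3L, pe_lag = 1L, ape_embed = 2L,
                    ape_tol = 0.2, renyi_order = 2),
    selection = list(k = 16L, gamma = 0.5, mi_bins = 10L),
    classifier = list(n_hidden = 10L, decay = 1e-4, max_iters = 500L),
    cv = list(folds = 5L, seed = 1L)
  )
  for (stage in names(cfg)) {
    ov <- get(stage)
    bad <- setdiff(names(ov), names(cfg[[stage]]))
    if (length(bad))
      abort(paste0("unknown ", stage, " option(s): ",
                   paste(bad, collapse = ", ")))
    cfg[[stage]][names(ov)] <- ov
  }
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    stopifnot(framing$frame_len_s > 0,
              framing$overlap >= 0, framing$overlap < 1,
              framing$fs > 0,
              subbands$levels >= 1,
              selection$gamma >= 0, selection$gamma <= 1,
              selection$mi_bins >= 2,
              classifier$n_hidden >= 1,
              cv$folds >= 2)
  })
  m <- (cfg$subbands$levels + 2L) * 7L
  if (cfg$selection$k < 1 || cfg$selection$k > m)
    abort(sprintf("selection k = %d out of range 1..%d for %d levels",
                  cfg$selection$k, m, cfg$subbands$levels))
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         c("framing", "subbands", "features",
                                           "selection", "classifier",
                                           "cv"))])
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate a synthetic dataset to Bonn-style text files
#'
#' Writes one single-column text file per frame plus a `labels.csv`
#' manifest, so the files round-trip through [read_eeg_segment()].
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_class Frames per class.
#' @param cfg A [pipeline_config()] (framing block supplies fs and length).
#' @param synth A [synth_config()]; defaults derive fs/frame length from
#'   `cfg`.
#' @param seed Master seed.
#' @return The manifest tibble (`file`, `label`), invisibly.
#' @export
run_simulate <- function(out_dir, n_per_class, cfg = pipeline_config(),
                         synth = NULL, seed = 1L) {
  synth <- synth %||% synth_config(fs = cfg$framing$fs,
                                   frame_len_s = cfg$framing$frame_len_s)
  frames <- gen_dataset(n_per_class, synth, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.txt", frames$source_id)
  for (i in seq_len(nrow(frames)))
    write_bonn_segment(frames$samples[[i]], file.path(out_dir, files[i]))
  manifest <- tibble::tibble(file = files, label = frames$label)
  utils::write.csv(manifest, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Extract a feature table from Bonn-style input files
#'
#' Each input file is read, framed per the config, decomposed and
#' featurized; the result is the CSV interchange table of the pipeline.
#'
#' @param inputs Character vector of input file paths.
#' @param out_csv Optional output CSV path.
#' @param cfg A [pipeline_config()].
#' @param labels Optional per-file labels (recycled to frames of the file).
#' @param quiet Suppress per-file progress messages.
#' @return The feature tibble, invisibly when `out_csv` is given.
#' @export
run_extract <- function(inputs, out_csv = NULL, cfg = pipeline_config(),
                        labels = NULL, quiet = FALSE) {
  if (!length(inputs)) abort("no input files")
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    abort(paste0("input file(s) not found: ",
                 paste(missing, collapse = ", ")))
  if (!is.null(labels) && length(labels) != length(inputs))
    abort("`labels` must match `inputs` in length")
  fp <- feature_params(pe_embed = cfg$features$pe_embed,
                       pe_lag = cfg$features$pe_lag,
                       ape_embed = cfg$features$ape_embed,
                       ape_tol = cfg$features$ape_tol,
                       renyi_order = cfg$features$renyi_order)
  tables <- purrr::map(seq_along(inputs), function(i) {
    seg <- read_eeg_segment(inputs[i], fs = cfg$framing$fs)
    frames <- frame_signal(seg, frame_len_s = cfg$framing$frame_len_s,
                           overlap = cfg$framing$overlap,
                           end_anchor = cfg$framing$end_anchor,
                           label = if (is.null(labels)) NULL else labels[i])
    if (!quiet)
      message(sprintf("%s: %d frames", basename(inputs[i]), nrow(frames)))
    extract_features(frames, levels = cfg$subbands$levels,
                     wavelet = cfg$subbands$wavelet, params = fp)
  })
  features <- dplyr::bind_rows(tables)
  if (!is.null(out_csv)) {
    utils::write.csv(features, out_csv, row.names = FALSE)
    return(invisible(features))
  }
  features
}

#' Fit GED selection on a feature table and serialize the ranking
#'
#' @param features Feature tibble or CSV path.
#' @param out_json Optional JSON path for indices, names and weights.
#' @param cfg A [pipeline_config()].
#' @return The `ged_fit`, invisibly when `out_json` is given.
#' @export
run_select <- function(features, out_json = NULL, cfg = pipeline_config()) {
  features <- load_feature_table(features)
  fit <- ged_select(features, k = cfg$selection$k,
                    gamma = cfg$selection$gamma,
                    mi_bins = cfg$selection$mi_bins)
  if (!is.null(out_json)) {
    obj <- list(selected_indices = fit$ranking[seq_len(fit$k)],
                selected_names = fit$selected,
                weights = as.list(fit$weights),
                gamma = fit$gamma, k = fit$k)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), out_json)
    return(invisible(fit))
  }
  fit
}

#' Cross-validated evaluation of a labeled feature table
#'
#' @param features Feature tibble or CSV path (labels required).
#' @param out_json Optional JSON path for the full CV result.
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress the metric summary message.
#' @return The `cv_result`, invisibly when `out_json` is given.
#' @export
run_evaluate <- function(features, out_json = NULL, cfg = pipeline_config(),
                         quiet = FALSE) {
  features <- load_feature_table(features)
  if (anyNA(features$label)) abort("unlabeled feature table")
  res <- kfold_evaluate(
    features, k_features = cfg$selection$k, folds = cfg$cv$folds,
    gamma = cfg$selection$gamma, mi_bins = cfg$selection$mi_bins,
    classifier = ffnn_classifier(n_hidden = cfg$classifier$n_hidden,
                                 decay = cfg$classifier$decay,
                                 max_iters = cfg$classifier$max_iters),
    seed = cfg$cv$seed
  )
  if (!quiet)
    message(sprintf("mean ACC %.2f%%, SEN %.2f%%, SPE %.2f%%",
                    res$mean_acc, res$mean_sen, res$mean_spe))
  if (!is.null(out_json)) {
    cv_result_json(res, out_json)
    return(invisible(res))
  }
  res
}

load_feature_table <- function(features) {
  if (is.character(features)) {
    if (!file.exists(features))
      abort(paste0("feature table not found: ", features))
    features <- tibble::as_tibble(utils::read.csv(features,
                                                  check.names = FALSE))
  }
  features
}
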