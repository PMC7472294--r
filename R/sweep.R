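# Sweep utilities mirroring the two tuning experiments: mean CV accuracy
# as a function of the decomposition level, and a grid over the number of
# selected features x hidden units.

#' Sweep the wavelet decomposition level
#'
#' Re-extracts features at each requested level and reports the mean
#' cross-validated accuracy, mirroring the accuracy-versus-level
#' experiment. `k_features` is capped at the feature count available at
#' each level (`(level + 2) * 7`).
#'
#' @param frames Labeled frame tibble (e.g. from [gen_dataset()]).
#' @param levels Integer vector of decomposition levels to try.
#' @param cfg A [pipeline_config()] providing the remaining parameters.
#' @return A tibble with `levels`, `n_features`, `k_features`, `mean_acc`,
#'   `mean_sen`, `mean_spe`; the accuracy argmax is reported in the
#'   `argmax` attribute.
#' @export
sweep_levels <- function(frames, levels = 1:6, cfg = pipeline_config()) {
  if (!length(levels)) abort("empty level grid")
  check_frames(frames)
  rows <- purrr::map(levels, function(lv) {
    feats <- extract_features(frames, levels = lv,
                              wavelet = cfg$subbands$wavelet)
    m <- (lv + 2L) * 7L
    k <- min(cfg$selection$k, m)
    res <- kfold_evaluate(
      feats, k_features = k, folds = cfg$cv$folds,
      gamma = cfg$selection$gamma, mi_bins = cfg$selection$mi_bins,
      classifier = ffnn_classifier(n_hidden = cfg$classifier$n_hidden),
      seed = cfg$cv$seed
    )
    tibble::tibble(levels = lv, n_features = m, k_features = k,
                   mean_acc = res$mean_acc, mean_sen = res$mean_sen,
                   mean_spe = res$mean_spe)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "argmax") <- out$levels[which.max(out$mean_acc)]
  out
}

#' Grid search over selected-feature count and hidden-layer width
#'
#' Evaluates the mean CV accuracy on a fixed feature table for every
#' combination of `k_grid` (features kept by GED) and `hidden_grid`
#' (network width).
#'
#' @param features Labeled feature tibble.
#' @param k_grid Integer vector of feature counts.
#' @param hidden_grid Integer vector of hidden-unit counts.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per grid cell (`k_features`, `n_hidden`,
#'   `mean_acc`, `mean_sen`, `mean_spe`); the accuracy argmax cell is in
#'   the `argmax` attribute.
#' @export
sweep_grid <- function(features, k_grid, hidden_grid,
                       cfg = pipeline_config()) {
  if (!length(k_grid) || !length(hidden_grid)) abort("empty grid")
  features <- load_feature_table(features)
  m <- ncol(feature_matrix(features)$x)
  if (any(k_grid < 1 | k_grid > m))
    abort(sprintf("k grid values must lie in 1..%d", m))
  cells <- tidyr::expand_grid(k_features = sort(unique(k_grid)),
                              n_hidden = sort(unique(hidden_grid)))
  rows <- purrr::pmap(cells, function(k_features, n_hidden) {
    res <- kfold_evaluate(
      features, k_features = k_features, folds = cfg$cv$folds,
      gamma = cfg$selection$gamma, mi_bins = cfg$selection$mi_bins,
      classifier = ffnn_classifier(n_hidden = n_hidden),
      seed = cfg$cv$seed
    )
    tibble::tibble(k_features = k_features, n_hidden = n_hidden,
                   mean_acc = res$mean_acc, mean_sen = res$mean_sen,
                   mean_spe = res$mean_spe)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "argmax") <- out[which.max(out$mean_acc),
                             c("k_features", "n_hidden")]
  out
}

#' Accuracy heat map of a feature x hidden-unit grid
#'
#' @param sweep Result of [sweep_grid()].
#' @return A ggplot object.
#' @export
plot_sweep_grid <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$k_features),
                                      y = factor(.data$n_hidden),
                                      fill = .data$mean_acc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean ACC (%)") +
    ggplot2::labs(x = "selected features", y = "hidden units") +
    ggplot2::theme_minimal()
}
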