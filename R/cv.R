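# Stratified K-fold evaluation of the full selection + classification
# stage. Feature ranking, standardization statistics and the network are
# all fitted on the training folds only and applied to the held-out fold.

#' Seeded stratified K-fold assignment
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per row, class-balanced.
#' @export
stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- as.integer(y)
  if (any(table(y) < k)) abort("infeasible stratification: need >= K per class")
  fold <- integer(length(y))
  fold_sizes <- integer(k)
  withr_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      counts <- rep.int(base, k)
      if (rem > 0) {
        # spread remainders onto the currently smallest folds so overall
        # fold sizes stay as equal as the class sizes allow
        extras <- order(fold_sizes, seq_len(k))[seq_len(rem)]
        counts[extras] <- counts[extras] + 1L
      }
      fold[idx] <- sample(rep.int(seq_len(k), counts))
      fold_sizes <- fold_sizes + counts
    }
  })
  fold
}

#' Cross-validated evaluation of the seizure-detection pipeline
#'
#' Runs stratified K-fold cross-validation over a labeled feature table.
#' Within each fold the GED ranking ([ged_select()]) and the z-score
#' statistics ([standardize()]) are fitted on the training rows alone, the
#' top-`k_features` columns are selected, the classifier is trained, and
#' accuracy/sensitivity/specificity are computed on the held-out rows.
#'
#' @param features Labeled feature tibble from [extract_features()].
#' @param k_features Number of features selected per fold (default 16).
#' @param folds Number of CV folds K (default 5: 80% train / 20%
#'   validation).
#' @param gamma,mi_bins GED parameters (see [ged_select()]).
#' @param classifier A classifier hook (default [ffnn_classifier()] with 10
#'   hidden units).
#' @param seed Integer seed driving fold assignment and network
#'   initialisation; the whole evaluation is deterministic given it.
#' @return An object of class `cv_result`: `per_fold` (tibble of per-fold
#'   confusion counts and metrics), `mean_acc`, `mean_sen`, `mean_spe`,
#'   `selected` (list of per-fold selected feature names), `config` echo
#'   and `seed`. Methods: [tidy()], [glance()], [autoplot()],
#'   [cv_result_json()].
#' @examples
#' feats <- extract_features(gen_dataset(15, seed = 7), levels = 2)
#' res <- kfold_evaluate(feats, k_features = 6, folds = 3, seed = 7)
#' glance(res)
#' @export
kfold_evaluate <- function(features, k_features = 16, folds = 5,
                           gamma = 0.5, mi_bins = 10,
                           classifier = ffnn_classifier(), seed = 1L) {
  fm <- feature_matrix(features)
  if (anyNA(fm$label)) abort("labeled features required")
  fold_id <- stratified_folds(fm$label, k = folds, seed = seed)
  per_fold <- vector("list", folds)
  selected <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- ged_select(features[tr, , drop = FALSE], k = k_features,
                      gamma = gamma, mi_bins = mi_bins)
    keep <- fit$ranking[seq_len(k_features)]
    std <- standardize(fm$x[tr, keep, drop = FALSE],
                       fm$x[, keep, drop = FALSE])
    model <- classifier$fit(std$x[tr, , drop = FALSE], fm$label[tr],
                            seed + f)
    pred <- classifier$predict(model, std$x[!tr, , drop = FALSE])
    if (is.data.frame(pred)) pred <- pred$label
    per_fold[[f]] <- dplyr::mutate(
      compute_metrics(fm$label[!tr], pred),
      fold = f, n_train = sum(tr), n_validate = sum(!tr),
      .before = 1
    )
    selected[[f]] <- colnames(fm$x)[keep]
  }
  per_fold <- dplyr::bind_rows(per_fold)
  structure(
    list(per_fold = per_fold,
         mean_acc = mean(per_fold$acc),
         mean_sen = mean(per_fold$sen),
         mean_spe = mean(per_fold$spe),
         selected = selected,
         config = list(k_features = k_features, folds = folds,
                       gamma = gamma, mi_bins = mi_bins,
                       classifier = classifier$label),
         seed = as.integer(seed)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV (%s, top %d features): ACC %.2f%%, SEN %.2f%%, SPE %.2f%%\n",
    x$config$folds, x$config$classifier, x$config$k_features,
    x$mean_acc, x$mean_sen, x$mean_spe))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(folds = x$config$folds,
                 k_features = x$config$k_features,
                 classifier = x$config$classifier,
                 mean_acc = x$mean_acc, mean_sen = x$mean_sen,
                 mean_spe = x$mean_spe, seed = x$seed)
}

#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, c("acc", "sen", "spe"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold),
                                     y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "fold", y = "percent",
                  title = sprintf("%d-fold CV: mean ACC %.1f%%",
                                  object$config$folds, object$mean_acc)) +
    ggplot2::theme_minimal()
}

#' Serialize a CV result to JSON
#'
#' Per-fold confusion counts and metrics, the selected feature names, the
#' configuration echo and the seed — enough to reproduce the run exactly.
#'
#' @param x A `cv_result`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
cv_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cv_result"))
  obj <- list(per_fold = x$per_fold,
              means = list(acc = x$mean_acc, sen = x$mean_sen,
                           spe = x$mean_spe),
              selected = x$selected, config = x$config, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
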