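#' Confusion counts and ACC/SEN/SPE
#'
#' Binary classification metrics with the seizure class (label 1) as
#' positive: `ACC = 100 (TP + TN) / (TP + TN + FP + FN)`,
#' `SEN = 100 TP / (TP + FN)`, `SPE = 100 TN / (TN + FP)`; sensitivity and
#' specificity are defined as 0 when their denominator is 0.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `acc`, `sen`, `spe`
#'   (percentages).
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    abort("labels must be binary 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = 100 * (tp + tn) / max(tp + tn + fp + fn, 1),
    sen = if (tp + fn == 0) 0 else 100 * tp / (tp + fn),
    spe = if (tn + fp == 0) 0 else 100 * tn / (tn + fp)
  )
}

#' Z-score standardization fitted on training rows
#'
#' Column means and standard deviations are estimated on `train` only and
#' applied to `apply_to`; zero-variance columns are centered and passed
#' through (never NaN).
#'
#' @param train Numeric matrix defining the statistics.
#' @param apply_to Numeric matrix to transform (defaults to `train`).
#' @return A list with `x` (transformed `apply_to`), `center`, `scale`.
#' @export
standardize <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  if (ncol(train) != ncol(apply_to)) abort("column mismatch")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  x <- sweep(sweep(apply_to, 2, ctr, "-"), 2, scl, "/")
  list(x = x, center = ctr, scale = scl)
}
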