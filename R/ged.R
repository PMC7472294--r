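# Graph-eigen-decomposition feature selection: features are vertices of an
# undirected graph whose adjacency mixes a rank-1 relevance kernel (min-max
# normalized Fisher scores times mutual-information scores) with a pairwise
# dispersion matrix; features are ranked by the absolute principal
# eigenvector of the symmetrized adjacency.

#' Fisher discriminant scores per feature
#'
#' `D_i = (mu_i1 - mu_i2)^2 / (sigma_i1^2 + sigma_i2^2 + eps)` with
#' population (1/n) class moments; `eps` guards constant features.
#'
#' @param x Numeric feature matrix (rows = frames, columns = features).
#' @param y Binary label vector (two classes present).
#' @param eps Variance guard added to the denominator (default 1e-12).
#' @return Nonnegative numeric vector, one score per column.
#' @export
fisher_scores <- function(x, y, eps = 1e-12) {
  x <- as.matrix(x)
  cls <- sort(unique(y))
  if (length(cls) != 2) abort("two classes required")
  a <- x[y == cls[1], , drop = FALSE]
  b <- x[y == cls[2], , drop = FALSE]
  mu_a <- colMeans(a); mu_b <- colMeans(b)
  var_a <- colMeans(a^2) - mu_a^2
  var_b <- colMeans(b^2) - mu_b^2
  d <- (mu_a - mu_b)^2 / (pmax(var_a, 0) + pmax(var_b, 0) + eps)
  stats::setNames(d, colnames(x))
}

#' Mutual information between binned features and the class label
#'
#' Each feature is discretized into `bins` equal-width bins over its
#' observed range (values outside the fitted range, e.g. held-out data
#' scored against training-fold bins, clip to the edge bins) and the
#' feature/label mutual information `R_i = sum p(m,t) log(p(m,t) /
#' (p(m) p(t)))` is returned in nats. Constant features occupy a single bin
#' and score 0.
#'
#' @param x Numeric feature matrix.
#' @param y Binary label vector.
#' @param bins Histogram bin count (default 10, >= 2).
#' @return Nonnegative numeric vector of mutual informations (nats).
#' @export
mutual_info_scores <- function(x, y, bins = 10) {
  x <- as.matrix(x)
  if (bins < 2) abort("`bins` must be >= 2")
  if (length(unique(y)) < 2) abort("two classes required")
  n <- nrow(x)
  yf <- factor(y)
  apply_named(x, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(0)
    b <- pmin(pmax(floor((v - rng[1]) / diff(rng) * bins) + 1L, 1L), bins)
    joint <- table(factor(b, levels = seq_len(bins)), yf) / n
    pm <- rowSums(joint); pt <- colSums(joint)
    idx <- joint > 0
    sum(joint[idx] * log(joint[idx] / outer(pm, pt)[idx]))
  })
}

apply_named <- function(x, f) {
  stats::setNames(vapply(seq_len(ncol(x)), function(j) f(x[, j]),
                         numeric(1)),
                  colnames(x))
}

# min-max normalization to [0, 1]; a constant vector maps to all 0.5 so the
# rank-1 kernel never collapses to zero
minmax01 <- function(v) {
  rng <- range(v)
  if (!all(is.finite(rng))) abort("non-finite scores")
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Graph adjacency matrix from relevance scores and dispersions
#'
#' Builds `U = gamma * Theta + (1 - gamma) * rho`, where
#' `Theta = D_norm %*% t(R_norm)` is the rank-1 kernel of the min-max
#' normalized Fisher (`D`) and mutual-information (`R`) score vectors, and
#' `rho[i, j] = max(sigma_i, sigma_j)` is the pairwise dispersion matrix,
#' min-max rescaled into `[0, 1]` over its entries before mixing.
#'
#' @param d Fisher score vector (length M).
#' @param r Mutual-information score vector (length M).
#' @param sigmas Per-feature standard deviations (length M).
#' @param gamma Loading coefficient in `[0, 1]` (default 0.5): 1 uses the
#'   relevance kernel alone, 0 the dispersion matrix alone.
#' @return M x M numeric adjacency matrix.
#' @export
build_adjacency <- function(d, r, sigmas, gamma = 0.5) {
  m <- length(d)
  if (length(r) != m || length(sigmas) != m)
    abort("`d`, `r` and `sigmas` must have equal length")
  if (gamma < 0 || gamma > 1) abort("`gamma` must be in [0, 1]")
  theta <- outer(minmax01(d), minmax01(r))
  rho_raw <- outer(sigmas, sigmas, pmax)
  rng <- range(rho_raw)
  rho <- if (rng[1] == rng[2]) matrix(0.5, m, m) else
    (rho_raw - rng[1]) / (rng[2] - rng[1])
  gamma * theta + (1 - gamma) * rho
}

#' Feature weights from the principal eigenvector of the adjacency
#'
#' Eigendecomposes the symmetrized adjacency `(U + t(U)) / 2` and returns
#' the absolute principal eigenvector (the one whose eigenvalue has largest
#' magnitude), normalized to unit Euclidean norm. If several eigenvalues tie
#' at the maximum magnitude (within 1e-9 relative) the weights are the
#' square roots of the diagonal of the orthogonal projector onto the tied
#' eigenspace — basis-invariant, reducing to `|v0|` for a simple eigenvalue
#' and to the uniform `1/sqrt(M)` vector for `U = I`.
#'
#' @param u Square numeric adjacency matrix.
#' @return Nonnegative weight vector with unit Euclidean norm.
#' @export
principal_weights <- function(u) {
  u <- as.matrix(u)
  if (nrow(u) != ncol(u)) abort("`u` must be square")
  if (!all(is.finite(u))) abort("`u` must be finite")
  m <- nrow(u)
  if (m == 1) return(1)
  eg <- eigen((u + t(u)) / 2, symmetric = TRUE)
  mag <- abs(eg$values)
  top <- max(mag)
  tied <- which(mag >= top - 1e-9 * max(top, 1))
  if (length(tied) == 1) {
    w <- abs(eg$vectors[, tied])
  } else {
    v <- eg$vectors[, tied, drop = FALSE]
    w <- sqrt(rowSums(v^2))
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) rep(1 / sqrt(m), m) else w / nrm
}

#' Rank features by descending weight
#'
#' @param w Weight vector.
#' @param names Optional feature names carried into the result.
#' @return Integer permutation of `seq_along(w)` ordering weights
#'   descendingly; ties go to the lower original index.
#' @export
rank_features <- function(w, names = NULL) {
  ord <- order(-w, seq_along(w))
  if (!is.null(names)) attr(ord, "names_ranked") <- names[ord]
  ord
}

#' Subset a feature table to the top-k ranked features
#'
#' @param features Feature tibble (see [extract_features()]) or numeric
#'   matrix.
#' @param ranking Integer permutation from [rank_features()].
#' @param k Number of features to keep (default 16).
#' @return Same type as `features`, feature columns reordered and truncated
#'   to the top `k`; metadata/label columns are retained for tibbles.
#' @export
select_top_k <- function(features, ranking, k = 16) {
  m <- length(ranking)
  if (k < 1 || k > m) abort(sprintf("`k` must be in 1..%d", m))
  keep <- ranking[seq_len(k)]
  if (is.matrix(features)) return(features[, keep, drop = FALSE])
  fm <- feature_matrix(features)
  meta <- intersect(c("source_id", "frame", "start_index", "label"),
                    names(features))
  dplyr::bind_cols(features[, meta, drop = FALSE],
                   tibble::as_tibble(fm$x[, keep, drop = FALSE]))
}

#' Fit the GED feature-ranking on a labeled feature table
#'
#' Runs the full selection stage: Fisher scores, binned mutual information,
#' adjacency construction and principal-eigenvector weighting, returning a
#' fitted object that can score and subset new data without looking at its
#' labels.
#'
#' @param features Labeled feature tibble from [extract_features()].
#' @param k Number of features to select (default 16).
#' @param gamma Adjacency loading coefficient (default 0.5).
#' @param mi_bins Mutual-information histogram bins (default 10).
#' @param eps Fisher variance guard (default 1e-12).
#' @return An object of class `ged_fit` with elements `fisher`, `mi`,
#'   `fisher_norm`, `mi_norm`, `theta`, `rho`, `gamma`, `adjacency`,
#'   `weights`, `ranking`, `selected` (names) and `k`. Methods: [tidy()],
#'   [glance()], [autoplot()], [predict()][predict.ged_fit()].
#' @examples
#' feats <- extract_features(gen_dataset(12, seed = 1), levels = 2)
#' fit <- ged_select(feats, k = 5)
#' tidy(fit)
#' @export
ged_select <- function(features, k = 16, gamma = 0.5, mi_bins = 10,
                       eps = 1e-12) {
  fm <- feature_matrix(features)
  if (anyNA(fm$label)) abort("labeled features required")
  m <- ncol(fm$x)
  if (k < 1 || k > m) abort(sprintf("`k` must be in 1..%d", m))
  d <- fisher_scores(fm$x, fm$label, eps = eps)
  r <- mutual_info_scores(fm$x, fm$label, bins = mi_bins)
  sigmas <- sqrt(pmax(colMeans(fm$x^2) - colMeans(fm$x)^2, 0))
  theta <- outer(minmax01(d), minmax01(r))
  rho_raw <- outer(sigmas, sigmas, pmax)
  rng <- range(rho_raw)
  rho <- if (rng[1] == rng[2]) matrix(0.5, m, m) else
    (rho_raw - rng[1]) / (rng[2] - rng[1])
  u <- gamma * theta + (1 - gamma) * rho
  w <- stats::setNames(principal_weights(u), colnames(fm$x))
  ranking <- rank_features(w)
  structure(
    list(fisher = d, mi = r,
         fisher_norm = minmax01(d), mi_norm = minmax01(r),
         theta = theta, rho = rho,
         gamma = gamma, adjacency = u,
         weights = w, ranking = as.integer(ranking),
         selected = colnames(fm$x)[ranking[seq_len(k)]], k = as.integer(k),
         mi_bins = as.integer(mi_bins)),
    class = "ged_fit"
  )
}

#' @export
print.ged_fit <- function(x, ...) {
  cat(sprintf("<ged_fit> %d features, gamma = %.2f, top %d selected:\n",
              length(x$weights), x$gamma, x$k))
  cat(" ", paste(utils::head(x$selected, 8), collapse = ", "),
      if (x$k > 8) "..." else "", "\n")
  invisible(x)
}

#' Apply a fitted GED selection to (possibly unlabeled) data
#'
#' Subsets the feature columns of `newdata` to the fitted top-k set; labels
#' and other metadata pass through untouched, so held-out rows are never
#' consulted during selection.
#'
#' @param object A `ged_fit`.
#' @param newdata Feature tibble or matrix with the same feature columns.
#' @param ... Unused.
#' @return `newdata` restricted to the selected features.
#' @export
predict.ged_fit <- function(object, newdata, ...) {
  select_top_k(newdata, object$ranking, object$k)
}

#' @export
tidy.ged_fit <- function(x, ...) {
  ord <- x$ranking
  tibble::tibble(
    feature = names(x$weights),
    fisher = unname(x$fisher),
    mi = unname(x$mi),
    weight = unname(x$weights),
    rank = match(seq_along(ord), ord),
    selected = seq_along(ord) %in% ord[seq_len(x$k)]
  )
}

#' @export
glance.ged_fit <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights), k = x$k, gamma = x$gamma,
                 mi_bins = x$mi_bins,
                 top_feature = x$selected[1],
                 top_weight = max(x$weights))
}

#' @export
autoplot.ged_fit <- function(object, ...) {
  td <- tidy(object)
  td$feature <- factor(td$feature, levels = td$feature)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$feature, y = .data$weight,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "GED weight",
                  title = "Feature weights (absolute principal eigenvector)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
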