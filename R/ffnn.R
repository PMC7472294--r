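# Single-hidden-layer feedforward network: tanh hidden units, 2-unit
# softmax output, cross-entropy loss, trained by deterministic BFGS with
# analytic gradients and seeded initialisation.

#' Feedforward network configuration
#'
#' @param n_hidden Hidden-layer width (default 10).
#' @param max_iters Optimizer iteration cap (default 500).
#' @param reltol Convergence tolerance on the loss (default 1e-10).
#' @param decay L2 weight decay, stabilises the separable case
#'   (default 1e-4).
#' @param seed Integer seed for weight initialisation.
#' @return A named list of class `ffnn_config`.
#' @export
ffnn_config <- function(n_hidden = 10, max_iters = 500, reltol = 1e-10,
                        decay = 1e-4, seed = 1L) {
  stopifnot(n_hidden >= 1, max_iters >= 1, decay >= 0)
  structure(list(n_hidden = as.integer(n_hidden),
                 max_iters = as.integer(max_iters),
                 reltol = reltol, decay = decay, seed = as.integer(seed),
                 optimizer = "BFGS"),
            class = "ffnn_config")
}

# parameter vector <-> weight matrices
.ffnn_unpack <- function(theta, p, h) {
  i1 <- p * h
  list(w1 = matrix(theta[seq_len(i1)], p, h),
       b1 = theta[i1 + seq_len(h)],
       w2 = matrix(theta[i1 + h + seq_len(h * 2)], h, 2),
       b2 = theta[i1 + h + h * 2 + seq_len(2)])
}

.ffnn_forward <- function(x, par) {
  hid <- tanh(sweep(x %*% par$w1, 2, par$b1, "+"))
  z <- sweep(hid %*% par$w2, 2, par$b2, "+")
  zmax <- pmax(z[, 1], z[, 2])
  ez <- exp(z - zmax)
  list(hid = hid, prob = ez / rowSums(ez))
}

#' Train the feedforward seizure classifier
#'
#' Fits a single-hidden-layer network (tanh hidden activation, softmax
#' output over the two classes, targets one-hot encoded from the 0/1
#' labels) by BFGS on the mean cross-entropy with a small L2 penalty.
#' Training is deterministic given `cfg$seed`.
#'
#' @param x Numeric matrix of predictors (rows = frames).
#' @param y Binary labels (0 = non-seizure, 1 = seizure); both classes must
#'   be present.
#' @param cfg An [ffnn_config()].
#' @return An object of class `ffnn` holding the fitted weights, the
#'   training loss trace endpoint and the column names seen at fit time.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(0:1, each = 30)
#' fit <- train_ffnn(x, y, ffnn_config(n_hidden = 4))
#' mean(predict(fit, x)$label == y)
#' @export
train_ffnn <- function(x, y, cfg = ffnn_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("two classes required for training")
  if (nrow(x) != length(y)) abort("`x` rows and `y` length differ")
  if (!all(is.finite(x))) abort("non-finite predictors")
  p <- ncol(x); h <- cfg$n_hidden; n <- nrow(x)
  tgt <- cbind(1 - y, y)  # columns: class 0, class 1
  npar <- p * h + h + h * 2 + 2
  theta0 <- withr_seed(cfg$seed, stats::runif(npar, -0.5, 0.5) /
                         sqrt(max(p, 1)))
  loss <- function(theta) {
    par <- .ffnn_unpack(theta, p, h)
    pr <- .ffnn_forward(x, par)$prob
    -sum(tgt * log(pmax(pr, 1e-300))) / n +
      cfg$decay * sum(theta^2) / 2
  }
  grad <- function(theta) {
    par <- .ffnn_unpack(theta, p, h)
    fw <- .ffnn_forward(x, par)
    dz2 <- (fw$prob - tgt) / n
    gw2 <- crossprod(fw$hid, dz2)
    gb2 <- colSums(dz2)
    dhid <- (dz2 %*% t(par$w2)) * (1 - fw$hid^2)
    gw1 <- crossprod(x, dhid)
    gb1 <- colSums(dhid)
    c(as.vector(gw1), gb1, as.vector(gw2), gb2) + cfg$decay * theta
  }
  opt <- stats::optim(theta0, loss, grad, method = "BFGS",
                      control = list(maxit = cfg$max_iters,
                                     reltol = cfg$reltol))
  structure(
    list(par = .ffnn_unpack(opt$par, p, h), cfg = cfg,
         loss = opt$value, converged = opt$convergence == 0,
         feature_names = colnames(x)),
    class = "ffnn"
  )
}

# evaluate expr with a local RNG seed, restoring global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Predict classes and class probabilities
#'
#' @param object A fitted `ffnn`.
#' @param newdata Numeric matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return A tibble with `p0`, `p1` (softmax probabilities, summing to 1)
#'   and `label` (argmax; exact 0.5 ties go to class 0).
#' @export
predict.ffnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$par$w1))
    abort("`newdata` column count differs from the training matrix")
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    abort("`newdata` columns differ from the training columns")
  if (nrow(newdata) == 0)
    return(tibble::tibble(p0 = numeric(), p1 = numeric(),
                          label = integer()))
  pr <- .ffnn_forward(newdata, object$par)$prob
  tibble::tibble(p0 = pr[, 1], p1 = pr[, 2],
                 label = as.integer(pr[, 2] > 0.5))
}

#' @export
print.ffnn <- function(x, ...) {
  cat(sprintf("<ffnn> %d-%d-2 (tanh/softmax), final loss %.4g%s\n",
              nrow(x$par$w1), ncol(x$par$w1), x$loss,
              if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

#' Pluggable classifier interface
#'
#' The cross-validation driver accepts any classifier expressed as a pair
#' of closures, enabling external models (SVM, LDA, ...) to be evaluated in
#' the identical pipeline without being implemented here. `ffnn_classifier()`
#' wraps the package's own network in that interface.
#'
#' @param fit `function(x, y, seed)` returning a model object.
#' @param predict `function(model, x)` returning an integer 0/1 label
#'   vector (or a data frame with a `label` column).
#' @param label Display name for logs and results.
#' @return A list of class `epiged_classifier`.
#' @export
classifier_hook <- function(fit, predict, label = "custom") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, label = label),
            class = "epiged_classifier")
}

#' @rdname classifier_hook
#' @param n_hidden,decay,max_iters Passed to [ffnn_config()].
#' @export
ffnn_classifier <- function(n_hidden = 10, decay = 1e-4, max_iters = 500) {
  classifier_hook(
    fit = function(x, y, seed)
      train_ffnn(x, y, ffnn_config(n_hidden = n_hidden, decay = decay,
                                   max_iters = max_iters, seed = seed)),
    predict = function(model, x) predict(model, x)$label,
    label = sprintf("ffnn-%d", n_hidden)
  )
}
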