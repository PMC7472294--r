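test_that("standardization is fitted on training rows only", {
  withr::with_seed(14, {
    tr <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
    std <- standardize(tr)
    expect_equal(colMeans(std$x), rep(0, 4), tolerance = 1e-12)
    expect_equal(apply(std$x, 2, sd), rep(1, 4), tolerance = 1e-12)
    # constant column: centered zeros, no NaN
    tr2 <- cbind(tr, konst = rep(7, 50))
    std2 <- standardize(tr2)
    expect_true(all(std2$x[, 5] == 0))
    # applying to new data uses the fitted statistics
    new <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4)
    out <- standardize(tr, new)
    expect_equal(out$x, sweep(sweep(new, 2, std$center), 2, std$scale, "/"))
    expect_error(standardize(tr, new[, 1:2]), "column mismatch")
  })
})

test_that("the network separates Gaussian blobs and learns XOR", {
  withr::with_seed(100, {
    x <- rbind(matrix(rnorm(200), 100, 2),
               matrix(rnorm(200, mean = 3), 100, 2))
    y <- rep(c(0L, 1L), each = 100)
  })
  fit <- train_ffnn(x, y, ffnn_config(n_hidden = 10, seed = 5))
  pred <- predict(fit, x)
  expect_gte(mean(pred$label == y), 0.99)

  withr::with_seed(101, {
    centers <- rbind(c(0, 0), c(3, 3), c(0, 3), c(3, 0))
    idx <- rep(1:4, each = 50)
    xx <- centers[idx, ] + matrix(rnorm(400, sd = 0.5), 200, 2)
    yy <- as.integer(idx >= 3)   # XOR arrangement
  })
  fit2 <- train_ffnn(xx, yy, ffnn_config(n_hidden = 10, seed = 5))
  expect_gte(mean(predict(fit2, xx)$label == yy), 0.95)
})

test_that("training is deterministic and softmax probabilities are proper", {
  withr::with_seed(102, {
    x <- matrix(rnorm(120), 60, 2)
    y <- rep(c(0L, 1L), 30)
  })
  f1 <- train_ffnn(x, y, ffnn_config(n_hidden = 4, seed = 9))
  f2 <- train_ffnn(x, y, ffnn_config(n_hidden = 4, seed = 9))
  expect_identical(predict(f1, x), predict(f2, x))
  pr <- predict(f1, x)
  expect_true(all(pr$p0 >= 0 & pr$p0 <= 1))
  expect_equal(pr$p0 + pr$p1, rep(1, 60), tolerance = 1e-12)
  expect_equal(pr$label, as.integer(pr$p1 > 0.5))
  # contracts: empty input, column mismatch, single-class training
  empty <- predict(f1, x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_error(predict(f1, x[, 1, drop = FALSE]), "column")
  expect_error(train_ffnn(x, rep(1L, 60)), "two classes")
})

test_that("an independent logistic-hidden network agrees on separable data", {
  skip_if_not_installed("nnet")
  withr::with_seed(103, {
    x <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 3), 50, 2))
    y <- rep(c(0L, 1L), each = 50)
  })
  ours <- train_ffnn(x, y, ffnn_config(n_hidden = 5, seed = 2))
  ref <- withr::with_seed(2, nnet::nnet(x, cbind(1 - y, y), size = 5,
                                        softmax = TRUE, trace = FALSE))
  ref_lab <- max.col(predict(ref, x)) - 1L
  expect_gte(mean(predict(ours, x)$label == y), 0.99)
  expect_gte(mean(ref_lab == y), 0.99)
  expect_gte(mean(predict(ours, x)$label == ref_lab), 0.98)
})

test_that("confusion metrics follow the printed formulas exactly", {
  m <- compute_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                       c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(m$tp, 3); expect_equal(m$tn, 5)
  expect_equal(m$fp, 1); expect_equal(m$fn, 1)
  expect_equal(m$acc, 80)
  expect_equal(m$sen, 75)
  expect_equal(m$spe, 100 * 5 / 6)
  perfect <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(c(perfect$acc, perfect$sen, perfect$spe), c(100, 100, 100))
  inverted <- compute_metrics(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(c(inverted$acc, inverted$sen, inverted$spe), c(0, 0, 0))
  expect_error(compute_metrics(c(0, 1), c(1)), "length")
  # identities over random confusion tables; empty denominators -> 0
  withr::with_seed(104, {
    for (i in 1:25) {
      y <- rbinom(30, 1, runif(1, 0.1, 0.9))
      p <- rbinom(30, 1, runif(1, 0.1, 0.9))
      m <- compute_metrics(y, p)
      expect_equal(m$tp + m$tn + m$fp + m$fn, 30)
      expect_equal(m$acc, 100 * (m$tp + m$tn) / 30)
      expect_equal(m$sen,
                   if (m$tp + m$fn == 0) 0 else 100 * m$tp / (m$tp + m$fn))
      expect_equal(m$spe,
                   if (m$tn + m$fp == 0) 0 else 100 * m$tn / (m$tn + m$fp))
    }
  })
})

test_that("stratified folds balance classes and respect feasibility", {
  y <- rep(c(0L, 1L), each = 5)
  fold <- stratified_folds(y, k = 2, seed = 3)
  expect_equal(as.integer(table(fold)), c(5L, 5L))
  for (f in 1:2)
    expect_true(sum(y[fold == f] == 1) %in% 2:3)
  expect_error(stratified_folds(c(0L, 1L), k = 3), "stratification")
})

test_that("K-fold evaluation splits 800 frames into 640 train / 160 test", {
  tbl <- planted_features(400, 42, informative = c(1, 8, 15, 22, 29),
                          shift = 2, seed = 17)
  res <- kfold_evaluate(tbl, k_features = 16, folds = 5, seed = 17)
  expect_equal(res$per_fold$n_train, rep(640L, 5))
  expect_equal(res$per_fold$n_validate, rep(160L, 5))
  expect_equal(res$mean_acc, mean(res$per_fold$acc))
  expect_equal(res$mean_sen, mean(res$per_fold$sen))
  expect_gte(res$mean_acc, 95)   # 2-SD planted signal is separable
  expect_length(res$selected, 5)
  gl <- glance(res)
  expect_equal(gl$mean_acc, res$mean_acc)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("per-fold pipelines are leakage-free and reproducible", {
  tbl <- planted_features(50, 10, informative = c(2, 7), shift = 2,
                          seed = 23)
  r1 <- kfold_evaluate(tbl, k_features = 4, folds = 5, seed = 11)
  r2 <- kfold_evaluate(tbl, k_features = 4, folds = 5, seed = 11)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(cv_result_json(r1), cv_result_json(r2))
  # shuffling held-out labels cannot change what was selected per fold
  fold <- stratified_folds(tbl$label, k = 5, seed = 11)
  shuffled <- tbl
  out <- fold == 1
  shuffled$label[out] <- withr::with_seed(9, sample(shuffled$label[out]))
  fit_a <- ged_select(tbl[!out, ], k = 4)
  fit_b <- ged_select(shuffled[!out, ], k = 4)
  expect_identical(fit_a$selected, fit_b$selected)
})

test_that("a pluggable classifier drops into the CV driver", {
  tbl <- planted_features(30, 8, informative = 1, shift = 3, seed = 31)
  centroid <- classifier_hook(
    fit = function(x, y, seed) {
      list(c0 = colMeans(x[y == 0, , drop = FALSE]),
           c1 = colMeans(x[y == 1, , drop = FALSE]))
    },
    predict = function(model, x) {
      d0 <- rowSums(sweep(x, 2, model$c0)^2)
      d1 <- rowSums(sweep(x, 2, model$c1)^2)
      as.integer(d1 < d0)
    },
    label = "nearest-centroid"
  )
  res <- kfold_evaluate(tbl, k_features = 3, folds = 3,
                        classifier = centroid, seed = 2)
  expect_equal(res$config$classifier, "nearest-centroid")
  expect_gte(res$mean_acc, 90)
})
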