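test_that("Fisher scores follow the two-class criterion", {
  # population moments: class 1 mean 0 / var 1, class 2 mean 2 / var 1
  x <- cbind(f1 = c(-1, 1, 1, 3), f2 = c(5, 5, 5, 5))
  y <- c(0, 0, 1, 1)
  d <- fisher_scores(x, y)
  expect_equal(unname(d["f1"]), 4 / 2, tolerance = 1e-9)
  expect_equal(unname(d["f2"]), 0)     # identical class moments
  expect_true(all(d >= 0))
  expect_error(fisher_scores(x, c(1, 1, 1, 1)), "two classes")
  # monotone in mean separation at fixed variances
  base <- c(-1, 1); scores <- vapply(c(1, 2, 4), function(mu)
    fisher_scores(cbind(v = c(base, base + mu)), c(0, 0, 1, 1))[["v"]],
    1)
  expect_true(all(diff(scores) > 0))
})

test_that("mutual information matches analytic cases and bounds", {
  # binary feature identical to a balanced label: joint [[.5,0],[0,.5]]
  y <- rep(c(0L, 1L), each = 100)
  x <- cbind(ident = as.numeric(y))
  expect_equal(unname(mutual_info_scores(x, y, bins = 10)["ident"]),
               log(2), tolerance = 1e-12)
  # independence: a label-shuffled feature carries ~0 information
  withr::with_seed(21, {
    v <- rnorm(400)
    yy <- sample(rep(c(0L, 1L), each = 200))
    r <- mutual_info_scores(cbind(v = v), yy, bins = 10)
    expect_lt(r[["v"]], 0.05)
    # bound: R <= min(H(bins), H(label))
    b <- cut(v, breaks = seq(min(v), max(v), length.out = 11),
             include.lowest = TRUE)
    h_feat <- -sum(prop.table(table(b)) * log(prop.table(table(b))))
    expect_lte(r[["v"]], min(h_feat, log(2)) + 1e-12)
  })
  expect_equal(unname(mutual_info_scores(cbind(k = rep(1, 10)),
                                         rep(c(0L, 1L), 5))["k"]), 0)
})

test_that("adjacency mixes the rank-1 kernel and dispersion as stated", {
  d <- c(0.2, 0.9); r <- c(0.7, 0.1); s <- c(1, 2)
  expect_equal(build_adjacency(d, r, s, gamma = 1),
               outer(c(0, 1), c(1, 0)))          # U = Theta
  rho <- (outer(s, s, pmax) - 1) / 1             # [[0,1],[1,1]]
  expect_equal(build_adjacency(d, r, s, gamma = 0), rho)  # U = rho
  # hand-computed 2x2 mix at gamma = 0.5
  u <- build_adjacency(d, r, s, gamma = 0.5)
  expect_equal(u, 0.5 * rbind(c(0, 0), c(1, 0)) +
                 0.5 * rbind(c(0, 1), c(1, 1)))
  expect_error(build_adjacency(d, r, c(1, 2, 3), 0.5), "equal length")
  expect_error(build_adjacency(d, r, s, gamma = 2), "gamma")
  # constant score vectors normalize to all 0.5, not a zero kernel
  expect_equal(build_adjacency(c(1, 1), c(1, 1), s, gamma = 1),
               matrix(0.25, 2, 2))
})

test_that("principal weights match a power-iteration oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- matrix(rnorm(100), 10, 10)
      u <- (a + t(a)) / 2 + diag(10) * 2   # symmetric, spectral gap likely
      w <- principal_weights(u)
      expect_equal(w, oracle_principal(u), tolerance = 1e-8)
      expect_true(all(w >= 0))
      expect_equal(sum(w^2), 1, tolerance = 1e-12)
    }
    # asymmetric input: weights are those of the symmetrized matrix
    a <- matrix(runif(25), 5, 5)
    expect_equal(principal_weights(a), oracle_principal(a),
                 tolerance = 1e-8)
  })
  # fully degenerate spectrum: uniform weights
  expect_equal(principal_weights(diag(4)), rep(0.5, 4))
  expect_equal(principal_weights(matrix(3, 1, 1)), 1)
})

test_that("ranking and top-k selection respect weights and tie rules", {
  expect_equal(rank_features(c(0.1, 0.9, 0.3))[1:3], c(2L, 3L, 1L))
  expect_equal(rank_features(rep(0.5, 4))[1:4], 1:4)   # ties -> low index
  x <- planted_features(10, 6, informative = 2, seed = 1)
  rk <- rank_features(c(0.3, 0.9, 0.1, 0.5, 0.2, 0.4))
  top <- select_top_k(x, rk, k = 2)
  expect_equal(setdiff(names(top), c("source_id", "frame", "label")),
               c("f02", "f04"))
  all_cols <- select_top_k(x, rk, k = 6)
  expect_equal(ncol(all_cols), ncol(x))
  expect_error(select_top_k(x, rk, k = 0), "k")
  expect_error(select_top_k(x, rk, k = 7), "k")
})

test_that("planted informative features rise to the top of the ranking", {
  informative <- c(3, 11, 19, 27, 40)
  hits <- vapply(1:20, function(seed) {
    tbl <- planted_features(200, 42, informative, shift = 2, seed = seed)
    fit <- ged_select(tbl, k = 8)
    top8 <- fit$ranking[1:8]
    all(informative %in% top8)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # and they always beat the median rank
  tbl <- planted_features(200, 42, informative, shift = 2, seed = 99)
  fit <- ged_select(tbl, k = 8)
  ranks <- match(informative, fit$ranking)
  expect_true(all(ranks <= 21))
})

test_that("weights stay finite and unit-norm across the gamma grid", {
  tbl <- planted_features(50, 12, informative = c(1, 5), seed = 4)
  for (g in c(0, 0.25, 0.5, 0.75, 1)) {
    fit <- ged_select(tbl, k = 4, gamma = g)
    expect_true(all(is.finite(fit$weights)))
    expect_equal(sum(fit$weights^2), 1, tolerance = 1e-10)
    expect_equal(fit$adjacency,
                 g * fit$theta + (1 - g) * fit$rho, tolerance = 1e-12)
  }
})

test_that("applying a fitted ranking never consults held-out labels", {
  tbl <- planted_features(100, 20, informative = c(2, 9), seed = 8)
  fit <- ged_select(tbl, k = 5)
  heldout <- planted_features(30, 20, informative = c(2, 9), seed = 80)
  shuffled <- heldout
  shuffled$label <- withr::with_seed(1, sample(shuffled$label))
  a <- predict(fit, heldout)
  b <- predict(fit, shuffled)
  feat_cols <- setdiff(names(a), c("source_id", "frame", "label"))
  expect_identical(a[feat_cols], b[feat_cols])
  expect_identical(names(a), names(b))
})

test_that("ged_fit tidiers expose scores, weights and the selection", {
  tbl <- planted_features(40, 10, informative = 3, seed = 6)
  fit <- ged_select(tbl, k = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_equal(sum(td$selected), 4)
  expect_equal(td$feature[td$rank == 1], fit$selected[1])
  gl <- glance(fit)
  expect_equal(gl$k, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
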