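test_that("SODP pairs are the lag-aligned successive increments", {
  p <- sodp_pairs(c(0, 1, 3, 6))
  expect_equal(p$y1, c(1, 2))
  expect_equal(p$y2, c(2, 3))
  expect_equal(nrow(sodp_pairs(c(5, 1, 9))), 1)   # length 3 -> one pair
  pc <- sodp_pairs(rep(2, 10))
  expect_true(all(pc$y1 == 0) && all(pc$y2 == 0))
  expect_error(sodp_pairs(c(1, 2)), "at least 3")
  # y2 is y1 shifted by one sample
  x <- rnorm(20)
  p <- sodp_pairs(x)
  expect_equal(p$y2[-nrow(p)], p$y1[-1])
})

test_that("all seven features match their brute-force oracles", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- rnorm(50, sd = runif(1, 0.5, 5))
      expect_equal(ellipse_area(x), oracle_ellipse_area(x),
                   tolerance = 1e-10)
      expect_equal(squared_cv_abs(x), oracle_vsc(x), tolerance = 1e-10)
      expect_equal(fluctuation_index(x), oracle_fi(x), tolerance = 1e-10)
      expect_equal(permutation_entropy(x), oracle_pe(x), tolerance = 1e-10)
      expect_equal(approximate_entropy(x), oracle_apen(x),
                   tolerance = 1e-10)
      expect_equal(renyi_entropy(x), oracle_renyi(x), tolerance = 1e-8)
      expect_equal(phase_entropy(x), oracle_phase(x), tolerance = 1e-8)
    }
  })
})

test_that("spike features vanish on constant input and scale homogeneously", {
  const <- rep(4.2, 40)
  expect_equal(ellipse_area(const), 0)
  expect_equal(squared_cv_abs(const), 0)   # sigma = 0
  expect_equal(fluctuation_index(const), 0)
  expect_equal(approximate_entropy(const), 0)

  withr::with_seed(11, {
    x <- rnorm(60)
    for (c_ in c(0.5, 3, 17)) {
      expect_equal(ellipse_area(c_ * x), c_^2 * ellipse_area(x),
                   tolerance = 1e-10)
      expect_equal(fluctuation_index(c_ * x), c_ * fluctuation_index(x),
                   tolerance = 1e-12)
      expect_equal(squared_cv_abs(c_ * x), squared_cv_abs(x),
                   tolerance = 1e-12)
      expect_equal(permutation_entropy(c_ * x), permutation_entropy(x))
      # apE tolerance scales with sd, so it is scale invariant too
      expect_equal(approximate_entropy(c_ * x), approximate_entropy(x),
                   tolerance = 1e-10)
    }
  })
})

test_that("closed-form feature values hold for structured inputs", {
  # alternating +1/-1: mean |x| = 1, mean 0, variance 1
  expect_equal(squared_cv_abs(rep(c(1, -1), 25)), 1)
  # alternating +a/-a: every increment has magnitude 2a
  expect_equal(fluctuation_index(rep(c(2, -2), 30)), 4)
  # linear ramp with step s
  expect_equal(fluctuation_index(seq(0, 9.8, by = 0.7)), 0.7)
})

test_that("permutation entropy spans [0, log(embed!)] with stable ties", {
  expect_equal(permutation_entropy(1:50), 0)            # monotone
  expect_equal(permutation_entropy(50:1), 0)
  # cyclic base whose 60 sliding windows hit each of the 6 ordinal
  # patterns exactly 10 times
  base <- c(4, 5, 8, 1, 0, 9)
  x <- c(rep(base, 10), base[1:2])
  counts <- oracle_pattern_counts(x)
  expect_length(counts, 6)
  expect_true(all(counts == 10))
  expect_equal(permutation_entropy(x), log(6), tolerance = 1e-12)
  # entropy maximum and tie handling
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- sample(0:3, 40, replace = TRUE)  # many ties
      expect_lte(permutation_entropy(x), log(6) + 1e-12)
      expect_equal(permutation_entropy(x), oracle_pe(x), tolerance = 1e-12)
    }
  })
  expect_equal(permutation_entropy(rep(1, 30)), 0)  # all ties, one pattern
})

test_that("approximate entropy separates periodic from irregular series", {
  x_per <- rep(c(0, 1), 32)
  x_rnd <- withr::with_seed(5, runif(64))
  expect_equal(approximate_entropy(x_per), oracle_apen(x_per),
               tolerance = 1e-10)
  expect_equal(approximate_entropy(x_rnd), oracle_apen(x_rnd),
               tolerance = 1e-10)
  expect_lt(approximate_entropy(x_per), approximate_entropy(x_rnd))
  # the worked repeating-pattern example agrees with the oracle
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  expect_equal(approximate_entropy(x), oracle_apen(x), tolerance = 1e-10)
})

test_that("Renyi entropy attains its analytic extremes", {
  # unit impulse: |X(f)| identical in every bin -> flat spectrum
  imp <- c(1, rep(0, 255))
  expect_equal(renyi_entropy(imp), log(128), tolerance = 1e-10)
  # integer-cycle sinusoid concentrates in one bin
  x <- sin(2 * pi * 8 * (0:255) / 256)
  expect_lt(renyi_entropy(x), 0.05)
  # order-2 specialization: enE = -log sum p^2
  y <- withr::with_seed(2, rnorm(64))
  pw <- (Mod(fft(y))^2)[2:33]
  expect_equal(renyi_entropy(y), -log(sum((pw / sum(pw))^2)),
               tolerance = 1e-12)
  expect_equal(renyi_entropy(rep(0, 64)), 0)
  expect_error(renyi_entropy(rnorm(64), order = 1), "order")
})

test_that("phase entropy: uniform bound, coupling concentration, zero floor", {
  # impulse: all admissible bispectrum cells equal -> log(#cells)
  imp <- c(1, rep(0, 63))
  f <- 32
  expect_equal(phase_entropy(imp), log(f * (f - 1) / 2), tolerance = 1e-10)
  # quadratic phase coupling (5 + 9 -> 14 cycles) concentrates the mass
  n <- 64
  x <- cos(2 * pi * 5 * (0:(n - 1)) / n) +
    cos(2 * pi * 9 * (0:(n - 1)) / n) +
    cos(2 * pi * 14 * (0:(n - 1)) / n)
  expect_lt(phase_entropy(x), 0.5 * log(f * (f - 1) / 2))
  expect_equal(phase_entropy(x), oracle_phase(x), tolerance = 1e-8)
  expect_gte(phase_entropy(rnorm(64)), 0)
  expect_equal(phase_entropy(rep(0, 64)), 0)
})

test_that("the feature vector is the ordered composition of the features", {
  withr::with_seed(9, {
    x <- rnorm(256)
    sb <- dwt_decompose(x, levels = 4)
    fv <- extract_feature_vector(sb)
    expect_length(fv, 42)
    expect_equal(names(fv)[1:7],
                 paste0("Sb1:", c("Ae", "Vsc", "Fi", "pE", "apE", "enE",
                                  "phE")))
    expect_equal(names(fv)[36:42],
                 paste0("S:", c("Ae", "Vsc", "Fi", "pE", "apE", "enE",
                                "phE")))
    # compositional consistency with the individual operations
    expect_equal(fv[["Sb3:Ae"]], ellipse_area(sb$signals$Sb3))
    expect_equal(fv[["S:pE"]], permutation_entropy(x))
    expect_equal(fv[["Sb1:enE"]], renyi_entropy(sb$signals$Sb1))
    expect_equal(fv[["Sb5:apE"]], approximate_entropy(sb$signals$Sb5))
  })
  # degenerate frame: finite defaults, spike features 0
  fz <- extract_feature_vector(dwt_decompose(rep(0, 256), levels = 4))
  expect_true(all(is.finite(fz)))
  expect_true(all(fz[grep(":(Ae|Vsc|Fi)$", names(fz))] == 0))
})

test_that("feature tables stack frames with labels and finite entries", {
  frames <- gen_dataset(3, fast_synth(), seed = 2)
  feats <- extract_features(frames, levels = 2)
  expect_equal(dim(feats), c(6, 3 + 4 * 7))
  expect_true(all(vapply(feature_matrix(feats)$x, is.finite, TRUE)))
  expect_setequal(feats$label, c(0L, 1L))
})
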