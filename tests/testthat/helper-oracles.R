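# Independent brute-force oracles: literal, loop-based transcriptions of the
# feature and selection definitions, kept deliberately naive and separate
# from the package implementations they check.

oracle_ellipse_area <- function(x) {
  n <- length(x)
  y1 <- numeric(n - 2); y2 <- numeric(n - 2)
  for (k in 1:(n - 2)) {
    y1[k] <- x[k + 1] - x[k]
    y2[k] <- x[k + 2] - x[k + 1]
  }
  k1sq <- 0; k2sq <- 0; k12 <- 0
  for (k in 1:(n - 2)) {
    k1sq <- k1sq + y1[k]^2 / (n - 1)
    k2sq <- k2sq + y2[k]^2 / (n - 1)
    k12 <- k12 + y1[k] * y2[k] / (n - 1)
  }
  delta <- sqrt(max((k1sq + k2sq)^2 - 4 * (k1sq * k2sq - k12^2), 0))
  alpha <- sqrt(3 * (k1sq + k2sq + delta))
  beta <- sqrt(3 * max(k1sq + k2sq - delta, 0))
  pi * alpha * beta
}

oracle_vsc <- function(x) {
  n <- length(x)
  mu <- sum(abs(x)) / n
  if (mu == 0) return(0)
  xb <- sum(x) / n
  sigma2 <- sum((x - xb)^2) / n
  sigma2 / mu^2
}

oracle_fi <- function(x) {
  n <- length(x)
  s <- 0
  for (k in 1:(n - 1)) s <- s + abs(x[k + 1] - x[k])
  s / (n - 1)
}

# ordinal pattern of one window, ties by temporal order (stable sort)
oracle_pattern <- function(w) paste(order(w), collapse = "")

oracle_pe <- function(x, embed = 3, lag = 1) {
  n <- length(x)
  nw <- n - (embed - 1) * lag
  pats <- character(nw)
  for (k in 1:nw) {
    w <- x[k + (0:(embed - 1)) * lag]
    pats[k] <- oracle_pattern(w)
  }
  p <- table(pats) / nw
  -sum(p * log(p))
}

oracle_pattern_counts <- function(x, embed = 3, lag = 1) {
  n <- length(x)
  nw <- n - (embed - 1) * lag
  pats <- vapply(1:nw, function(k)
    oracle_pattern(x[k + (0:(embed - 1)) * lag]), character(1))
  table(pats)
}

oracle_apen <- function(x, m = 2, tol_factor = 0.2) {
  n <- length(x)
  r <- tol_factor * sqrt(mean((x - mean(x))^2))
  phi <- function(dim) {
    nv <- n - dim + 1
    acc <- 0
    for (k in 1:nv) {
      cnt <- 0
      for (j in 1:nv) {
        d <- max(abs(x[k + 0:(dim - 1)] - x[j + 0:(dim - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / nv)
    }
    acc / nv
  }
  phi(m) - phi(m + 1)
}

# naive DFT, independent of stats::fft
oracle_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(f)
    sum(x * exp(-2i * pi * f * (0:(n - 1)) / n)), complex(1))
}

oracle_renyi <- function(x, order = 2) {
  n <- length(x)
  f <- floor(n / 2)
  X <- oracle_dft(x)
  pw <- Mod(X[2:(f + 1)])^2
  if (sum(pw) == 0) return(0)
  p <- pw / sum(pw)
  log(sum(p^order)) / (1 - order)
}

oracle_phase <- function(x) {
  n <- length(x)
  f <- floor(n / 2)
  X <- oracle_dft(x)
  b <- matrix(0, f, f)
  for (f1 in 1:f) for (f2 in 1:f) {
    if (f1 + f2 <= f)
      b[f1, f2] <- Mod(X[f1 + 1] * X[f2 + 1] * Conj(X[f1 + f2 + 1]))^2
  }
  tot <- sum(b)
  if (tot == 0) return(0)
  p <- b[b > 0] / tot
  -sum(p * log(p))
}

oracle_features <- function(x) {
  c(Ae = oracle_ellipse_area(x), Vsc = oracle_vsc(x), Fi = oracle_fi(x),
    pE = oracle_pe(x), apE = oracle_apen(x), enE = oracle_renyi(x),
    phE = oracle_phase(x))
}

# power iteration on the symmetrized matrix: converges to the eigenvector of
# the largest-magnitude eigenvalue (independent of eigen())
oracle_principal <- function(u, iters = 10000) {
  s <- (u + t(u)) / 2
  v <- rep(1, nrow(s)) / sqrt(nrow(s))
  for (i in seq_len(iters)) {
    w <- s %*% v
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(abs(v))
    w <- w / nrm
    if (max(abs(abs(w) - abs(v))) < 1e-14) { v <- w; break }
    v <- w
  }
  a <- abs(as.vector(v))
  a / sqrt(sum(a^2))
}

# FFT band-energy oracle: fraction of spectral power of `x` inside [lo, hi) Hz
oracle_band_energy_frac <- function(x, fs, lo, hi) {
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs <= fs / 2
  inband <- half & freqs >= lo & freqs < hi
  sum(pw[inband]) / sum(pw[half])
}
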