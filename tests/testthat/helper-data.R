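# Shared fixture builders: everything is generated in code at test time.

# a Bonn-style text file with the given samples; returns the path
bonn_file <- function(samples, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".txt")
  write_bonn_segment(samples, path)
  path
}

# small synthetic generator for fast tests: short frames, modest rate
fast_synth <- function(...) {
  synth_config(fs = 100, frame_len_s = 2.56, ...)
}

# gaussian two-class feature table: `informative` columns get a mean shift
# of `shift` pooled SDs, the rest are pure noise
planted_features <- function(n_per_class, m, informative, shift = 2,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(n * m), n, m)
    y <- rep(c(0L, 1L), each = n_per_class)
    x[y == 1, informative] <- x[y == 1, informative] + shift
    colnames(x) <- sprintf("f%02d", seq_len(m))
    dplyr::bind_cols(
      tibble::tibble(source_id = "sim", frame = seq_len(n), label = y),
      tibble::as_tibble(x)
    )
  })
}
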