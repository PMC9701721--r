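# Shared fixtures and independent oracles, built in code at test time.

# Small synthetic subject, memoised per option set so repeated tests reuse it.
.subject_cache <- new.env(parent = emptyenv())

small_subject <- function(seed = 11, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.subject_cache[[key]])) {
    spec <- synth_spec(n_channels = 8, fs = 64, n_seizures = 3,
                       interictal_minutes = 2, preictal_minutes = 1,
                       seed = seed, ...)
    .subject_cache[[key]] <- synth_segments(spec, standardize = TRUE)
  }
  .subject_cache[[key]]
}

# Hand-built segments object (labels/blocks supplied directly), for fold and
# trainer tests that need controlled geometry.
toy_segments <- function(x, label, block_id, fs = dim(x)[3]) {
  structure(
    list(x = x, tensor = NULL, label = as.integer(label),
         block_id = as.integer(block_id),
         t0_s = seq_len(dim(x)[1]) - 1, fs = fs, subject_id = "toy",
         channel_names = sprintf("T%02d", seq_len(dim(x)[2]))),
    class = "eeg_segments")
}

# Two-Gaussian-blob segments: class mean +/- mu on every sample of channel 1.
# Linearly separable through every model's input view.
blob_segments <- function(n_per_class = 60, N = 4, M = 16, mu = 1.5,
                          seed = 1, n_blocks = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(rnorm(n * N * M, sd = 0.5), c(n, N, M))
  y <- rep(0:1, each = n_per_class)
  x[y == 1, 1, ] <- x[y == 1, 1, ] + mu
  x[y == 0, 1, ] <- x[y == 0, 1, ] - mu
  blocks <- rep(rep(seq_len(n_blocks), length.out = n_per_class), 2)
  tensorize_segments(toy_segments(x, y, blocks, fs = M))
}

# Rank-based AUC oracle (Mann-Whitney), independent of the package's
# trapezoid ROC implementation.
rank_auc <- function(y, s) {
  r <- rank(s)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mean off-diagonal of a square matrix.
offdiag_mean <- function(R) mean(R[upper.tri(R)])

# FFT band power of one segment (mean over channels), oracle for spectral
# properties of the generator.
band_power_oracle <- function(x, fs, lo, hi) {
  sp <- Mod(stats::mvfft(t(x)))^2
  f <- (seq_len(nrow(sp)) - 1) * fs / nrow(sp)
  f <- pmin(f, fs - f)
  mean(sp[f >= lo & f <= hi, , drop = FALSE])
}
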