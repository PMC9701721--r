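# Filtering, resampling, segmentation, and the two segment representations,
# each checked against an independent oracle.

tone_rec <- function(freq, fs, secs = 4, N = 1) {
  tt <- seq_len(fs * secs) / fs
  new_eeg_recording(matrix(sin(2 * pi * freq * tt), N, fs * secs, byrow = TRUE),
                    fs, sprintf("C%d", seq_len(N)))
}

# Analytic magnitude response of the digital Butterworth bandpass actually
# constructed, evaluated from its transfer-function coefficients.
butter_gain <- function(freq, fs, low, high, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / fs)
  num <- sum(bf$b * z^(seq_along(bf$b) - 1))
  den <- sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(num / den)
}

test_that("bandpass preserves in-band tones per the analytic response", {
  rec <- tone_rec(10, fs = 256)
  out <- eeg_bandpass(rec, 0.5, 70, order = 4)
  # zero-phase application squares the magnitude response
  expected <- butter_gain(10, 256, 0.5, 70)^2
  mid <- 257:(ncol(out$data) - 256)  # ignore filter edge transients
  ratio <- stats::sd(out$data[1, mid]) / stats::sd(rec$data[1, mid])
  expect_lt(abs(ratio - expected), 0.01)
  expect_gt(expected, 0.99)
})

test_that("bandpass removes DC and attenuates stop-band tones as predicted", {
  fs <- 256
  # DC is out of band; away from the filter's edge transients the output is
  # numerically zero
  dc <- new_eeg_recording(matrix(5, 1, fs * 60), fs, "A")
  out <- eeg_bandpass(dc, 0.5, 70)
  mid_dc <- (20 * fs):(40 * fs)
  expect_lt(max(abs(out$data[1, mid_dc])), 5 * 1e-6)

  rec <- tone_rec(120, fs = fs, secs = 8)
  out2 <- eeg_bandpass(rec, 0.5, 70)
  expected <- butter_gain(120, fs, 0.5, 70)^2
  mid <- (2 * fs):(6 * fs)
  ratio <- stats::sd(out2$data[1, mid]) / stats::sd(rec$data[1, mid])
  expect_lt(abs(ratio - expected), 0.05 * max(expected, 0.01))
})

test_that("infeasible bands are rejected", {
  rec <- tone_rec(5, fs = 64)
  expect_error(eeg_bandpass(rec, 0.5, 70), "infeasible")
  expect_error(eeg_bandpass(rec, 10, 5), "infeasible")
})

test_that("resampling: identity short-circuit, sample counts, waveform fidelity", {
  rec <- tone_rec(5, fs = 256)
  expect_identical(eeg_resample(rec, 256), rec)

  rec400 <- tone_rec(5, fs = 400, secs = 10)
  out <- eeg_resample(rec400, 256)
  expect_equal(ncol(out$data), 2560)
  expect_equal(out$fs, 256)

  rec1024 <- tone_rec(5, fs = 1024, secs = 4)
  out2 <- eeg_resample(rec1024, 256)
  tt <- seq_len(ncol(out2$data)) / 256
  ref <- sin(2 * pi * 5 * tt)
  mid <- 129:(length(ref) - 128)
  # the polyphase filter has a small group delay; align before comparing
  best <- max(vapply(-3:3, function(lag) {
    stats::cor(out2$data[1, mid], ref[mid + lag])
  }, 0))
  expect_gt(best, 0.999)
})

test_that("segmentation floors durations and inherits labels", {
  fs <- 256
  rec <- new_eeg_recording(matrix(rnorm(2 * fs * 15), 2), fs, c("A", "B"))
  iv <- data.frame(start_s = 0.0, end_s = 10.7, label = "interictal",
                   block_id = 1L)
  segs <- segment_recording(rec, iv)
  expect_equal(dim(segs$x), c(10, 2, 256))
  expect_equal(segs$label, rep(0L, 10))
  # a half-second interval yields nothing, without error
  iv0 <- data.frame(start_s = 11, end_s = 11.5, label = "preictal", block_id = 1L)
  expect_equal(dim(segment_recording(rec, iv0)$x)[1], 0)
})

test_that("a 30-minute pre-ictal block yields 1800 one-second segments", {
  fs <- 16
  rec <- new_eeg_recording(matrix(rnorm(1 * fs * 1900), 1), fs, "A")
  iv <- data.frame(start_s = 0, end_s = 1800, label = "preictal", block_id = 1L)
  segs <- segment_recording(rec, iv)
  expect_equal(dim(segs$x)[1], 1800)
  expect_equal(segs$t0_s, 0:1799)
})

test_that("pca_plane matches a dense eigendecomposition oracle up to sign", {
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(rnorm(4 * 256), 4, 256)
    got <- pca_plane(x)
    # oracle: eigendecomposition of the observation (channel) covariance
    xc <- sweep(x, 2, colMeans(x))
    G <- xc %*% t(xc)
    ev <- eigen(G, symmetric = TRUE)
    scores_oracle <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    for (k in 1:4) {
      a <- got[, k]
      b <- scores_oracle[, k]
      if (sum(abs(a)) < 1e-8) {
        expect_lt(sqrt(sum(b^2)), 1e-6)  # rank-deficient tail
      } else {
        expect_lt(min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))), 1e-8)
      }
    }
  }
})

test_that("pca_plane structure: ordering, orthogonality, variance budget", {
  set.seed(1)
  x <- matrix(rnorm(6 * 128), 6, 128)
  s <- pca_plane(x)
  v <- apply(s, 2, stats::var)
  expect_true(all(diff(v) <= 1e-10))
  cp <- crossprod(s)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  # centred total variance is preserved by the projection
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(sum(s^2), sum(xc^2), tolerance = 1e-10)
  # identical rows centre away to nothing
  flat <- matrix(rep(rnorm(64), each = 3), 3, 64)
  expect_equal(pca_plane(flat), matrix(0, 3, 3))
  expect_error(pca_plane(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("pearson_plane matches direct evaluation of the correlation sums", {
  # brute force from the summation form of the correlation coefficient
  pearson_oracle <- function(x) {
    n <- ncol(x)
    N <- nrow(x)
    R <- diag(N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j) next
      xi <- x[i, ]; yj <- x[j, ]
      num <- n * sum(xi * yj) - sum(xi) * sum(yj)
      den <- sqrt(n * sum(xi^2) - sum(xi)^2) * sqrt(n * sum(yj^2) - sum(yj)^2)
      R[i, j] <- num / den
    }
    R
  }
  set.seed(3)
  for (rep in 1:20) {
    x <- matrix(rnorm(6 * 256), 6, 256)
    expect_lt(max(abs(pearson_plane(x) - pearson_oracle(x))), 1e-10)
  }
})

test_that("pearson_plane handles exact and degenerate correlation", {
  x <- rnorm(100)
  seg <- rbind(x, 2 * x, -x + 3)
  R <- pearson_plane(seg)
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_equal(diag(R), rep(1, 3))
  # zero-variance channel: off-diagonals 0, diagonal stays 1
  seg2 <- rbind(x, rep(2, 100))
  R2 <- pearson_plane(seg2)
  expect_equal(R2[1, 2], 0)
  expect_equal(diag(R2), c(1, 1))
  # invariance under positive affine per-channel rescaling
  seg3 <- matrix(rnorm(4 * 64), 4, 64)
  seg3b <- seg3 * c(2, 5, 0.1, 7) + c(1, -3, 0, 10)
  expect_equal(pearson_plane(seg3), pearson_plane(seg3b), tolerance = 1e-12)
})

test_that("tensorize stacks the planes in the documented order", {
  set.seed(4)
  x <- matrix(rnorm(16 * 256), 16, 256)
  tz <- tensorize(x)
  expect_equal(dim(tz), c(2, 16, 16))
  expect_equal(diag(tz[2, , ]), rep(1, 16))       # Pearson plane has unit diagonal
  expect_false(all(abs(diag(tz[1, , ]) - 1) < 1e-6))
  # zero signal: PCA plane 0, Pearson plane = identity under the
  # zero-variance rule
  z <- tensorize(matrix(0, 4, 32))
  expect_equal(z[1, , ], matrix(0, 4, 4))
  expect_equal(z[2, , ], diag(4))
})

test_that("balancing subsamples inter-ictal deterministically", {
  set.seed(6)
  x <- array(rnorm(120 * 2 * 8), c(120, 2, 8))
  segs <- toy_segments(x, label = c(rep(1, 20), rep(0, 100)),
                       block_id = rep(1:4, 30))
  b1 <- balance_segments(segs, seed = 1)
  expect_equal(sum(b1$label == 1), 20)
  expect_equal(sum(b1$label == 0), 20)
  b2 <- balance_segments(segs, seed = 1)
  expect_identical(b1$x, b2$x)
  b3 <- balance_segments(segs, seed = 2)
  expect_false(identical(b1$x, b3$x))
  expect_equal(dim(b3$x), dim(b1$x))
  # equal counts pass through unchanged
  even <- toy_segments(x[1:40, , , drop = FALSE], rep(0:1, 20), rep(1, 40))
  expect_identical(balance_segments(even, 1)$x, even$x)
  # inverted imbalance: keep all, warn
  inv <- toy_segments(x, label = c(rep(1, 100), rep(0, 20)), block_id = rep(1, 120))
  expect_warning(out <- balance_segments(inv, 1), "keeping all")
  expect_equal(length(out$label), 120)
})

test_that("standardize_recording zeroes means, units variances, keeps Pearson plane", {
  set.seed(8)
  rec <- new_eeg_recording(matrix(rnorm(3 * 640, mean = 12, sd = 25), 3), 64,
                           c("A", "B", "C"))
  z <- standardize_recording(rec)
  expect_lt(max(abs(rowMeans(z$data))), 1e-12)
  expect_equal(apply(z$data, 1, stats::sd), rep(1, 3))
  seg_raw <- rec$data[, 1:64]
  seg_z <- z$data[, 1:64]
  expect_equal(pearson_plane(seg_raw), pearson_plane(seg_z), tolerance = 1e-12)
})
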