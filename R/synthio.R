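# Synthetic multichannel EEG with a controllable pre-ictal effect size.
#
# The generator exists so the whole pipeline — labelling, segmentation, the
# dual representation and the networks — can be exercised offline. Pre-ictal
# blocks differ from inter-ictal blocks along exactly the two axes the two
# network branches are designed to exploit: the cross-channel correlation
# level (instance branch, Pearson plane) and the band-power profile of the
# oscillatory content (sequence branch).

# Band edges (Hz) and inter-ictal band powers (signal-variance units) of
# the three oscillatory packets. Each packet is an independent band-limited
# Gaussian noise process per channel (white noise restricted to the band in
# the frequency domain), so every one-second segment carries energy across
# the whole band and the packets are mutually uncorrelated across channels.
# Total power is preserved under the pre-ictal spectral shift, which moves
# power out of alpha into theta+beta.
.synth_band_lo     <- c(theta = 4, alpha = 8, beta = 13)
.synth_band_hi     <- c(theta = 8, alpha = 13, beta = 30)
# Alpha-dominant background, the hallmark of resting EEG; the pre-ictal
# spectral shift suppresses alpha toward theta+beta.
.synth_band_power  <- c(theta = 6, alpha = 40, beta = 6)
.synth_noise_sd    <- 5
.synth_ictal_secs  <- 20
.synth_ictal_freq  <- 3
.synth_ictal_amp   <- 50

#' Specify a synthetic EEG subject
#'
#' Describes a subject whose recording alternates inter-ictal blocks,
#' pre-ictal blocks and short ictal events. The pre-ictal regime differs
#' from the inter-ictal regime by an effect size `effect_size` (delta) that
#' scales both a cross-channel correlation increase (`corr_shift`) and a
#' spectral shift (`spectral_shift`, the fraction of alpha-band power moved
#' half to theta and half to beta). `effect_size = 0` makes the two regimes
#' identically distributed by construction.
#'
#' @param n_channels Number of channels (N).
#' @param fs Sampling rate in Hz (integer).
#' @param n_seizures Number of seizures; at least 3, matching the
#'   eligibility rule used for real subjects.
#' @param interictal_minutes Length of each inter-ictal block, minutes.
#' @param preictal_minutes Length of each pre-ictal block, minutes.
#' @param effect_size Non-negative scale delta applied to both shifts.
#' @param base_corr Inter-ictal cross-channel correlation (compound
#'   symmetric), in `[0, 1)`.
#' @param corr_shift Additional correlation in the pre-ictal regime at
#'   `effect_size = 1`; `base_corr + effect_size * corr_shift` must stay
#'   below 1 for the target correlation to be positive definite.
#' @param spectral_shift Fraction of alpha-band power moved to theta+beta
#'   in the pre-ictal regime at `effect_size = 1`, in `[0, 1]`.
#' @param ar_coeff AR(1) coefficient of the broadband noise, in (-1, 1).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_spec`.
#' @seealso [generate_subject()]
#' @export
#' @examples
#' spec <- synth_spec(n_channels = 4, fs = 64, n_seizures = 3,
#'                    interictal_minutes = 1, preictal_minutes = 1, seed = 1)
#' rec <- generate_subject(spec)
#' rec
synth_spec <- function(n_channels = 16, fs = 256, n_seizures = 4,
                       interictal_minutes = 10, preictal_minutes = 30,
                       effect_size = 1, base_corr = 0.2, corr_shift = 0.3,
                       spectral_shift = 0.5, ar_coeff = 0.6, seed = 1) {
  stopifnot_scalar_num(n_channels, "n_channels", lower = 1)
  stopifnot_scalar_num(fs, "fs", lower = 1)
  if (fs != round(fs)) stop("`fs` must be an integer sampling rate", call. = FALSE)
  stopifnot_scalar_num(n_seizures, "n_seizures", lower = 3)
  stopifnot_scalar_num(interictal_minutes, "interictal_minutes", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_num(preictal_minutes, "preictal_minutes", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_num(effect_size, "effect_size", lower = 0)
  stopifnot_scalar_num(base_corr, "base_corr", lower = 0, upper = 1, strict_upper = TRUE)
  stopifnot_scalar_num(corr_shift, "corr_shift", lower = -1, upper = 1)
  stopifnot_scalar_num(spectral_shift, "spectral_shift", lower = 0, upper = 1)
  stopifnot_scalar_num(ar_coeff, "ar_coeff", lower = -1, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  rho_pre <- base_corr + effect_size * corr_shift
  if (rho_pre >= 1 || rho_pre < 0) {
    stop(sprintf(paste0(
      "pre-ictal correlation base_corr + effect_size * corr_shift = %.3f is ",
      "outside [0, 1): the target correlation matrix would not be positive ",
      "definite"), rho_pre), call. = FALSE)
  }
  if (effect_size * spectral_shift > 1) {
    stop("effect_size * spectral_shift must not exceed 1 (cannot remove more than the full alpha power)",
         call. = FALSE)
  }
  structure(
    list(
      n_channels = as.integer(n_channels), fs = as.integer(fs),
      n_seizures = as.integer(n_seizures),
      interictal_minutes = interictal_minutes,
      preictal_minutes = preictal_minutes,
      effect_size = effect_size, base_corr = base_corr,
      corr_shift = corr_shift, spectral_shift = spectral_shift,
      ar_coeff = ar_coeff, seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic EEG subject spec: %d channels @ %d Hz, %d seizures\n",
    x$n_channels, x$fs, x$n_seizures))
  cat(sprintf("  blocks: %.3g min inter-ictal + %.3g min pre-ictal per seizure\n",
              x$interictal_minutes, x$preictal_minutes))
  cat(sprintf("  effect size %.3g (corr shift %.3g, spectral shift %.3g), seed %d\n",
              x$effect_size, x$corr_shift, x$spectral_shift, x$seed))
  invisible(x)
}

# Compound-symmetric channel correlation with off-diagonal rho; returns the
# transposed Cholesky factor used to mix independent sources.
.corr_mixer <- function(n, rho) {
  R <- matrix(rho, n, n)
  diag(R) <- 1
  U <- tryCatch(chol(R), error = function(e) {
    stop(sprintf(
      "requested channel correlation %.3f does not give a positive definite matrix",
      rho), call. = FALSE)
  })
  t(U)
}

# Band powers of the oscillatory packets for a regime; `shift` is the
# fraction of alpha power moved (half to theta, half to beta).
.band_power <- function(shift) {
  p <- .synth_band_power
  moved <- p[["alpha"]] * shift
  c(theta = p[["theta"]] + moved / 2,
    alpha = p[["alpha"]] - moved,
    beta  = p[["beta"]] + moved / 2)
}

# Band-limited Gaussian noise of the given variance: white noise whose
# Fourier coefficients outside [lo, hi] Hz are zeroed, rescaled to the
# target power.
.band_noise <- function(n_samples, fs, lo, hi, power) {
  e <- rnorm(n_samples)
  sp <- stats::fft(e)
  f <- (seq_len(n_samples) - 1) * fs / n_samples
  f <- pmin(f, fs - f)  # two-sided spectrum folds at Nyquist
  sp[f < lo | f > hi] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n_samples
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(numeric(n_samples))
  x * sqrt(power) / s
}

# One block of mixed AR(1)-plus-oscillation signal. Sources are independent
# per channel (AR(1) noise with stationary sd .synth_noise_sd, plus one
# band-limited noise packet per band); mixing through the Cholesky factor
# sets the cross-channel correlation without touching the per-channel
# spectrum.
.synth_block <- function(n_channels, fs, n_samples, mixer, band_power,
                         ar_coeff, extra = NULL) {
  tt <- seq_len(n_samples) / fs
  innov_sd <- .synth_noise_sd * sqrt(1 - ar_coeff^2)
  S <- matrix(0, n_channels, n_samples)
  for (c in seq_len(n_channels)) {
    e <- rnorm(n_samples, sd = innov_sd)
    e[1] <- rnorm(1, sd = .synth_noise_sd)  # stationary start
    noise <- as.numeric(stats::filter(e, ar_coeff, method = "recursive"))
    osc <- 0
    for (b in names(.synth_band_lo)) {
      osc <- osc + .band_noise(n_samples, fs, .synth_band_lo[[b]],
                               .synth_band_hi[[b]], band_power[[b]])
    }
    S[c, ] <- noise + osc
    if (!is.null(extra)) {
      S[c, ] <- S[c, ] + extra$amp * sin(2 * pi * extra$freq * tt + runif(1, 0, 2 * pi))
    }
  }
  mixer %*% S
}

#' Generate a synthetic subject recording
#'
#' Builds a continuous multichannel recording laid out as `n_seizures`
#' repetitions of inter-ictal block, pre-ictal block, 20-s ictal event, with
#' seizure annotations at the ictal events. The pre-ictal regime differs
#' from the inter-ictal regime by the delta-scaled correlation and spectral
#' shifts in the spec; at `effect_size = 0` the two regimes are generated
#' from the identical distribution.
#'
#' @param spec A [synth_spec()].
#' @return An `eeg_recording`: list with `data` (channels x samples matrix),
#'   `fs`, `channel_names`, `annotations` (data.frame of `onset_s`,
#'   `offset_s`), `subject_id`, and a `regimes` block table recording the
#'   generating regime of every block (useful for validation).
#' @export
generate_subject <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("`spec` must be a synth_spec", call. = FALSE)
  N <- spec$n_channels
  fs <- spec$fs
  n_inter <- as.integer(round(spec$interictal_minutes * 60 * fs))
  n_pre   <- as.integer(round(spec$preictal_minutes * 60 * fs))
  n_ict   <- as.integer(.synth_ictal_secs * fs)
  if (n_inter < fs || n_pre < fs) {
    stop("blocks must be at least one second long at the requested fs", call. = FALSE)
  }

  mixer_inter <- .corr_mixer(N, spec$base_corr)
  mixer_pre   <- .corr_mixer(N, spec$base_corr + spec$effect_size * spec$corr_shift)
  bp_inter <- .band_power(0)
  bp_pre   <- .band_power(spec$effect_size * spec$spectral_shift)

  with_seed(spec$seed, {
    blocks <- vector("list", 3L * spec$n_seizures)
    regime <- character(3L * spec$n_seizures)
    for (k in seq_len(spec$n_seizures)) {
      i <- 3L * (k - 1L)
      blocks[[i + 1L]] <- .synth_block(N, fs, n_inter, mixer_inter, bp_inter, spec$ar_coeff)
      blocks[[i + 2L]] <- .synth_block(N, fs, n_pre, mixer_pre, bp_pre, spec$ar_coeff)
      blocks[[i + 3L]] <- .synth_block(
        N, fs, n_ict, mixer_inter, bp_inter, spec$ar_coeff,
        extra = list(freq = .synth_ictal_freq, amp = .synth_ictal_amp))
      regime[i + 1:3] <- c("interictal", "preictal", "ictal")
    }
    lens <- vapply(blocks, ncol, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens
    data <- do.call(cbind, blocks)

    ict <- which(regime == "ictal")
    annotations <- data.frame(
      onset_s = starts[ict] / fs,
      offset_s = ends[ict] / fs
    )
    regimes <- data.frame(
      start_s = starts / fs, end_s = ends / fs, regime = regime,
      stringsAsFactors = FALSE
    )
    new_eeg_recording(
      data = data, fs = fs,
      channel_names = sprintf("SYN%02d", seq_len(N)),
      annotations = annotations,
      subject_id = sprintf("synth_seed%d", spec$seed),
      regimes = regimes
    )
  })
}

#' Generate, label, segment, tensorize and balance a synthetic subject
#'
#' Convenience chain for simulation studies: runs [generate_subject()],
#' labels intervals using the generator's own pre-ictal horizon (annotation
#' merging is disabled since synthetic annotations are exact, and the
#' post-ictal buffer defaults to 15 s because the generator returns to the
#' inter-ictal regime immediately after each 20-s ictal event), segments,
#' attaches the (2, N, N) tensors and balances the classes.
#'
#' @param spec A [synth_spec()].
#' @param postictal_buffer_min Post-ictal exclusion in minutes
#'   (default 0.25).
#' @param balance_seed Seed for the class-balancing draw (default: the
#'   generator seed).
#' @param standardize If `TRUE`, apply [standardize_recording()] before
#'   segmentation (default `FALSE`).
#' @return A balanced, tensorized `eeg_segments` object.
#' @export
synth_segments <- function(spec, postictal_buffer_min = 0.25,
                           balance_seed = spec$seed, standardize = FALSE) {
  rec <- generate_subject(spec)
  if (standardize) rec <- standardize_recording(rec)
  iv <- label_intervals(rec, preictal_min = spec$preictal_minutes,
                        postictal_buffer_min = postictal_buffer_min,
                        gap_min = 0)
  segs <- tensorize_segments(segment_recording(rec, iv))
  balance_segments(segs, seed = balance_seed)
}
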