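# Preprocessing: bandpass filter, resampling, 1-s segmentation, and the
# dual representation of each segment — the raw channels x samples matrix
# for the sequence branch and the (2, N, N) tensor (PCA score plane +
# Pearson correlation plane) for the instance branch.

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth bandpass to every
#' channel. Defaults cover the standard clinical EEG band.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order (default 4).
#' @return The filtered recording (same length, same annotations).
#' @export
eeg_bandpass <- function(rec, low_hz = 0.5, high_hz = 70, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band [%g, %g] Hz is infeasible for fs = %g Hz (need 0 < low < high < %g)",
                 low_hz, high_hz, rec$fs, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec$data
  for (c in seq_len(nrow(out))) {
    out[c, ] <- signal::filtfilt(bf, rec$data[c, ])
  }
  new_eeg_recording(out, rec$fs, rec$channel_names, rec$annotations,
                    subject_id = rec$subject_id, regimes = rec$regimes)
}

#' Resample a recording to a target rate
#'
#' Polyphase resampling of every channel. Annotation times are in seconds
#' and therefore unchanged. A recording already at the target rate is
#' returned as-is.
#'
#' @param rec An `eeg_recording` with integer `fs`.
#' @param target_hz Target sampling rate in Hz (default 256).
#' @return The resampled recording with `fs = target_hz`.
#' @export
eeg_resample <- function(rec, target_hz = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  stopifnot_scalar_num(target_hz, "target_hz", lower = 1)
  if (rec$fs == target_hz) return(rec)
  if (rec$fs != round(rec$fs) || target_hz != round(target_hz)) {
    stop("resampling requires integer sampling rates", call. = FALSE)
  }
  g <- .gcd(as.integer(target_hz), as.integer(rec$fs))
  p <- as.integer(target_hz) %/% g
  q <- as.integer(rec$fs) %/% g
  n_out <- floor(ncol(rec$data) * target_hz / rec$fs)
  out <- matrix(0, nrow(rec$data), n_out)
  for (c in seq_len(nrow(rec$data))) {
    y <- signal::resample(rec$data[c, ], p, q)
    if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
    out[c, ] <- y[seq_len(n_out)]
  }
  new_eeg_recording(out, target_hz, rec$channel_names, rec$annotations,
                    subject_id = rec$subject_id, regimes = rec$regimes)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Cut labelled intervals into non-overlapping 1-second segments
#'
#' Each labelled interval yields `floor(duration_s)` segments of exactly
#' `fs` samples; a trailing partial second is discarded. Labels and block
#' ids are inherited from the interval.
#'
#' @param rec An `eeg_recording` (already filtered/resampled as desired).
#' @param intervals Interval table from [label_intervals()].
#' @return An `eeg_segments` object: list with `x` (segments x channels x
#'   samples array), `label` (1 = preictal, 0 = interictal), `block_id`,
#'   `t0_s`, `fs`, `subject_id`, `channel_names`, and `tensor` (`NULL`
#'   until [tensorize_segments()] is called).
#' @export
segment_recording <- function(rec, intervals) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("segmentation requires an integer sampling rate", call. = FALSE)
  N <- nrow(rec$data)
  keep <- intervals$label %in% c("preictal", "interictal")
  intervals <- intervals[keep, , drop = FALSE]

  counts <- pmax(floor(intervals$end_s - intervals$start_s), 0)
  S <- sum(counts)
  x <- array(0, dim = c(S, N, fs))
  label <- integer(S)
  block_id <- integer(S)
  t0 <- numeric(S)
  s <- 0L
  for (i in seq_len(nrow(intervals))) {
    n_seg <- counts[i]
    if (n_seg == 0) next
    start_sample <- round(intervals$start_s[i] * fs)
    for (k in seq_len(n_seg)) {
      s <- s + 1L
      idx <- start_sample + (k - 1L) * fs + seq_len(fs)
      x[s, , ] <- rec$data[, idx, drop = FALSE]
      label[s] <- if (intervals$label[i] == "preictal") 1L else 0L
      block_id[s] <- intervals$block_id[i]
      t0[s] <- intervals$start_s[i] + (k - 1)
    }
  }
  structure(
    list(x = x, tensor = NULL, label = label, block_id = block_id,
         t0_s = t0, fs = fs, subject_id = rec$subject_id,
         channel_names = rec$channel_names),
    class = "eeg_segments"
  )
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf(
    "%d EEG segments (%d channels x %d samples) from '%s': %d pre-ictal, %d inter-ictal%s\n",
    dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$subject_id,
    sum(x$label == 1L), sum(x$label == 0L),
    if (is.null(x$tensor)) "" else "; tensorized"))
  invisible(x)
}

#' Subset segments by index
#' @param x An `eeg_segments` object.
#' @param i Integer or logical index over segments.
#' @param ... Ignored.
#' @return The subsetted `eeg_segments`.
#' @export
`[.eeg_segments` <- function(x, i, ...) {
  out <- x
  out$x <- x$x[i, , , drop = FALSE]
  if (!is.null(x$tensor)) out$tensor <- x$tensor[i, , , , drop = FALSE]
  out$label <- x$label[i]
  out$block_id <- x$block_id[i]
  out$t0_s <- x$t0_s[i]
  out
}

#' PCA score plane of one segment
#'
#' Treats the N channels as observations and the M time samples as
#' features: features are mean-centred across channels, the principal axes
#' come from the singular value decomposition of the centred matrix, and
#' the output is the projection of the N channels onto the first N
#' principal axes (rows = electrodes, columns = components in decreasing
#' explained-variance order). Components beyond the matrix rank (at most
#' N-1 after centring) are zero-filled. Each component's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param x Channels x samples numeric matrix (one segment).
#' @return N x N score matrix.
#' @export
pca_plane <- function(x) {
  if (!is.matrix(x) || !all(is.finite(x))) {
    stop("segment must be a finite numeric matrix", call. = FALSE)
  }
  N <- nrow(x)
  if (ncol(x) < N) stop("segment needs at least as many samples as channels", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = N, nv = N)
  r <- sum(sv$d > max(dim(x)) * .Machine$double.eps * max(sv$d, 1))
  scores <- matrix(0, N, N)
  if (r > 0) {
    for (k in seq_len(min(r, N))) {
      v <- sv$v[, k]
      sgn <- sign(v[which.max(abs(v))])
      if (sgn == 0) sgn <- 1
      scores[, k] <- sv$u[, k] * sv$d[k] * sgn
    }
  }
  scores
}

#' Pearson correlation plane of one segment
#'
#' The N x N matrix of pairwise channel Pearson correlations. The matrix is
#' symmetric with unit diagonal; any pair involving a zero-variance
#' (flat-lined) channel is assigned correlation 0 so the tensor stays
#' finite.
#'
#' @param x Channels x samples numeric matrix (one segment, >= 2 samples).
#' @return N x N correlation matrix.
#' @export
pearson_plane <- function(x) {
  if (!is.matrix(x) || !all(is.finite(x))) {
    stop("segment must be a finite numeric matrix", call. = FALSE)
  }
  if (ncol(x) < 2) stop("segment needs at least 2 samples", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(x)))
  dimnames(R) <- NULL
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Build the (2, N, N) tensor for one segment
#'
#' Plane 1 is the PCA score plane, plane 2 the Pearson correlation plane.
#'
#' @param x Channels x samples numeric matrix.
#' @return A 2 x N x N array.
#' @export
tensorize <- function(x) {
  N <- nrow(x)
  out <- array(0, dim = c(2, N, N))
  out[1, , ] <- pca_plane(x)
  out[2, , ] <- pearson_plane(x)
  out
}

#' Attach the (2, N, N) tensors to every segment
#'
#' @param segs An `eeg_segments` object.
#' @return The same object with `tensor` filled (segments x 2 x N x N).
#' @export
tensorize_segments <- function(segs) {
  stopifnot(inherits(segs, "eeg_segments"))
  S <- dim(segs$x)[1]
  N <- dim(segs$x)[2]
  tensor <- array(0, dim = c(S, 2, N, N))
  for (s in seq_len(S)) {
    tensor[s, , , ] <- tensorize(segs$x[s, , ])
  }
  segs$tensor <- tensor
  segs
}

#' Balance classes by subsampling the inter-ictal segments
#'
#' Keeps every pre-ictal segment and draws, uniformly without replacement,
#' the same number of inter-ictal segments. If the inter-ictal class is
#' already the smaller one, all segments are kept with a warning.
#'
#' @param segs An `eeg_segments` object containing both classes.
#' @param seed Integer seed making the draw deterministic.
#' @return The balanced `eeg_segments` (original segment order preserved).
#' @export
balance_segments <- function(segs, seed = 1) {
  stopifnot(inherits(segs, "eeg_segments"))
  pre <- which(segs$label == 1L)
  inter <- which(segs$label == 0L)
  if (length(pre) == 0L || length(inter) == 0L) {
    stop("both classes must be present before balancing", call. = FALSE)
  }
  if (length(inter) < length(pre)) {
    warning("fewer inter-ictal than pre-ictal segments; keeping all")
    return(segs)
  }
  keep_inter <- with_seed(seed, sort(sample(inter, length(pre))))
  segs[sort(c(pre, keep_inter))]
}

#' Per-recording channel standardization
#'
#' Rescales every channel to zero mean and unit variance using
#' recording-wide statistics. Whether the raw sequence fed to the
#' recurrent branch should be standardized is a modelling choice; the
#' Pearson plane is invariant to this rescaling, and it brings the
#' sequence branch's inputs to the unit scale its gate nonlinearities
#' operate on. Off by default throughout the package.
#'
#' @param rec An `eeg_recording`.
#' @return The standardized recording.
#' @export
standardize_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec$data
  mu <- rowMeans(out)
  sd_ <- apply(out, 1, stats::sd)
  sd_[sd_ < .Machine$double.eps] <- 1
  out <- (out - mu) / sd_
  new_eeg_recording(out, rec$fs, rec$channel_names, rec$annotations,
                    subject_id = rec$subject_id, regimes = rec$regimes)
}

#' Save a segment archive
#'
#' Serializes the segments together with provenance metadata (subject,
#' sampling rate, preprocessing settings, seed) so downstream runs are
#' reproducible from the archive alone.
#'
#' @param segs An `eeg_segments` object.
#' @param path Output file path (RDS).
#' @param meta Named list of provenance attributes to embed.
#' @return `path`, invisibly.
#' @export
save_segments <- function(segs, path, meta = list()) {
  stopifnot(inherits(segs, "eeg_segments"))
  attr(segs, "meta") <- meta
  saveRDS(segs, path)
  invisible(path)
}

#' Load a segment archive written by [save_segments()]
#' @param path Archive path.
#' @return The `eeg_segments` object (provenance in `attr(, "meta")`).
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop(sprintf("archive not found: %s", path), call. = FALSE)
  segs <- readRDS(path)
  if (!inherits(segs, "eeg_segments")) {
    stop(sprintf("%s is not a segment archive", path), call. = FALSE)
  }
  segs
}
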