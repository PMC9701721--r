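# Ingestion: recording container, EDF 16-bit I/O, channel selection,
# seizure merging and pre-ictal/inter-ictal interval labelling.

#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate, Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param annotations data.frame with numeric `onset_s`, `offset_s` (seconds
#'   from recording start), one row per seizure; may have zero rows.
#' @param subject_id Subject identifier string.
#' @param regimes Optional block table (used by the synthetic generator).
#' @return An object of class `eeg_recording`.
#' @export
new_eeg_recording <- function(data, fs, channel_names,
                              annotations = data.frame(onset_s = numeric(),
                                                       offset_s = numeric()),
                              subject_id = "subject", regimes = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) < 1L || ncol(data) < fs) {
    stop("recording must have at least one channel and one second of samples",
         call. = FALSE)
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  if (!all(c("onset_s", "offset_s") %in% names(annotations))) {
    stop("`annotations` needs columns onset_s and offset_s", call. = FALSE)
  }
  dur <- ncol(data) / fs
  if (nrow(annotations) > 0) {
    if (any(annotations$offset_s <= annotations$onset_s) ||
        any(annotations$onset_s < 0)) {
      stop("annotations must satisfy 0 <= onset_s < offset_s", call. = FALSE)
    }
    if (any(annotations$offset_s > dur + 1e-9)) {
      stop(sprintf("annotation extends beyond recording end (%.1f s)", dur),
           call. = FALSE)
    }
    annotations <- annotations[order(annotations$onset_s), , drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         annotations = annotations, subject_id = subject_id,
         regimes = regimes),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels @ %g Hz, %.1f min, %d seizure(s)\n",
              x$subject_id, nrow(x$data), x$fs,
              ncol(x$data) / x$fs / 60, nrow(x$annotations)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# EDF 16-bit reader/writer (continuous recordings, identical sampling rate on
# every channel, one data record per second). The format is a 256-byte ASCII
# header, 256 ASCII bytes per signal, then data records of little-endian
# 16-bit integers with per-channel linear physical scaling.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one data record per second; every channel is scaled
#' independently to the full digital range, so the round-trip error is
#' bounded by the 16-bit quantisation step of each channel's physical range.
#' A trailing partial second, if any, is dropped with a warning. Seizure
#' annotations are written to a sidecar CSV next to the EDF when
#' `annotation_path` is given.
#'
#' @param rec An `eeg_recording`.
#' @param path Output EDF path.
#' @param annotation_path Optional sidecar CSV path for the annotations.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, annotation_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  N <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec * fs < ncol(rec$data)) {
    warning("dropping trailing partial second when writing EDF")
  }
  X <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  phys_min <- apply(X, 1, min)
  phys_max <- apply(X, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad("preictal synthetic/export", 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * N, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(N, 4)
  )
  sig <- paste0(
    paste(vapply(rec$channel_names, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), N), collapse = ""),
    paste(rep(.edf_pad("uV", 8), N), collapse = ""),
    paste(vapply(phys_min, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_pad(dig_min, 8), N), collapse = ""),
    paste(rep(.edf_pad(dig_max, 8), N), collapse = ""),
    paste(rep(.edf_pad("", 80), N), collapse = ""),
    paste(rep(.edf_pad(fs, 8), N), collapse = ""),
    paste(rep(.edf_pad("", 32), N), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- X[, idx, drop = FALSE]
    dig <- round((block - phys_min) / scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    # records store each signal's fs samples consecutively: row-wise layout
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  if (!is.null(annotation_path)) {
    write_annotations(rec$annotations, annotation_path,
                      subject_id = rec$subject_id)
  }
  invisible(path)
}

#' Read an EDF file (16-bit, continuous)
#'
#' @param path EDF file path.
#' @param annotation_path Optional sidecar CSV of seizure annotations with
#'   columns `onset_s`, `offset_s` (seconds from recording start).
#' @return An `eeg_recording`. Annotation times beyond the recording end are
#'   a validation error; a missing or malformed EDF is an I/O error naming
#'   the file.
#' @export
read_edf <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("EDF file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) {
    stop(sprintf("corrupt EDF header in %s", path), call. = FALSE)
  }
  grab <- function(s, from, len) substr(s, from, from + len - 1)
  subject_id <- trimws(grab(hdr, 9, 80))
  n_rec <- as.integer(trimws(grab(hdr, 237, 8)))
  rec_dur <- as.numeric(trimws(grab(hdr, 245, 8)))
  N <- as.integer(trimws(grab(hdr, 253, 4)))
  if (is.na(N) || N < 1 || is.na(n_rec)) {
    stop(sprintf("corrupt EDF header in %s", path), call. = FALSE)
  }
  sig <- readChar(con, 256 * N, useBytes = TRUE)
  fld <- function(from_total, width) {
    vapply(seq_len(N), function(i) {
      trimws(grab(sig, from_total + (i - 1) * width + 1, width))
    }, "")
  }
  off <- 0
  labels <- fld(off, 16); off <- off + 16 * N
  off <- off + 80 * N                      # transducer
  off <- off + 8 * N                       # physical dimension
  phys_min <- as.numeric(fld(off, 8)); off <- off + 8 * N
  phys_max <- as.numeric(fld(off, 8)); off <- off + 8 * N
  dig_min <- as.numeric(fld(off, 8)); off <- off + 8 * N
  dig_max <- as.numeric(fld(off, 8)); off <- off + 8 * N
  off <- off + 80 * N                      # prefiltering
  spr <- as.integer(fld(off, 8))
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports a single sampling rate across channels", call. = FALSE)
  }
  fs <- spr[1] / rec_dur

  raw <- readBin(con, integer(), n = n_rec * N * spr[1], size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * N * spr[1]) {
    stop(sprintf("truncated EDF data in %s", path), call. = FALSE)
  }
  X <- matrix(0, N, n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    chunk <- raw[((r - 1) * N * spr[1] + 1):(r * N * spr[1])]
    M <- t(matrix(chunk, nrow = spr[1], ncol = N))  # undo row-wise layout
    X[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- (M - dig_min) * scale + phys_min
  }

  ann <- if (is.null(annotation_path)) {
    data.frame(onset_s = numeric(), offset_s = numeric())
  } else {
    read_annotations(annotation_path)
  }
  new_eeg_recording(X, fs, labels, ann, subject_id = subject_id)
}

#' Write seizure annotations to CSV
#' @param annotations data.frame with `onset_s`, `offset_s`.
#' @param path Output CSV path.
#' @param subject_id Subject id recorded alongside each row.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, subject_id = "subject") {
  df <- data.frame(
    subject_id = rep(subject_id, nrow(annotations)),
    seizure_index = seq_len(nrow(annotations)),
    onset_s = annotations$onset_s,
    offset_s = annotations$offset_s
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations from CSV
#' @param path CSV with columns `onset_s`, `offset_s` (extra columns are
#'   ignored).
#' @return data.frame with `onset_s`, `offset_s`, sorted by onset.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(df))) {
    stop(sprintf("annotation file %s needs columns onset_s, offset_s", path),
         call. = FALSE)
  }
  df <- df[order(df$onset_s), c("onset_s", "offset_s"), drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------

#' Select and reorder channels by name
#'
#' Matching is case-insensitive and ignores whitespace/punctuation other
#' than dashes, since EDF dialects disagree on channel-name formatting.
#'
#' @param rec An `eeg_recording`.
#' @param wanted Character vector of channel names, in the desired output
#'   order.
#' @return The recording restricted to `wanted`, rows in that order.
#' @export
select_channels <- function(rec, wanted) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- normalize_channel_name(rec$channel_names)
  want <- normalize_channel_name(wanted)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop(sprintf("channel(s) not found in recording: %s",
                 paste(wanted[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  new_eeg_recording(
    rec$data[idx, , drop = FALSE], rec$fs, rec$channel_names[idx],
    rec$annotations, subject_id = rec$subject_id, regimes = rec$regimes
  )
}

#' The 18 bipolar channels shared by most CHB-MIT-style scalp recordings
#' @return Character vector of 18 channel names.
#' @export
chbmit_channels <- function() {
  c("P8-O2", "F8-T8", "F7-T7", "P7-O1", "FZ-CZ", "FP1-F7", "FP2-F8",
    "T8-P8", "F3-C3", "C4-P4", "CZ-PZ", "T7-P7", "F4-C4", "C3-P3",
    "P3-O1", "FP2-F4", "FP1-F3", "P4-O2")
}

#' Merge seizures separated by short gaps
#'
#' Consecutive seizures whose gap (next onset minus previous offset) is
#' strictly less than `gap_min` minutes are fused into a single annotation
#' spanning both. The operation is idempotent.
#'
#' @param annotations data.frame with `onset_s`, `offset_s`, sorted.
#' @param gap_min Merge threshold in minutes (default 30).
#' @return Merged annotation data.frame.
#' @export
merge_seizures <- function(annotations, gap_min = 30) {
  if (nrow(annotations) <= 1L) return(annotations)
  ann <- annotations[order(annotations$onset_s), , drop = FALSE]
  out <- ann[1, , drop = FALSE]
  for (i in 2:nrow(ann)) {
    gap <- ann$onset_s[i] - out$offset_s[nrow(out)]
    if (gap < gap_min * 60) {
      out$offset_s[nrow(out)] <- max(out$offset_s[nrow(out)], ann$offset_s[i])
    } else {
      out <- rbind(out, ann[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Label a recording into pre-ictal / inter-ictal intervals
#'
#' For each (merged) seizure, the `preictal_min` minutes before onset are
#' pre-ictal, truncated at the recording start or at the previous seizure's
#' exclusion zone. The ictal span and a post-ictal buffer after each offset
#' are excluded from both classes; all remaining time is inter-ictal.
#' Pre-ictal and inter-ictal blocks carry independent 1-based `block_id`s in
#' time order (pre-ictal block k ends at seizure k's onset).
#'
#' @param rec An `eeg_recording`. Its annotations are passed through
#'   [merge_seizures()] first (idempotent if already merged).
#' @param preictal_min Pre-ictal horizon in minutes (default 30).
#' @param postictal_buffer_min Post-ictal exclusion after each seizure
#'   offset, minutes (default 30).
#' @param gap_min Seizure-merge threshold in minutes (default 30).
#' @return data.frame with `start_s`, `end_s`, `label`
#'   ("preictal"/"interictal"), `block_id`; intervals are disjoint and
#'   ordered in time.
#' @export
label_intervals <- function(rec, preictal_min = 30, postictal_buffer_min = 30,
                            gap_min = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- ncol(rec$data) / rec$fs
  ann <- merge_seizures(rec$annotations, gap_min = gap_min)
  if (nrow(ann) == 0L) {
    warning("recording has no seizures; labelling everything inter-ictal")
    return(data.frame(start_s = 0, end_s = dur, label = "interictal",
                      block_id = 1L, stringsAsFactors = FALSE))
  }

  pre <- NULL
  prev_excl_end <- 0   # end of previous seizure's exclusion zone
  dropped <- 0L
  for (k in seq_len(nrow(ann))) {
    lo <- max(ann$onset_s[k] - preictal_min * 60, 0, prev_excl_end)
    hi <- ann$onset_s[k]
    if (hi - lo > 1e-9) {
      pre <- rbind(pre, data.frame(start_s = lo, end_s = hi,
                                   label = "preictal", block_id = NA_integer_,
                                   stringsAsFactors = FALSE))
    } else {
      dropped <- dropped + 1L
    }
    prev_excl_end <- min(ann$offset_s[k] + postictal_buffer_min * 60, dur)
  }
  if (dropped > 0L) {
    warning(sprintf("%d seizure(s) yielded no pre-ictal block (window swallowed by a previous exclusion zone)",
                    dropped))
  }
  if (!is.null(pre)) pre$block_id <- seq_len(nrow(pre))

  # excluded zones: ictal span + post-ictal buffer, plus pre-ictal blocks;
  # inter-ictal is the complement within [0, dur]
  excl <- data.frame(
    start_s = ann$onset_s,
    end_s = pmin(ann$offset_s + postictal_buffer_min * 60, dur)
  )
  occupied <- rbind(
    excl,
    if (is.null(pre)) NULL else pre[, c("start_s", "end_s")]
  )
  occupied <- occupied[order(occupied$start_s), , drop = FALSE]

  inter <- NULL
  cursor <- 0
  for (k in seq_len(nrow(occupied))) {
    if (occupied$start_s[k] - cursor > 1e-9) {
      inter <- rbind(inter, data.frame(start_s = cursor,
                                       end_s = occupied$start_s[k],
                                       label = "interictal",
                                       block_id = NA_integer_,
                                       stringsAsFactors = FALSE))
    }
    cursor <- max(cursor, occupied$end_s[k])
  }
  if (dur - cursor > 1e-9) {
    inter <- rbind(inter, data.frame(start_s = cursor, end_s = dur,
                                     label = "interictal",
                                     block_id = NA_integer_,
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(inter)) inter$block_id <- seq_len(nrow(inter))

  out <- rbind(pre, inter)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
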