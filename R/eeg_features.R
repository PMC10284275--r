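#' Construct an EEG recording
#'
#' Multichannel EEG time-locked to video onset, stored as a channels x
#' samples matrix in microvolts.
#'
#' @param participant_id,video_id Identifiers (coerced to character).
#' @param data Numeric matrix, channels x samples.
#' @param channel_names Character vector, one name per data row.
#' @param fs Sampling rate in Hz.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(participant_id, video_id, data, channel_names, fs) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (length(channel_names) != nrow(data))
    stop("number of channel names must equal number of data rows")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  fs <- as.numeric(fs)
  if (ncol(data) < fs)
    stop("recording must contain at least one full second of samples")
  structure(list(participant_id = as.character(participant_id),
                 video_id = as.character(video_id),
                 data = data,
                 channel_names = as.character(channel_names),
                 fs = fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> participant %s, video %s: %d ch x %d samples @ %g Hz\n",
              x$participant_id, x$video_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Preprocess an EEG recording
#'
#' Zero-phase 50-Hz powerline notch (biquad, quality factor 30) followed by
#' a zero-phase 4th-order Butterworth band-pass at 0.05-47 Hz. An optional
#' artifact-removal hook (e.g. an ICA-based ocular cleaner) can be plugged
#' in after filtering; none is applied by default.
#'
#' @param rec An `eeg_recording`.
#' @param notch_hz Powerline frequency to remove (default 50).
#' @param notch_q Notch quality factor (default 30).
#' @param bp_hz Band-pass edges in Hz (default `c(0.05, 47)`).
#' @param bp_order Butterworth order of the band-pass (default 4).
#' @param artifact_hook Optional `function(rec) -> rec` applied last.
#' @return A preprocessed `eeg_recording` of the same shape.
#' @export
preprocess <- function(rec, notch_hz = 50, notch_q = 30,
                       bp_hz = c(0.05, 47), bp_order = 4L,
                       artifact_hook = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (any(!is.finite(rec$data))) stop("non-finite samples in recording")
  if (rec$fs / 2 <= bp_hz[2])
    stop("sampling rate too low: need fs/2 > ", bp_hz[2], " Hz")
  x <- t(rec$data)                       # samples x channels
  x <- filtfilt_mat(design_notch(rec$fs, notch_hz, notch_q), x)
  x <- filtfilt_mat(design_butter(rec$fs, bp_hz, "pass", bp_order), x)
  out <- rec
  out$data <- t(x)
  if (!is.null(artifact_hook)) out <- artifact_hook(out)
  out
}

#' Decompose a recording into frequency bands
#'
#' One zero-phase Butterworth band-pass filtered copy of the data per band.
#' Bands must be well-formed (`low < high`) and non-overlapping.
#'
#' @param rec A (preprocessed) `eeg_recording`.
#' @param bands Named list of `c(low_hz, high_hz)` (default [eeg_bands()]).
#' @param order Butterworth order (default 4).
#' @return Named list of channels x samples matrices, one per band.
#' @export
band_decompose <- function(rec, bands = eeg_bands(), order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- eeg_bands(bands)
  edges <- do.call(rbind, bands)
  if (any(edges[, 2] >= rec$fs / 2))
    stop("band upper edge at or above Nyquist")
  o <- order(edges[, 1])
  if (nrow(edges) > 1 &&
      any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)]))
    stop("bands must not overlap")
  x <- t(rec$data)
  out <- lapply(bands, function(e)
    t(filtfilt_mat(design_butter(rec$fs, e, "pass", order), x)))
  names(out) <- names(bands)
  out
}

#' Per-second band power features for one recording
#'
#' For every non-overlapping 1-s window, channel and band, the power is the
#' sum of squares of the `fs` samples in the window. A trailing partial
#' second is dropped. Columns are ordered channel-major: all bands of
#' channel 1, then all bands of channel 2, and so on, labelled
#' `<channel>_<band>`.
#'
#' @param banded Named list of channels x samples matrices as returned by
#'   [band_decompose()].
#' @param fs Sampling rate in Hz (samples per 1-s window).
#' @param channel_names Character vector of channel names.
#' @param log10_power Apply `log10` to the powers (default `FALSE`; the
#'   default raw-power scale is what the rest of the pipeline assumes).
#' @return A `feature_matrix`: seconds x (channels * bands) numeric matrix
#'   with a `feature_labels` attribute (data frame `channel`, `band`).
#' @export
segment_power <- function(banded, fs, channel_names, log10_power = FALSE) {
  stopifnot(is.list(banded), length(banded) >= 1L)
  nch <- nrow(banded[[1]])
  nsamp <- ncol(banded[[1]])
  if (length(channel_names) != nch)
    stop("channel_names length must match channel count")
  if (nsamp < fs) stop("fewer than fs samples: no full second to segment")
  band_names <- names(banded)
  n_sec <- nsamp %/% fs
  nb <- length(banded)
  per_band <- lapply(banded, function(m) window_sumsq(t(m), as.integer(fs)))
  out <- matrix(0, n_sec, nch * nb)
  labels <- data.frame(channel = rep(channel_names, each = nb),
                       band = rep(band_names, times = nch),
                       stringsAsFactors = FALSE)
  for (ch in seq_len(nch))
    for (b in seq_len(nb))
      out[, (ch - 1L) * nb + b] <- per_band[[b]][, ch]
  if (log10_power) out <- log10(out)
  colnames(out) <- paste(labels$channel, labels$band, sep = "_")
  structure(out, feature_labels = labels, class = c("feature_matrix", "matrix"))
}

# Shared fast path operating on a samples x channels matrix: notch + wide
# band-pass, then per band a zero-phase band filter and per-second sum of
# squares. Numerically identical to preprocess() + band_decompose() +
# segment_power() (same filters in the same order, without the transposes).
features_from_samples <- function(x, fs, channel_names, bands,
                                  log10_power = FALSE) {
  x <- filtfilt_mat(design_notch(fs), x)
  x <- filtfilt_mat(design_butter(fs, c(0.05, 47), "pass"), x)
  nb <- length(bands)
  nch <- ncol(x)
  n_sec <- nrow(x) %/% fs
  out <- matrix(0, n_sec, nch * nb)
  for (b in seq_along(bands)) {
    xb <- filtfilt_mat(design_butter(fs, bands[[b]], "pass"), x)
    out[, seq(b, by = nb, length.out = nch)] <- window_sumsq(xb, as.integer(fs))
  }
  if (log10_power) out <- log10(out)
  labels <- data.frame(channel = rep(channel_names, each = nb),
                       band = rep(names(bands), times = nch),
                       stringsAsFactors = FALSE)
  colnames(out) <- paste(labels$channel, labels$band, sep = "_")
  structure(out, feature_labels = labels, class = c("feature_matrix", "matrix"))
}

#' Full feature extraction for one recording
#'
#' Convenience wrapper: [preprocess()] then [band_decompose()] then
#' [segment_power()].
#'
#' @inheritParams preprocess
#' @inheritParams segment_power
#' @param bands Named list of band edges (default [eeg_bands()]).
#' @return A `feature_matrix` for the recording.
#' @export
eeg_features <- function(rec, bands = eeg_bands(), log10_power = FALSE,
                         artifact_hook = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- eeg_bands(bands)
  if (is.null(artifact_hook)) {
    if (any(!is.finite(rec$data))) stop("non-finite samples in recording")
    if (rec$fs / 2 <= 47)
      stop("sampling rate too low: need fs/2 > 47 Hz")
    return(features_from_samples(t(rec$data), rec$fs, rec$channel_names,
                                 bands, log10_power))
  }
  rec <- preprocess(rec, artifact_hook = artifact_hook)
  banded <- band_decompose(rec, bands)
  segment_power(banded, rec$fs, rec$channel_names, log10_power = log10_power)
}

#' Feature labels of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Data frame with columns `channel` and `band`.
#' @export
feature_labels <- function(fm) attr(fm, "feature_labels")

#' Average feature matrices across participants
#'
#' Element-wise arithmetic mean of per-participant feature matrices that
#' must agree exactly in shape and column labels. Averaging across
#' participants yields the group-level features that represent the shared
#' stimulus-locked response.
#'
#' @param per_participant List of `feature_matrix` objects.
#' @return A `feature_matrix` of the same shape.
#' @export
group_average <- function(per_participant) {
  stopifnot(is.list(per_participant), length(per_participant) >= 1L)
  ref <- per_participant[[1]]
  for (fm in per_participant[-1]) {
    if (!identical(dim(fm), dim(ref)) ||
        !identical(colnames(fm), colnames(ref)))
      stop("feature matrices differ in shape or labels")
  }
  avg <- Reduce(`+`, lapply(per_participant, unclass)) / length(per_participant)
  structure(avg, feature_labels = feature_labels(ref),
            class = c("feature_matrix", "matrix"))
}

#' Write / read a feature matrix as CSV
#'
#' CSV with a leading `second` column (1-based) and one column per
#' `<channel>_<band>` feature.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `read_feature_matrix` returns a `feature_matrix`;
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(second = seq_len(nrow(fm)), unclass(fm),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "second") stop("expected leading 'second' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  labels <- data.frame(
    channel = vapply(parts, function(p) paste(head(p, -1), collapse = "_"),
                     character(1)),
    band = vapply(parts, tail, character(1), n = 1L),
    stringsAsFactors = FALSE)
  structure(m, feature_labels = labels, class = c("feature_matrix", "matrix"))
}

#' Read an EEG recording from a delimited matrix plus metadata sidecar
#'
#' The data file is a delimited numeric matrix (channels x samples, no
#' header); the metadata file is JSON with fields `fs` (Hz), `channels`
#' (array of names) and optionally `participant_id` and `video_id`.
#'
#' @param data_path Path to the delimited matrix (whitespace- or
#'   comma-separated; see `sep`).
#' @param meta_path Path to the JSON metadata sidecar.
#' @param sep Field separator of the data file (default `","`).
#' @return An `eeg_recording`.
#' @export
read_eeg_delim <- function(data_path, meta_path, sep = ",") {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$channels))
    stop("metadata must provide 'fs' and 'channels'")
  m <- as.matrix(read.table(data_path, sep = sep, header = FALSE))
  eeg_recording(participant_id = meta$participant_id %||% "unknown",
                video_id = meta$video_id %||% "unknown",
                data = m, channel_names = meta$channels, fs = meta$fs)
}

#' @rdname read_eeg_delim
#' @param rec An `eeg_recording` to write.
#' @export
write_eeg_delim <- function(rec, data_path, meta_path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  write.table(rec$data, data_path, sep = sep, row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channel_names,
                            participant_id = rec$participant_id,
                            video_id = rec$video_id),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
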