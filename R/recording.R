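# Multichannel EEG container and preprocessing: band-pass + notch filtering,
# average referencing, neighbor interpolation of bad channels, and
# anti-aliased downsampling. All filters are zero-phase (forward-backward),
# so filtered features keep their original latencies.

#' Construct an EEG recording
#'
#' A lightweight container: a channels x time matrix in microvolts, a
#' sampling rate, and 10-10 channel labels. Time is 0-based seconds; sample
#' `i` covers `[(i-1)/fs, i/fs)`.
#'
#' @param samples Numeric matrix, channels in rows.
#' @param fs Sampling rate (samples/s).
#' @param channel_labels Character vector, one per row.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels) {
  samples <- as.matrix(samples)
  stopifnot(fs > 0, nrow(samples) == length(channel_labels))
  if (!all(is.finite(samples))) stop("recording contains non-finite values")
  structure(
    list(samples = samples, fs = fs, channel_labels = as.character(channel_labels)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %.1f s @ %g Hz [%s]\n",
    nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
    paste(utils::head(x$channel_labels, 6), collapse = ", ")
  ))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

rec_channel <- function(rec, channel) {
  i <- match(channel, rec$channel_labels)
  if (is.na(i)) stop("channel not in recording: ", channel)
  rec$samples[i, ]
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase band-pass (Butterworth, high-pass + low-pass cascade) followed
#' by a zero-phase band-stop notch. Defaults follow the conventional wide-band
#' EEG setting: 0.5-70 Hz pass band with a 60 Hz mains notch.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Pass-band edges (Hz).
#' @param notch_hz Notch center (Hz); `NULL` disables the notch.
#' @param notch_halfwidth Half-width of the stop band (Hz, default 2).
#' @return Filtered [eeg_recording()].
#' @export
bandpass_notch <- function(rec, low_hz = 0.5, high_hz = 70, notch_hz = 60,
                           notch_halfwidth = 2) {
  nyq <- rec$fs / 2
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency")
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  out <- rec
  notch <- NULL
  if (!is.null(notch_hz)) {
    if (notch_hz >= nyq) stop("notch_hz must be below the Nyquist frequency")
    notch <- signal::butter(
      2, c(notch_hz - notch_halfwidth, notch_hz + notch_halfwidth) / nyq,
      type = "stop"
    )
  }
  for (i in seq_len(nrow(rec$samples))) {
    x <- bandpass_zerophase(rec$samples[i, ], rec$fs, low_hz, high_hz, order = 4L)
    if (!is.null(notch)) x <- signal::filtfilt(notch, x)
    out$samples[i, ] <- x
  }
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so the
#' output's column means are zero. Idempotent.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return Re-referenced [eeg_recording()].
#' @export
average_reference <- function(rec) {
  if (nrow(rec$samples) < 2L) stop("average reference needs >= 2 channels")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

#' Replace bad channels by weighted neighbor averages
#'
#' A simplified repair of visually-marked bad channels: each bad channel is
#' replaced by the inverse-distance-weighted mean of its good neighbors from
#' a supplied neighbor map. The map is data, not geometry: for each channel
#' it lists neighbor labels and distances (arbitrary units).
#'
#' @param rec An [eeg_recording()].
#' @param bad_labels Channels to replace.
#' @param neighbor_map Named list: `label -> named numeric vector` of
#'   neighbor distances, e.g. `list(C3 = c(F3 = 1, P3 = 1))`.
#' @return Repaired [eeg_recording()].
#' @export
interpolate_bad <- function(rec, bad_labels, neighbor_map) {
  if (length(bad_labels) == 0L) return(rec)
  stopifnot(all(bad_labels %in% rec$channel_labels))
  out <- rec
  for (lab in bad_labels) {
    nb <- neighbor_map[[lab]]
    if (is.null(nb) || length(nb) < 2L) {
      stop("need >= 2 listed neighbors for bad channel ", lab)
    }
    good <- setdiff(names(nb), bad_labels)
    good <- intersect(good, rec$channel_labels)
    if (length(good) == 0L) stop("all neighbors of ", lab, " are bad or absent")
    w <- 1 / nb[good]
    w <- w / sum(w)
    idx <- match(good, rec$channel_labels)
    out$samples[match(lab, rec$channel_labels), ] <-
      drop(w %*% rec$samples[idx, , drop = FALSE])
  }
  out
}

#' Downsample with anti-alias filtering
#'
#' Zero-phase Butterworth low-pass at 80% of the new Nyquist frequency, then
#' decimation. If the rate ratio is not an integer the signal is decimated at
#' the nearest integer factor with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs New sampling rate (samples/s).
#' @return Downsampled [eeg_recording()].
#' @export
downsample_recording <- function(rec, target_fs) {
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs >= rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    warning("fs/target_fs is not an integer; decimating by ", round(q))
  }
  q <- as.integer(round(q))
  lp <- signal::butter(6, 0.8 / q, type = "low")
  keep <- seq(1L, ncol(rec$samples), by = q)
  filtered <- t(apply(rec$samples, 1, function(x) signal::filtfilt(lp, x)))
  rec$samples <- filtered[, keep, drop = FALSE]
  rec$fs <- rec$fs / q
  rec
}
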