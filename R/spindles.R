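# Sleep-spindle detection from the 11-15 Hz amplitude envelope with a
# median-relative threshold and 1-s onset/offset rules, plus per-event
# amplitude and peak-frequency features.

#' Band-limited amplitude envelope of one channel
#'
#' Magnitude of the analytic signal of the band-passed channel — the signal
#' the spindle detector thresholds. The band filter is a zero-phase FFT
#' design with unity pass-band gain, so a pure in-band tone of amplitude A
#' has envelope A. The envelope is lightly smoothed (centered moving
#' average, `smooth_s` seconds) before thresholding: without smoothing the
#' envelope of band-limited noise crosses a median-relative threshold in
#' brief bursts often enough that the 1-s offset rule chains them into
#' spurious events.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label.
#' @param band Detection band in Hz (default 11-15).
#' @param smooth_s Envelope smoothing window (s); 0 disables.
#' @return List of class `eeg_envelope`: `values` (uV, >= 0), `filtered`
#'   (the band-passed signal), `fs`, `channel`, `band`, `smooth_s`.
#' @export
band_envelope <- function(rec, channel, band = c(11, 15), smooth_s = 0.3) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < rec$fs / 2)
  x <- rec_channel(rec, channel)
  filt <- fft_bandpass(x, rec$fs, band[1], band[2])
  env <- Mod(analytic_signal(filt))
  if (smooth_s > 0) env <- moving_average(env, smooth_s, rec$fs)
  structure(
    list(values = env, filtered = filt,
         fs = rec$fs, channel = channel, band = band, smooth_s = smooth_s),
    class = "eeg_envelope"
  )
}

#' Detect sleep spindles from an amplitude envelope
#'
#' The detection threshold is `mult` times the median envelope over
#' artifact-free samples (over the whole recording by default, or sleep only
#' via `median_scope`). A candidate starts when the envelope crosses above
#' threshold; sub-threshold dips shorter than `end_gap` are absorbed into the
#' event; the event ends at the first sample of the first sub-threshold run
#' lasting at least `end_gap`, and is kept if its supra-threshold span is at
#' least `min_dur`. Events overlapping the artifact mask are discarded.
#' Because the threshold is median-relative, detections are invariant to a
#' global rescaling of the signal's units.
#'
#' @param env A [band_envelope()].
#' @param mask Optional [artifact_mask()].
#' @param mult Threshold multiplier on the median (default 2).
#' @param min_dur Minimum event duration in seconds (default 1).
#' @param end_gap Minimum sub-threshold run that terminates an event (s).
#' @param median_scope `"all"` (all artifact-free samples) or `"sleep"`
#'   (artifact-free sleep only; requires `hyp`).
#' @param hyp Optional [hypnogram()], needed for `median_scope = "sleep"` and
#'   to label each event with its stage at onset.
#' @return Tibble of class `spindle_set`: `channel`, `onset_s`, `offset_s`,
#'   `duration_s`, `amplitude_uv`, `peak_freq_hz`, `stage` (if `hyp` given),
#'   with the detection parameters as attributes.
#' @export
detect_spindles <- function(env, mask = NULL, mult = 2, min_dur = 1,
                            end_gap = 1, median_scope = c("all", "sleep"),
                            hyp = NULL) {
  median_scope <- match.arg(median_scope)
  fs <- env$fs
  n <- length(env$values)
  t_sample <- (seq_len(n) - 1) / fs
  free <- !point_in_intervals(t_sample, mask)
  if (median_scope == "sleep") {
    if (is.null(hyp)) stop("median_scope = 'sleep' requires a hypnogram")
    free <- free & stage_at(hyp, t_sample) %in% c("N1", "N2", "N3", "REM")
  }
  if (!any(free)) stop("no artifact-free samples to compute the threshold")
  thr <- mult * stats::median(env$values[free])

  above <- env$values > thr
  # Absorb sub-threshold dips shorter than end_gap between supra runs.
  r <- rle(above)
  if (length(r$lengths) > 1) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    short <- interior[!r$values[interior] &
                        r$lengths[interior] < round(end_gap * fs)]
    if (length(short) > 0) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in short) above[starts[i]:ends[i]] <- TRUE
    }
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= round(min_dur * fs))
  onset_s <- (starts[keep] - 1) / fs
  offset_s <- ends[keep] / fs

  if (length(keep) > 0 && !is.null(mask) && nrow(mask) > 0) {
    hit <- vapply(seq_along(keep), function(i) {
      interval_overlap(onset_s[i], offset_s[i], mask) > 0
    }, logical(1))
    onset_s <- onset_s[!hit]; offset_s <- offset_s[!hit]
  }

  out <- tibble::tibble(
    channel = env$channel,
    onset_s = onset_s, offset_s = offset_s,
    duration_s = offset_s - onset_s
  )
  out <- spindle_features(out, env)
  if (!is.null(hyp)) out$stage <- stage_at(hyp, out$onset_s)
  attr(out, "detection") <- list(
    band = env$band, mult = mult, min_dur = min_dur, end_gap = end_gap,
    threshold_uv = thr, median_scope = median_scope
  )
  class(out) <- c("spindle_set", class(out))
  out
}

#' Spindle amplitude and peak frequency
#'
#' Amplitude is the maximum of the amplitude envelope within the event;
#' peak frequency is the argmax of a zero-padded periodogram of the
#' band-passed segment, restricted to the detection band. Zero-padding
#' (factor 8) interpolates the spectral grid well below the raw resolution
#' of a 1-2.5 s segment.
#'
#' @param spindles Tibble with `onset_s`, `offset_s`.
#' @param env The [band_envelope()] the events were detected on.
#' @return The input with `amplitude_uv` and `peak_freq_hz` filled.
#' @export
spindle_features <- function(spindles, env) {
  fs <- env$fs
  n <- length(env$values)
  amp <- peakf <- rep(NA_real_, nrow(spindles))
  for (i in seq_len(nrow(spindles))) {
    i0 <- max(1L, floor(spindles$onset_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(spindles$offset_s[i] * fs))
    if (i1 <= i0) next
    amp[i] <- max(env$values[i0:i1])
    seg <- env$filtered[i0:i1]
    nfft <- 8L * 2^ceiling(log2(length(seg)))
    spec <- Mod(stats::fft(c(seg * signal::hanning(length(seg)),
                             numeric(nfft - length(seg)))))^2
    freqs <- (seq_len(nfft) - 1) * fs / nfft
    in_band <- freqs >= env$band[1] & freqs <= env$band[2]
    peakf[i] <- freqs[in_band][which.max(spec[in_band])]
  }
  spindles$amplitude_uv <- amp
  spindles$peak_freq_hz <- peakf
  spindles
}

#' Per-stage spindle rates
#'
#' Spindle count divided by artifact-free minutes in each stage.
#'
#' @param spindles A [detect_spindles()] table with a `stage` column (or a
#'   ground-truth table).
#' @param hyp A [hypnogram()].
#' @param mask Optional [artifact_mask()].
#' @param stages Stages to tabulate (default N2 and N3).
#' @return Tibble with `stage`, `n_spindles`, `minutes`, `rate_per_min`.
#' @export
spindle_rates <- function(spindles, hyp, mask = NULL, stages = c("N2", "N3")) {
  purrr::map_dfr(stages, function(st) {
    mins <- artifact_free_duration(hyp, mask, st) / 60
    n_sp <- sum(stage_at(hyp, spindles$onset_s) %in% st &
                  !point_in_intervals(spindles$onset_s, mask))
    tibble::tibble(
      stage = st, n_spindles = n_sp, minutes = mins,
      rate_per_min = if (mins > 0) n_sp / mins else NA_real_
    )
  })
}
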