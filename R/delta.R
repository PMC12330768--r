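# Delta-band (0.5-4 Hz) power time series and its aggregation over
# one-minute artifact-free NREM windows together with twitch counts — the
# unit of analysis of the delta-twitch mixed model.

#' Delta-band power time series
#'
#' Squared magnitude of the analytic signal of the 0.5-4 Hz band-passed
#' channel: instantaneous delta power in uV^2 at every sample.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label (default `"C3"`).
#' @param band Band edges in Hz.
#' @return List of class `power_series`: `values` (uV^2), `fs`, `channel`,
#'   `band`.
#' @export
delta_power_series <- function(rec, channel = "C3", band = c(0.5, 4)) {
  x <- rec_channel(rec, channel)
  filt <- fft_bandpass(x, rec$fs, band[1], band[2], trans = min(1, band[1]))
  structure(
    list(values = Mod(analytic_signal(filt))^2, fs = rec$fs,
         channel = channel, band = band),
    class = "power_series"
  )
}

#' Tile artifact-free NREM runs into one-minute windows
#'
#' Each maximal contiguous NREM run (N2 and/or N3 with no intervening wake,
#' N1, or REM) is tiled left-to-right into `width`-second windows; a
#' remainder shorter than `width` is dropped, as is any window that
#' intersects the artifact mask. Windows may span N2-N3 transitions; the
#' stage label is the majority stage within the window.
#'
#' @param hyp A [hypnogram()].
#' @param mask Optional [artifact_mask()].
#' @param width Window width in seconds (default 60).
#' @return Tibble with `window_start_s`, `window_end_s`, `stage_label`.
#' @export
tile_nrem_windows <- function(hyp, mask = NULL, width = 60) {
  runs <- stage_runs(hyp, collapse = c("N2", "N3"))
  runs <- runs[runs$stage == "N2+N3", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(runs))) {
    if (runs$end_s[i] - runs$start_s[i] < width) next
    starts <- seq(runs$start_s[i], runs$end_s[i] - width, by = width)
    for (s0 in starts) {
      if (!is.null(mask) && interval_overlap(s0, s0 + width, mask) > 0) next
      mid <- seq(s0, s0 + width, length.out = 61)[-61] + width / 120
      st <- stage_at(hyp, mid)
      tab <- table(st)
      out[[length(out) + 1L]] <- tibble::tibble(
        window_start_s = s0, window_end_s = s0 + width,
        stage_label = names(tab)[which.max(tab)]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(window_start_s = numeric(0),
                          window_end_s = numeric(0),
                          stage_label = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Window-level delta power and twitch counts
#'
#' For each window: the mean of the delta power samples inside it, and the
#' number of twitch onsets in `[start, end)` (membership by onset time).
#'
#' @param power A [delta_power_series()].
#' @param twitches Twitch train tibble with `onset_s`.
#' @param windows A [tile_nrem_windows()] table.
#' @param infant_id Optional identifier copied into the output.
#' @return Tibble with `infant_id`, `window_start_s`, `mean_delta_uv2`,
#'   `n_twitches`, `stage_label`.
#' @export
build_window_table <- function(power, twitches, windows,
                               infant_id = NA_character_) {
  fs <- power$fs
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    s0 <- windows$window_start_s[i]; s1 <- windows$window_end_s[i]
    i0 <- floor(s0 * fs) + 1L
    i1 <- min(length(power$values), floor(s1 * fs))
    tibble::tibble(
      infant_id = infant_id,
      window_start_s = s0,
      mean_delta_uv2 = mean(power$values[i0:i1]),
      n_twitches = sum(twitches$onset_s >= s0 & twitches$onset_s < s1),
      stage_label = windows$stage_label[i]
    )
  })
}
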