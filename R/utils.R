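# Internal numeric helpers shared across modules.

#' Analytic signal and amplitude envelope
#'
#' Computes the discrete analytic signal of a real vector by the standard
#' frequency-domain construction (negative frequencies zeroed, positive
#' frequencies doubled), from which the instantaneous amplitude envelope is
#' `Mod(analytic_signal(x))`.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Zero-phase Butterworth band-pass
#'
#' Forward-backward (zero-phase) filtering with a Butterworth design. Very low
#' normalized band edges (slow bands at high sampling rates) use a cascade of
#' a high-pass and a low-pass section, which is numerically better conditioned
#' than a single narrow band-pass prototype.
#'
#' @param x numeric vector
#' @param fs sampling rate (samples/s)
#' @param low,high band edges in Hz
#' @param order filter order per section
#' @keywords internal
bandpass_zerophase <- function(x, fs, low, high, order = 4L) {
  stopifnot(low > 0, high > low, high < fs / 2)
  nyq <- fs / 2
  hp <- signal::butter(min(order, 2L), low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, as.numeric(x)))
}

#' Zero-phase FFT band-pass with unity pass band
#'
#' Frequency-domain filtering: gain exactly 1 inside the band, 0 outside,
#' with raised-cosine transition ramps centered on the band edges. Used for
#' the narrow analysis bands (spindle 11-15 Hz, delta 0.5-4 Hz) where an
#' IIR design would attenuate the pass band itself; exactly zero-phase.
#'
#' @param x numeric vector
#' @param fs sampling rate (samples/s)
#' @param low,high band edges in Hz
#' @param trans transition ramp full width (Hz); capped at the lower edge
#' @keywords internal
fft_bandpass <- function(x, fs, low, high, trans = 1) {
  n <- length(x)
  if (n == 0L) return(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency
  ramp <- function(fr, edge, width, rising) {
    g <- (fr - (edge - width / 2)) / width
    g <- pmin(1, pmax(0, g))
    g <- 0.5 - 0.5 * cos(pi * g)
    if (rising) g else 1 - g
  }
  t_lo <- min(trans, low)                    # keep the ramp above 0 Hz
  gain <- ramp(f, low, t_lo, TRUE) * ramp(f, high, trans, FALSE)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Centered moving-average smoother (odd window), edges padded by replication.
moving_average <- function(x, width_s, fs) {
  k <- max(1L, round(width_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1):(h + length(x))]
}

# Child-seed derivation: deterministic, keeps values in [1, 2^31 - 2].
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(i) * 16807) %% 2147483646 + 1)
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Total length of the intersection of [a0, a1) with a set of half-open
# intervals given as a two-column matrix/data frame (start, end).
interval_overlap <- function(a0, a1, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  lo <- pmax(a0, intervals[[1]])
  hi <- pmin(a1, intervals[[2]])
  sum(pmax(0, hi - lo))
}

# TRUE for each point that falls inside any half-open [start, end) interval.
point_in_intervals <- function(x, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(x)))
  }
  starts <- intervals[[1]]
  ends <- intervals[[2]]
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  idx <- findInterval(x, starts)
  res <- idx > 0
  res[res] <- x[res] < ends[idx[res]]
  res
}

# Merge sorted half-open intervals, dropping empties.
merge_intervals <- function(start, end) {
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  out_s <- start[1]; out_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= tail(out_e, 1)) {
      out_e[length(out_e)] <- max(tail(out_e, 1), end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  tibble::tibble(start_s = out_s, end_s = out_e)
}
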