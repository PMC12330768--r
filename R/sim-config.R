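# Generator configuration. The defaults are the planted "truths" of the
# synthetic cohort: group-mean stage durations, stage-conditional twitch and
# burst rates, spindle rates/frequency/amplitude, the delta variance split,
# and the fixed effects of the delta-twitch mixed model. Every pipeline stage
# is validated by recovering these values from simulated data.

#' Synthetic-cohort generator configuration
#'
#' Returns a validated list of generator parameters. All rates are per
#' minute, times in seconds, amplitudes in microvolts, powers in
#' microvolts squared. Stage maps are named vectors over a subset of
#' `W, N1, N2, N3, REM`; a missing stage means rate zero.
#'
#' @param n_infants Number of infants in a cohort.
#' @param epoch_len Hypnogram epoch length (s).
#' @param stage_mean_minutes Expected total minutes per stage and nap.
#' @param mean_bout_epochs Mean stage-bout length in epochs (geometric bouts).
#' @param twitch_rate Stage-conditional twitch rates (events/min).
#' @param burst_rate Stage-conditional twitch-burst rates (bursts/min).
#' @param prop_in_burst Fraction of twitches that are burst members, per stage.
#' @param twitch_dur_mean,twitch_dur_sd Twitch duration distribution (s).
#' @param body_part_weights Sampling probabilities over body parts.
#' @param rem_rate Rapid-eye-movement rate during REM sleep (events/min).
#' @param spindle_rate Stage-conditional spindle rates (events/min).
#' @param spindle_freq_hz Carrier frequency mean and sd (Hz).
#' @param spindle_amp_uv Peak spindle amplitude (uV).
#' @param spindle_dur_s Spindle duration range (s).
#' @param spindle_min_gap_s Minimum offset-to-onset gap between planted
#'   spindles (s); keeps planted events well separated for the detector.
#' @param delta_grand_mean Grand-mean delta power (uV^2).
#' @param delta_stage_scale Stage multipliers on delta power.
#' @param delta_fluct_sd SD of the slow log-amplitude fluctuation of delta.
#' @param icc_delta Planted intraclass correlation of window-level delta.
#' @param delta_within_sd Within-infant SD of window-level delta (uV^2).
#' @param beta0,beta_within,beta_between Mixed-model fixed effects
#'   (twitches per window; slopes per 100 uV^2).
#' @param twitch_intercept_sd SD of the infant random intercept (twitches).
#' @param twitch_resid_sd Residual SD of window twitch counts (twitches).
#' @param n_windows Windows per infant in the window-level generator.
#' @param p_twitch_given_spindle Planted P(Twitch | Spindle) per stage.
#' @param noise_color_exponent 1/f slope of the background noise.
#' @param noise_sd_uv Broadband background-noise SD (uV).
#' @param fs Sampling rate of synthesized EEG (samples/s).
#' @param channels Channel labels synthesized.
#' @param artifacts_per_hour Rate of planted movement-artifact intervals.
#' @param artifact_dur_s Artifact duration range (s).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_infants = 21,
    epoch_len = 30,
    stage_mean_minutes = c(REM = 5.44, N2 = 4.87, N3 = 16.25),
    mean_bout_epochs = c(REM = 6, N2 = 4, N3 = 10),
    twitch_rate = c(N2 = 13.45, N3 = 5.68, REM = 13.70),
    burst_rate = c(REM = 3.33, N2 = 2.58, N3 = 1.22),
    prop_in_burst = c(REM = 0.65, N2 = 0.63, N3 = 0.48),
    twitch_dur_mean = 0.44,
    twitch_dur_sd = 0.15,
    body_part_weights = c(
      fingers = 0.28, toes = 0.22, face = 0.14,
      arm = 0.10, leg = 0.10, wrist = 0.08, ankle = 0.08
    ),
    rem_rate = 8,
    spindle_rate = c(N2 = 3.50, N3 = 3.38),
    spindle_freq_hz = c(mean = 13.15, sd = 0.09),
    spindle_amp_uv = 20,
    spindle_dur_s = c(1, 2.5),
    spindle_min_gap_s = 2,
    delta_grand_mean = 1100,
    delta_stage_scale = c(W = 0.2, N1 = 0.4, N2 = 0.55, N3 = 1.13, REM = 0.3),
    delta_fluct_sd = 0.3,
    icc_delta = 0.57,
    delta_within_sd = 150,
    beta0 = 6.07,
    beta_within = -0.93,
    beta_between = -0.01,
    twitch_intercept_sd = 1.2,
    twitch_resid_sd = 2.2,
    n_windows = 20,
    p_twitch_given_spindle = c(N2 = 0.51, N3 = 0.26),
    noise_color_exponent = 1.0,
    noise_sd_uv = 3,
    fs = 250,
    channels = c("C3", "F3", "P3"),
    artifacts_per_hour = 0,
    artifact_dur_s = c(2, 10)) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

check_stage_map <- function(x, name, min = 0, max = Inf) {
  if (length(x) == 0) return(invisible())
  if (is.null(names(x)) || !all(names(x) %in% SLEEP_STAGES)) {
    stop(name, " must be named with stages among ",
         paste(SLEEP_STAGES, collapse = ", "))
  }
  if (any(x < min) || any(x > max)) {
    stop(name, " values must lie in [", min, ", ", max, "]")
  }
  invisible()
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_infants >= 1, epoch_len > 0, fs >= 100)
    check_stage_map(stage_mean_minutes, "stage_mean_minutes")
    check_stage_map(mean_bout_epochs, "mean_bout_epochs", min = 1e-9)
    check_stage_map(twitch_rate, "twitch_rate")
    check_stage_map(burst_rate, "burst_rate")
    check_stage_map(prop_in_burst, "prop_in_burst", max = 1)
    check_stage_map(spindle_rate, "spindle_rate")
    check_stage_map(p_twitch_given_spindle, "p_twitch_given_spindle", max = 1)
    stopifnot(
      twitch_dur_mean > 0, twitch_dur_sd > 0,
      all(body_part_weights >= 0), sum(body_part_weights) > 0,
      spindle_amp_uv > 0, length(spindle_dur_s) == 2,
      spindle_dur_s[1] > 0, diff(spindle_dur_s) >= 0,
      delta_grand_mean > 0, delta_within_sd > 0,
      icc_delta > 0, icc_delta < 1,
      twitch_resid_sd > 0, twitch_intercept_sd >= 0,
      n_windows >= 2, noise_sd_uv >= 0
    )
  })
  # The burst/single mixture must be solvable: the mean burst size implied by
  # (rate, burst_rate, prop_in_burst) has to be at least 2.
  for (st in names(cfg$burst_rate)) {
    b <- cfg$burst_rate[[st]]
    if (b <= 0) next
    r <- cfg$twitch_rate[st]
    p <- cfg$prop_in_burst[st]
    if (!is.na(r) && r == 0) next   # stage disabled entirely
    if (is.na(r) || is.na(p)) {
      stop("burst_rate for ", st, " needs twitch_rate and prop_in_burst")
    }
    m <- p * r / b
    if (m < 2) {
      stop(
        "inconsistent burst parameters for ", st, ": implied mean burst size ",
        "prop_in_burst*twitch_rate/burst_rate = ", signif(m, 4),
        " is < 2; lower burst_rate or raise prop_in_burst/twitch_rate"
      )
    }
  }
  invisible(cfg)
}
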