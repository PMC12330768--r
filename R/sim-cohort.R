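# Synthetic-cohort generators. Every generator is a deterministic function of
# (config, seed): per-infant seeds are derived with a fixed hash so cohorts
# are reproducible element-wise.

#' Simulate a nap hypnogram
#'
#' Stage structure is a semi-Markov chain with geometric bout lengths: for
#' each stage the number of bouts is Poisson with mean
#' `total_epochs / mean_bout_epochs`, each bout length is geometric with the
#' configured mean, and bouts are interleaved in random order. Expected
#' per-stage totals equal `stage_mean_minutes` exactly; as in real naps, a
#' stage can be absent for a given infant.
#'
#' @param config A [sim_config()].
#' @param infant_seed Integer seed for this infant.
#' @return A [hypnogram()].
#' @export
sim_hypnogram <- function(config, infant_seed) {
  el <- config$epoch_len
  run_seeded(infant_seed, {
    bouts <- list()
    for (st in names(config$stage_mean_minutes)) {
      tot_epochs <- config$stage_mean_minutes[[st]] * 60 / el
      if (tot_epochs <= 0) next
      m <- config$mean_bout_epochs[st]
      if (is.na(m)) m <- 4
      n_bouts <- rpois(1, tot_epochs / m)
      if (n_bouts == 0) next
      lens <- 1L + rgeom(n_bouts, prob = 1 / m)
      bouts <- c(bouts, lapply(lens, function(l) rep(st, l)))
    }
    if (length(bouts) == 0L) return(hypnogram(character(0), epoch_len = el))
    bouts <- bouts[sample.int(length(bouts))]
    hypnogram(unlist(bouts), epoch_len = el)
  })
}

# Cluster-process parameters for one stage: mean burst size, burst-cluster
# probability, and the exponential rate of the (0.5 s shifted) inter-cluster
# gaps that reproduces the aggregate twitch rate by renewal-reward.
twitch_process_params <- function(rate, burst_rate, prop, gap = 0.5,
                                  within_gap_mean = 0.25) {
  if (is.na(burst_rate) || burst_rate <= 0 || is.na(prop) || prop <= 0) {
    # Pure single process with >gap spacing.
    mean_cycle <- 60 / rate
    if (mean_cycle <= gap) stop("twitch rate too high for ", gap, " s spacing")
    return(list(mean_size = 1, p_burst = 0, exp_mean = mean_cycle - gap))
  }
  m <- prop * rate / burst_rate          # mean burst size (>= 2 by validation)
  p_burst <- prop / (m * (1 - prop) + prop)
  e_tw <- p_burst * m + (1 - p_burst)    # twitches per cluster
  mean_cycle <- e_tw / (rate / 60)       # seconds per cluster
  span <- within_gap_mean * (m - 1)      # mean burst span
  exp_mean <- mean_cycle - gap - p_burst * span
  if (exp_mean <= 0) {
    stop("inconsistent twitch/burst parameters: no positive inter-cluster gap")
  }
  list(mean_size = m, p_burst = p_burst, exp_mean = exp_mean)
}

sim_cluster_onsets <- function(start_s, end_s, pars, gap = 0.5) {
  onsets <- numeric(0)
  t <- start_s + rexp(1, 1 / pars$exp_mean)
  while (t < end_s) {
    if (pars$p_burst > 0 && runif(1) < pars$p_burst) {
      k <- 2L + rgeom(1, prob = 1 / (pars$mean_size - 1))
      gaps <- runif(k - 1L, 0.05, 0.45)
      ev <- t + c(0, cumsum(gaps))
      ev <- ev[ev < end_s]
    } else {
      ev <- t
    }
    onsets <- c(onsets, ev)
    t <- max(ev) + gap + rexp(1, 1 / pars$exp_mean)
  }
  onsets
}

#' Simulate a stage-conditional twitch train
#'
#' Twitches arrive as a burst/single cluster process per sleep stage: burst
#' clusters (>= 2 twitches with within-burst onset gaps < 0.5 s) and single
#' twitches, with cluster spacing > 0.5 s so planted clusters are exactly the
#' bursts the `<0.5 s` chaining rule recovers. Cluster-type probabilities and
#' spacing are solved from the configured aggregate rate, burst rate, and
#' proportion-in-burst, so all three are matched in expectation. No events
#' are generated during wake or inside artifact intervals.
#'
#' @param hyp A [hypnogram()].
#' @param config A [sim_config()].
#' @param infant_seed Integer seed.
#' @param mask Optional [artifact_mask()]; events overlapping it are dropped.
#' @return Tibble with `onset_s`, `duration_s`, `body_part`, `kind = "twitch"`.
#' @export
sim_twitch_train <- function(hyp, config, infant_seed, mask = NULL) {
  if (nrow(hyp) == 0L) return(empty_event_train())
  run_seeded(infant_seed, {
    out <- list()
    for (st in setdiff(names(config$twitch_rate), "W")) {
      rate <- config$twitch_rate[[st]]
      if (rate <= 0) next
      pars <- twitch_process_params(
        rate, config$burst_rate[st], config$prop_in_burst[st]
      )
      runs <- stage_runs(hyp, stages = st)
      for (i in seq_len(nrow(runs))) {
        on <- sim_cluster_onsets(runs$start_s[i], runs$end_s[i], pars)
        if (length(on) > 0) out[[length(out) + 1L]] <- on
      }
    }
    onsets <- sort(unlist(out))
    if (length(onsets) == 0L) return(empty_event_train())
    shape <- (config$twitch_dur_mean / config$twitch_dur_sd)^2
    dur <- stats::rgamma(length(onsets), shape = shape,
                         rate = shape / config$twitch_dur_mean)
    bp <- sample(names(config$body_part_weights), length(onsets),
                 replace = TRUE,
                 prob = config$body_part_weights / sum(config$body_part_weights))
    tr <- tibble::tibble(
      onset_s = onsets, duration_s = dur, body_part = bp, kind = "twitch"
    )
    if (!is.null(mask) && nrow(mask) > 0) {
      tr <- tr[!point_in_intervals(tr$onset_s, mask), , drop = FALSE]
    }
    tr
  })
}

empty_event_train <- function(kind = "twitch") {
  tibble::tibble(
    onset_s = numeric(0), duration_s = numeric(0),
    body_part = character(0), kind = character(0)
  )
}

#' Simulate rapid eye movements during REM sleep
#'
#' Poisson process at `config$rem_rate` within REM runs; durations are below
#' 1 s, matching the scoring definition of a rapid eye movement.
#'
#' @inheritParams sim_twitch_train
#' @return Tibble with `onset_s`, `duration_s`, `kind = "rem"`.
#' @export
sim_rem_train <- function(hyp, config, infant_seed, mask = NULL) {
  run_seeded(infant_seed, {
    runs <- stage_runs(hyp, stages = "REM")
    onsets <- numeric(0)
    for (i in seq_len(nrow(runs))) {
      span <- runs$end_s[i] - runs$start_s[i]
      n <- rpois(1, config$rem_rate * span / 60)
      onsets <- c(onsets, sort(runif(n, runs$start_s[i], runs$end_s[i])))
    }
    tr <- tibble::tibble(
      onset_s = sort(onsets),
      duration_s = runif(length(onsets), 0.1, 0.9),
      body_part = NA_character_,
      kind = "rem"
    )
    if (!is.null(mask) && nrow(mask) > 0) {
      tr <- tr[!point_in_intervals(tr$onset_s, mask), , drop = FALSE]
    }
    tr
  })
}

#' Simulate ground-truth spindle events
#'
#' Planted spindles arrive per stage as a renewal process with a refractory
#' offset-to-onset gap of at least `spindle_min_gap_s` (so events stay well
#' separated for detector-recall evaluation); the exponential part of the gap
#' is sized so the stage rate is matched in expectation. Durations are uniform
#' on `spindle_dur_s`, carrier frequencies Normal(`spindle_freq_hz`), and peak
#' amplitudes jittered within 10% of `spindle_amp_uv`.
#'
#' @inheritParams sim_twitch_train
#' @return Tibble with `onset_s`, `offset_s`, `freq_hz`, `amp_uv`, `stage`.
#' @export
sim_spindle_events <- function(hyp, config, infant_seed, mask = NULL) {
  run_seeded(infant_seed, {
    out <- list()
    mean_dur <- mean(config$spindle_dur_s)
    for (st in names(config$spindle_rate)) {
      rate <- config$spindle_rate[[st]]
      if (rate <= 0) next
      exp_mean <- 60 / rate - config$spindle_min_gap_s - mean_dur
      if (exp_mean <= 0) {
        stop("spindle_rate for ", st, " too high for spindle_min_gap_s")
      }
      runs <- stage_runs(hyp, stages = st)
      for (i in seq_len(nrow(runs))) {
        t <- runs$start_s[i] + rexp(1, 1 / exp_mean)
        while (TRUE) {
          dur <- runif(1, config$spindle_dur_s[1], config$spindle_dur_s[2])
          if (t + dur > runs$end_s[i]) break
          out[[length(out) + 1L]] <- tibble::tibble(
            onset_s = t, offset_s = t + dur,
            freq_hz = rnorm(1, config$spindle_freq_hz[["mean"]],
                            config$spindle_freq_hz[["sd"]]),
            amp_uv = config$spindle_amp_uv * runif(1, 0.9, 1.1),
            stage = st
          )
          t <- t + dur + config$spindle_min_gap_s + rexp(1, 1 / exp_mean)
        }
      }
    }
    sp <- dplyr::bind_rows(out)
    if (nrow(sp) == 0L) {
      sp <- tibble::tibble(
        onset_s = numeric(0), offset_s = numeric(0),
        freq_hz = numeric(0), amp_uv = numeric(0), stage = character(0)
      )
    } else {
      sp <- dplyr::arrange(sp, .data$onset_s)
    }
    if (!is.null(mask) && nrow(mask) > 0) {
      drop <- vapply(seq_len(nrow(sp)), function(i) {
        interval_overlap(sp$onset_s[i], sp$offset_s[i], mask) > 0
      }, logical(1))
      sp <- sp[!drop, , drop = FALSE]
    }
    sp
  })
}

# 1/f^alpha noise via spectral shaping, scaled to a target SD.
pink_noise <- function(n, sd_uv, exponent = 1) {
  if (n == 0L || sd_uv <= 0) return(numeric(n))
  white <- rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid DC blow-up
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequency
  spec <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd_uv
}

#' Synthesize multichannel EEG with planted spindles and delta
#'
#' Each channel is the sum of pink (1/f) background noise, a 0.5-4 Hz
#' narrowband delta component whose amplitude follows a per-second schedule
#' (stage-dependent scale times a slow log-normal fluctuation, so one-minute
#' windows genuinely vary), and Hann-windowed sinusoidal spindle bursts at
#' the planted carrier frequencies. The same spindle events are planted into
#' every synthesized channel.
#'
#' @inheritParams sim_twitch_train
#' @param spindles Optional precomputed [sim_spindle_events()] table; planted
#'   as given (generated internally when `NULL`).
#' @return List with `recording` ([eeg_recording()]), `spindles`
#'   (ground-truth table), and `delta_schedule` (per-second target delta
#'   power, uV^2).
#' @export
sim_eeg <- function(hyp, config, infant_seed, spindles = NULL, mask = NULL) {
  dur_s <- hyp_duration(hyp)
  fs <- config$fs
  n <- round(dur_s * fs)
  if (is.null(spindles)) {
    spindles <- sim_spindle_events(hyp, config, child_seed(infant_seed, 91),
                                   mask = mask)
  }
  run_seeded(child_seed(infant_seed, 92), {
    # Per-second target delta power (shared across channels).
    secs <- seq_len(max(1, ceiling(dur_s)))
    stage_sec <- stage_at(hyp, secs - 1)
    scale <- config$delta_stage_scale[stage_sec]
    scale[is.na(scale)] <- 0.2
    knot_t <- seq(0, dur_s, by = 30)
    z <- rnorm(length(knot_t))
    zf <- approx(knot_t, z, xout = secs - 0.5, rule = 2)$y
    s <- config$delta_fluct_sd
    fluct <- exp(s * zf - s^2)
    sched_power <- config$delta_grand_mean * as.numeric(scale) * fluct^2
    sigma_sec <- sqrt(sched_power / 2)
    sigma_samp <- approx(secs - 0.5, sigma_sec, xout = (seq_len(n) - 0.5) / fs,
                         rule = 2)$y

    # Spindle waveform, shared across channels.
    spind_wave <- numeric(n)
    for (i in seq_len(nrow(spindles))) {
      i0 <- floor(spindles$onset_s[i] * fs) + 1
      i1 <- min(n, floor(spindles$offset_s[i] * fs))
      if (i1 <= i0) next
      m <- i1 - i0 + 1
      tt <- (seq_len(m) - 1) / fs
      hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m)))
      phase <- runif(1, 0, 2 * pi)
      spind_wave[i0:i1] <- spind_wave[i0:i1] +
        spindles$amp_uv[i] * hann * sin(2 * pi * spindles$freq_hz[i] * tt + phase)
    }

    samples <- matrix(0, nrow = length(config$channels), ncol = n)
    for (ch in seq_along(config$channels)) {
      noise <- pink_noise(n, config$noise_sd_uv, config$noise_color_exponent)
      delta_raw <- fft_bandpass(rnorm(n), fs, 0.5, 4, trans = 0.5)
      delta_raw <- delta_raw / stats::sd(delta_raw)
      samples[ch, ] <- noise + delta_raw * sigma_samp + spind_wave
    }
    list(
      recording = eeg_recording(samples, fs, config$channels),
      spindles = spindles,
      delta_schedule = tibble::tibble(
        second = secs - 1, stage = stage_sec, target_power_uv2 = sched_power
      )
    )
  })
}

#' Plant twitch-spindle coupling
#'
#' Rewrites a twitch train so that, within each stage named in
#' `p_twitch_given_spindle`, the realized conditional probability
#' P(Twitch | Spindle) equals the planted value: exactly `round(p * n)`
#' spindles receive a twitch onset inside their interval (twitches are
#' relocated, or inserted with a warning if too few are available), and
#' twitch onsets are relocated out of the remaining spindles. Total twitch
#' count per stage is preserved unless insertion is required. A planted
#' probability of 0 leaves the train untouched (the independent null).
#'
#' @param twitches Twitch train ([sim_twitch_train()] output).
#' @param spindles Spindle table with `onset_s`, `offset_s` (ground truth or
#'   detected) from the same infant.
#' @param hyp The infant's [hypnogram()].
#' @param config A [sim_config()]; `p_twitch_given_spindle` is used.
#' @param infant_seed Integer seed.
#' @param mask Optional [artifact_mask()]; relocated twitches avoid it.
#' @return Twitch train tibble sorted by onset.
#' @export
plant_coupling <- function(twitches, spindles, hyp, config, infant_seed,
                           mask = NULL) {
  p_map <- config$p_twitch_given_spindle
  run_seeded(child_seed(infant_seed, 93), {
    tw <- twitches
    for (st in names(p_map)) {
      p <- p_map[[st]]
      if (p <= 0) next
      sp <- spindles[stage_at(hyp, spindles$onset_s) %in% st, , drop = FALSE]
      n_sp <- nrow(sp)
      if (n_sp == 0L) next
      k <- round(p * n_sp)
      sel <- sort(sample.int(n_sp, k))
      sp_sel <- sp[sel, , drop = FALSE]
      sp_un <- sp[-sel, , drop = FALSE]
      in_stage <- which(stage_at(hyp, tw$onset_s) %in% st)
      sp_iv <- sp[, c("onset_s", "offset_s")]
      in_any <- point_in_intervals(tw$onset_s, sp_iv)

      # Donors: stage twitches currently outside every spindle.
      donors <- setdiff(in_stage[!in_any[in_stage]], integer(0))
      donors <- sample(donors)
      need <- which(vapply(seq_len(nrow(sp_sel)), function(i) {
        !any(tw$onset_s[in_stage] >= sp_sel$onset_s[i] &
               tw$onset_s[in_stage] < sp_sel$offset_s[i])
      }, logical(1)))
      for (i in need) {
        pos <- runif(1, sp_sel$onset_s[i], sp_sel$offset_s[i] - 1e-6)
        if (length(donors) > 0) {
          tw$onset_s[donors[1]] <- pos
          donors <- donors[-1]
        } else {
          warning("plant_coupling: inserting twitches (donors exhausted) in ", st)
          tw <- dplyr::bind_rows(tw, tibble::tibble(
            onset_s = pos,
            duration_s = config$twitch_dur_mean,
            body_part = sample(names(config$body_part_weights), 1),
            kind = "twitch"
          ))
        }
      }

      # Evacuate non-selected spindles: relocate offending onsets to stage
      # time outside every spindle interval.
      if (nrow(sp_un) > 0) {
        off <- which(point_in_intervals(tw$onset_s, sp_iv) &
                       stage_at(hyp, tw$onset_s) %in% st)
        bad <- off[point_in_intervals(tw$onset_s[off],
                                      sp_un[, c("onset_s", "offset_s")])]
        if (length(bad) > 0) {
          runs <- stage_runs(hyp, stages = st)
          for (j in bad) {
            for (try in 1:200) {
              ri <- sample.int(nrow(runs), 1,
                               prob = runs$end_s - runs$start_s)
              pos <- runif(1, runs$start_s[ri], runs$end_s[ri])
              if (!any(pos >= sp$onset_s & pos < sp$offset_s) &&
                    !any(point_in_intervals(pos, mask))) {
                tw$onset_s[j] <- pos
                break
              }
            }
          }
        }
      }
    }
    dplyr::arrange(tw, .data$onset_s)
  })
}

#' Generate the window-level delta/twitch dataset directly
#'
#' The mixed model's unit of analysis, generated at the statistical level
#' (no EEG): per infant, a mean delta power drawn around the grand mean and
#' per-window deviations with the configured intraclass-correlation split;
#' window twitch counts are a rounded, floored-at-zero Gaussian response with
#' the configured fixed effects (slopes per 100 uV^2), infant random
#' intercept, and residual.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble with `infant_id`, `window_start_s`, `mean_delta_uv2`,
#'   `n_twitches`, `stage_label`.
#' @export
sim_window_data <- function(config, seed) {
  stopifnot(config$n_infants >= 2)
  sd_w <- config$delta_within_sd
  sd_b <- sd_w * sqrt(config$icc_delta / (1 - config$icc_delta))
  run_seeded(seed, {
    rows <- lapply(seq_len(config$n_infants), function(i) {
      nw <- config$n_windows
      mean_i <- rnorm(1, config$delta_grand_mean, sd_b)
      dev <- rnorm(nw, 0, sd_w)
      dev <- dev - mean(dev)          # within-deviations sum to zero
      delta <- mean_i + dev
      u0 <- rnorm(1, 0, config$twitch_intercept_sd)
      mu <- config$beta0 +
        config$beta_within * dev / 100 +
        config$beta_between * (mean_i - config$delta_grand_mean) / 100 +
        u0
      y <- pmax(0, round(mu + rnorm(nw, 0, config$twitch_resid_sd)))
      tibble::tibble(
        infant_id = sprintf("inf%02d", i),
        window_start_s = (seq_len(nw) - 1) * 60,
        mean_delta_uv2 = delta,
        n_twitches = as.integer(y),
        stage_label = "NREM"
      )
    })
    dplyr::bind_rows(rows)
  })
}

sim_artifacts <- function(hyp, config, infant_seed) {
  dur <- hyp_duration(hyp)
  run_seeded(child_seed(infant_seed, 94), {
    n <- rpois(1, config$artifacts_per_hour * dur / 3600)
    if (n == 0) return(artifact_mask())
    starts <- sort(runif(n, 0, dur))
    lens <- runif(n, config$artifact_dur_s[1], config$artifact_dur_s[2])
    artifact_mask(starts, pmin(dur, starts + lens))
  })
}

#' Simulate one infant
#'
#' Hypnogram, artifact mask, coupled twitch train, rapid eye movements,
#' ground-truth spindles, synthesized EEG, and the planted delta schedule.
#'
#' @param config A [sim_config()].
#' @param infant_id Identifier string.
#' @param infant_seed Integer seed.
#' @param eeg Synthesize the EEG matrix (set `FALSE` for event-level studies
#'   where only trains and ground truth are needed).
#' @return List of class `sim_infant`.
#' @export
sim_infant <- function(config, infant_id, infant_seed, eeg = TRUE) {
  hyp <- sim_hypnogram(config, child_seed(infant_seed, 1))
  mask <- sim_artifacts(hyp, config, infant_seed)
  spindles <- sim_spindle_events(hyp, config, child_seed(infant_seed, 2),
                                 mask = mask)
  twitches <- sim_twitch_train(hyp, config, child_seed(infant_seed, 3),
                               mask = mask)
  twitches <- plant_coupling(twitches, spindles, hyp, config, infant_seed,
                             mask = mask)
  rems <- sim_rem_train(hyp, config, child_seed(infant_seed, 4), mask = mask)
  out <- list(
    infant_id = infant_id, hypnogram = hyp, artifact_mask = mask,
    twitch_train = twitches, rem_train = rems,
    ground_truth_spindles = spindles
  )
  if (eeg && nrow(hyp) > 0) {
    e <- sim_eeg(hyp, config, infant_seed, spindles = spindles, mask = mask)
    out$recording <- e$recording
    out$delta_schedule <- e$delta_schedule
  }
  structure(out, class = "sim_infant")
}

#' Simulate a cohort of infants
#'
#' @param config A [sim_config()].
#' @param seed Master seed; per-infant seeds are derived deterministically.
#' @param eeg Synthesize EEG matrices (see [sim_infant()]).
#' @return List of class `sim_cohort` with elements `infants` and `config`.
#' @export
sim_cohort <- function(config = sim_config(), seed = 1, eeg = TRUE) {
  infants <- lapply(seq_len(config$n_infants), function(i) {
    sim_infant(config, sprintf("inf%02d", i), child_seed(seed, i * 1000), eeg = eeg)
  })
  structure(list(infants = infants, config = config, seed = seed),
            class = "sim_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `events.csv` (twitches and REMs), `hypnogram.csv`, `artifacts.csv`,
#' `ground_truth.json` (planted spindles and generator parameters), and one
#' `eeg_<id>.csv` matrix per infant (columns = channels, rows = samples;
#' first column is the sample index).
#'
#' @param cohort A [sim_cohort()].
#' @param dir Output directory (created if missing).
#' @param eeg Write the EEG matrices (large; default TRUE when present).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, eeg = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- dplyr::bind_rows(lapply(cohort$infants, function(inf) {
    dplyr::bind_rows(inf$twitch_train, inf$rem_train) |>
      dplyr::mutate(infant_id = inf$infant_id, channel = NA_character_)
  }))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  hyp <- dplyr::bind_rows(lapply(cohort$infants, function(inf) {
    tibble::tibble(infant_id = inf$infant_id,
                   epoch_index = inf$hypnogram$epoch,
                   stage = inf$hypnogram$stage)
  }))
  utils::write.csv(hyp, file.path(dir, "hypnogram.csv"), row.names = FALSE)
  art <- dplyr::bind_rows(lapply(cohort$infants, function(inf) {
    m <- inf$artifact_mask
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(infant_id = inf$infant_id, start_s = m$start_s, end_s = m$end_s)
  }))
  if (is.null(art) || nrow(art) == 0) {
    art <- tibble::tibble(infant_id = character(0), start_s = numeric(0),
                          end_s = numeric(0))
  }
  utils::write.csv(art, file.path(dir, "artifacts.csv"), row.names = FALSE)
  gt <- list(
    parameters = unclass(cohort$config),
    spindles = lapply(cohort$infants, function(inf) {
      c(list(infant_id = inf$infant_id), as.list(inf$ground_truth_spindles))
    })
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (eeg) {
    for (inf in cohort$infants) {
      if (is.null(inf$recording)) next
      m <- t(inf$recording$samples)
      colnames(m) <- inf$recording$channel_labels
      utils::write.csv(
        data.frame(sample = seq_len(nrow(m)), m, check.names = FALSE),
        file.path(dir, paste0("eeg_", inf$infant_id, ".csv")),
        row.names = FALSE
      )
    }
  }
  invisible(dir)
}
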