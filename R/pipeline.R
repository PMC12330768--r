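# End-to-end orchestration: simulate (or load) a cohort, detect spindles,
# compute delta windows, twitch metrics, coupling with shuffle nulls, fit
# the mixed model, and write the result tables plus a run manifest.

#' Pipeline run configuration
#'
#' Collects every analysis threshold with its conventional default: the
#' 11-15 Hz spindle band with 2x-median threshold and 1-s duration/gap
#' rules, the 0.5 s burst gap, 60-s NREM windows, +/-20-s perievent window
#' with 1-s bins, and 1000 shuffle permutations. Electrode groups are data
#' (config lists), defaulting to the synthesized channels. The configuration
#' round-trips losslessly through JSON.
#'
#' @param sim A [sim_config()] used when simulating (ignored for loaded
#'   cohorts).
#' @param channel Analysis channel for spindles and delta (default `"C3"`).
#' @param electrode_groups Named list of channel groups for group averages.
#' @param spindle_band,spindle_mult,spindle_min_dur,spindle_end_gap Spindle
#'   detector parameters.
#' @param burst_gap Burst chaining threshold (s).
#' @param window_width NREM window width (s).
#' @param perievent_half,perievent_bin Perievent window half-width and bin
#'   width (s).
#' @param n_perm Number of shuffle permutations.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), channel = "C3",
                       electrode_groups = list(central = c("C3"),
                                               frontal = c("F3")),
                       spindle_band = c(11, 15), spindle_mult = 2,
                       spindle_min_dur = 1, spindle_end_gap = 1,
                       burst_gap = 0.5, window_width = 60,
                       perievent_half = 20, perievent_bin = 1,
                       n_perm = 1000, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(spindle_mult > 0, spindle_min_dur > 0, spindle_end_gap > 0,
            burst_gap > 0, window_width > 0, n_perm >= 1)
  class(cfg) <- "run_config"
  cfg
}

analyze_infant <- function(inf, cfg) {
  hyp <- inf$hypnogram
  mask <- inf$artifact_mask
  out <- list(infant_id = inf$infant_id)
  tw <- inf$twitch_train

  out$rates <- purrr::map_dfr(c("N2", "N3", "REM"), function(st) {
    mins <- artifact_free_duration(hyp, mask, st) / 60
    tibble::tibble(
      infant_id = inf$infant_id, stage = st, minutes = mins,
      twitch_rate = if (mins > 0) suppressWarnings(stage_rate(tw, hyp, mask, st)) else NA_real_
    )
  })

  out$bursts <- purrr::map_dfr(c("N2", "N3", "REM"), function(st) {
    seg <- segment_bursts(tw, hyp, mask, stage = st, gap = cfg$burst_gap)
    mins <- artifact_free_duration(hyp, mask, st) / 60
    dplyr::mutate(burst_stats(seg, mins), infant_id = inf$infant_id, stage = st)
  })

  out$body_parts <- purrr::map_dfr(c("N2", "N3", "REM"), function(st) {
    bp <- body_part_proportions(tw, hyp, stage = st)
    if (nrow(bp) == 0) return(NULL)
    dplyr::mutate(bp, infant_id = inf$infant_id, stage = st)
  })

  out$itis <- purrr::map_dfr(c("N2", "N3", "REM"), function(st) {
    iv <- event_intervals(tw, hyp, mask, stage = st)
    if (length(iv) == 0) return(NULL)
    tibble::tibble(infant_id = inf$infant_id, stage = st, interval_s = iv)
  })

  if (!is.null(inf$recording)) {
    env <- band_envelope(inf$recording, cfg$channel, band = cfg$spindle_band)
    sp <- detect_spindles(env, mask = mask, mult = cfg$spindle_mult,
                          min_dur = cfg$spindle_min_dur,
                          end_gap = cfg$spindle_end_gap, hyp = hyp)
    out$spindles <- dplyr::mutate(tibble::as_tibble(sp),
                                  infant_id = inf$infant_id)
    out$spindle_rates <- dplyr::mutate(spindle_rates(sp, hyp, mask),
                                       infant_id = inf$infant_id)

    pw <- delta_power_series(inf$recording, cfg$channel)
    win <- tile_nrem_windows(hyp, mask, width = cfg$window_width)
    out$windows <- build_window_table(pw, tw, win, infant_id = inf$infant_id)

    segs_n2 <- stage_segments(hyp, mask, stage = "N2")
    segs_n3 <- stage_segments(hyp, mask, stage = "N3")
    out$coupling <- purrr::map_dfr(
      list(list(st = "N2", segs = segs_n2), list(st = "N3", segs = segs_n3)),
      function(x) {
        sp_st <- sp[!is.na(sp$stage) & sp$stage == x$st, , drop = FALSE]
        tw_st <- tw[stage_at(hyp, tw$onset_s) %in% x$st, , drop = FALSE]
        if (nrow(sp_st) < 3 || nrow(tw_st) < 3) return(NULL)
        res <- suppressWarnings(coupling_null(
          tw_st, sp_st, x$segs, shuffle = "spindles",
          n_perm = cfg$n_perm, seed = child_seed(cfg$seed, 7)
        ))
        dplyr::mutate(res, infant_id = inf$infant_id, stage = x$st,
                      channel = cfg$channel)
      }
    )
  }
  out
}

#' Run the full simulate-then-analyze pipeline
#'
#' Simulates (or accepts) a cohort, runs every analysis stage per infant,
#' assembles cohort-level tables (stage rates, bursts, body parts, interval
#' data, spindles and their rates, window-level delta/twitch data, coupling
#' summaries), fits the mixed model, and optionally writes CSV tables and a
#' JSON manifest (configuration, seed, package version) to
#' `config$out_dir`. Identical configuration and seed give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built [sim_cohort()]; simulated when `NULL`.
#' @return List of class `pipeline_result` with the tables above, the mixed
#'   model fit, and the manifest.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- sim_cohort(config$sim, seed = config$seed,
                         eeg = TRUE)
  }
  per <- lapply(cohort$infants, analyze_infant, cfg = config)
  gather <- function(name) {
    dplyr::bind_rows(purrr::map(per, name))
  }
  res <- list(
    rates = gather("rates"),
    bursts = gather("bursts"),
    body_parts = gather("body_parts"),
    itis = gather("itis"),
    spindles = gather("spindles"),
    spindle_rates = gather("spindle_rates"),
    windows = gather("windows"),
    coupling = gather("coupling")
  )
  if (nrow(res$windows) > 0 &&
      length(unique(res$windows$infant_id)) >= 2 &&
      sum(!is.na(res$windows$mean_delta_uv2)) >= 4) {
    dec <- decompose_delta(res$windows)
    res$model <- fit_delta_twitch(dec)
    res$model_fixed <- tidy(res$model)
    res$icc_delta <- delta_icc(res$windows)
    res$per_infant <- per_infant_ols(res$windows)
  }
  res$manifest <- list(
    seed = config$seed,
    n_perm = config$n_perm,
    channel = config$channel,
    n_infants = length(cohort$infants),
    package_version = as.character(utils::packageVersion("naptwitch")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("rates", "bursts", "body_parts", "itis", "spindles",
                 "spindle_rates", "windows", "coupling", "model_fixed",
                 "per_infant")) {
      tab <- res[[nm]]
      if (!is.null(tab) && nrow(tab) > 0) {
        utils::write.csv(tab, file.path(config$out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(res$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  infants:", x$manifest$n_infants, "\n")
  cat("  windows:", nrow(x$windows), " spindles:", nrow(x$spindles),
      " coupling rows:", nrow(x$coupling), "\n")
  if (!is.null(x$model_fixed)) {
    cat("  within-infant delta slope:",
        signif(x$model_fixed$estimate[x$model_fixed$term == "within_delta"], 3),
        "twitches per 100 uV^2\n")
  }
  invisible(x)
}
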