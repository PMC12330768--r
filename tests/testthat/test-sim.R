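test_that("generator configuration validates its parameter space", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(icc_delta = 1.2), "icc_delta")
  expect_error(sim_config(twitch_rate = c(Q5 = 3)), "stages among")
  expect_error(sim_config(prop_in_burst = c(N2 = 1.4, REM = 0.65, N3 = 0.48)),
               "prop_in_burst")
  # infeasible triple: implied mean burst size below 2
  expect_error(sim_config(burst_rate = c(REM = 9, N2 = 2.58, N3 = 1.22)),
               "mean burst size")
})

test_that("simulation is deterministic in (config, seed)", {
  cfg <- sim_config(n_infants = 2)
  c1 <- sim_cohort(cfg, seed = 3, eeg = FALSE)
  c2 <- sim_cohort(cfg, seed = 3, eeg = FALSE)
  expect_identical(c1$infants[[1]]$twitch_train, c2$infants[[1]]$twitch_train)
  expect_identical(c1$infants[[2]]$hypnogram, c2$infants[[2]]$hypnogram)
  expect_identical(c1$infants[[1]]$ground_truth_spindles,
                   c2$infants[[1]]$ground_truth_spindles)
  c3 <- sim_cohort(cfg, seed = 4, eeg = FALSE)
  expect_false(identical(c1$infants[[1]]$twitch_train,
                         c3$infants[[1]]$twitch_train))
})

test_that("degenerate configurations produce empty outputs", {
  cfg0 <- sim_config(stage_mean_minutes = c(REM = 0, N2 = 0, N3 = 0))
  expect_equal(nrow(sim_hypnogram(cfg0, 1)), 0)
  cfg_n3 <- sim_config(twitch_rate = c(N2 = 13.45, N3 = 0, REM = 13.7))
  h3 <- hypnogram(rep("N3", 40))
  expect_equal(nrow(sim_twitch_train(h3, cfg_n3, 1)), 0)
  cfg_sp0 <- sim_config(spindle_rate = c(N2 = 0, N3 = 0))
  expect_equal(nrow(sim_spindle_events(hypnogram(rep("N2", 40)), cfg_sp0, 1)), 0)
})

test_that("hypnogram stage totals match their planted means over seeds", {
  cfg <- sim_config()
  tot <- vapply(1:300, function(s) {
    h <- sim_hypnogram(cfg, s)
    c(sum(h$stage == "REM"), sum(h$stage == "N2"), sum(h$stage == "N3")) / 2
  }, numeric(3))
  mean_min <- rowMeans(tot)
  se <- apply(tot, 1, sd) / sqrt(ncol(tot))
  planted <- c(5.44, 4.87, 16.25)
  expect_true(all(abs(mean_min - planted) < 3 * se))
  # total sleep time is near the configured 26.6 min on average
  expect_equal(sum(mean_min), sum(planted), tolerance = 0.1)
})

test_that("events never fall in wake or inside artifact intervals", {
  cfg <- sim_config(artifacts_per_hour = 20)
  inf <- sim_infant(cfg, "x", 77, eeg = FALSE)
  st <- stage_at(inf$hypnogram, inf$twitch_train$onset_s)
  expect_false(any(st %in% "W"))
  if (nrow(inf$artifact_mask) > 0) {
    expect_false(any(naptwitch:::point_in_intervals(inf$twitch_train$onset_s,
                                                    inf$artifact_mask)))
    hits <- vapply(seq_len(nrow(inf$ground_truth_spindles)), function(i) {
      naptwitch:::interval_overlap(inf$ground_truth_spindles$onset_s[i],
                                   inf$ground_truth_spindles$offset_s[i],
                                   inf$artifact_mask) > 0
    }, logical(1))
    expect_false(any(hits))
  }
  # spindles lie inside sleep epochs and recordings span the hypnogram
  sp_st <- stage_at(inf$hypnogram, inf$ground_truth_spindles$onset_s)
  expect_true(all(sp_st %in% c("N2", "N3")))
})

test_that("twitch process conserves planted rates per stage", {
  cfg <- sim_config()
  for (st in c("N2", "N3")) {
    h <- hypnogram(rep(st, 120))   # 60 min
    rates <- vapply(1:8, function(s) {
      stage_rate(sim_twitch_train(h, cfg, s), h, NULL, st)
    }, numeric(1))
    planted <- cfg$twitch_rate[[st]]
    # Poisson-style conservation bound from the invariant
    expect_lt(abs(mean(rates) - planted), 3 * sqrt(planted / (8 * 60)))
  }
})

test_that("coupling planting hits its extremes", {
  cfg <- sim_config()
  h <- hypnogram(rep("N2", 60))
  sp <- sim_spindle_events(h, cfg, 5)
  tw <- sim_twitch_train(h, cfg, 6)
  # p = 1: every spindle contains a twitch onset
  cfg1 <- sim_config(p_twitch_given_spindle = c(N2 = 1))
  tw1 <- plant_coupling(tw, sp, h, cfg1, 7)
  expect_true(all(co_occurrence(tw1, sp)$spindle_flag))
  expect_equal(nrow(tw1), nrow(tw))   # rate preserved by relocation
  # p = 0 leaves the train untouched (independent null)
  cfg0 <- sim_config(p_twitch_given_spindle = c(N2 = 0))
  expect_identical(plant_coupling(tw, sp, h, cfg0, 7), tw)
})

test_that("cohort files round-trip as plain text", {
  cfg <- sim_config(n_infants = 2, stage_mean_minutes = c(N2 = 3, N3 = 4))
  co <- sim_cohort(cfg, seed = 2, eeg = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "events.csv")))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  expect_setequal(unique(ev$infant_id), c("inf01", "inf02"))
  hyp <- utils::read.csv(file.path(dir, "hypnogram.csv"))
  expect_true(all(hyp$stage %in% c("W", "N1", "N2", "N3", "REM")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$parameters$n_infants, 2)
})
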