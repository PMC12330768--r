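test_that("stage rate equals brute-force tally and handles empty stages", {
  h <- hypnogram(c("N2", "N2", "N3", "W"))
  ev <- tibble::tibble(onset_s = c(1, 10, 30, 70, 100))
  expect_equal(stage_rate(ev, h, NULL, "N2"), 3 / 1)           # 3 in 60 s
  expect_equal(stage_rate(ev, h, NULL, "N3"), 1 / 0.5)         # 1 in 30 s
  expect_equal(stage_rate(tibble::tibble(onset_s = numeric(0)), h, NULL, "N2"), 0)
  expect_warning(r <- stage_rate(ev, h, NULL, "REM"), "undefined")
  expect_true(is.na(r))
  # 10 events in 120 s of N2 -> 5/min
  h2 <- hypnogram(rep("N2", 4))
  ev10 <- tibble::tibble(onset_s = seq(0, 110, length.out = 10))
  expect_equal(stage_rate(ev10, h2, NULL, "N2"), 5)
  # masked events are excluded from numerator and denominator
  m <- artifact_mask(0, 30)
  expect_equal(stage_rate(ev, h, m, "N2"),
               sum(ev$onset_s >= 30 & ev$onset_s < 60) / 0.5)
  # invariance under time translation of the whole session
  shift <- 60
  h_s <- hypnogram(c("W", "W", h$stage))
  expect_equal(stage_rate(dplyr::mutate(ev, onset_s = onset_s + shift),
                          h_s, NULL, "N2"),
               stage_rate(ev, h, NULL, "N2"))
})

test_that("inter-event intervals obey the exclusion rules", {
  h <- hypnogram(c("N2", "N3", "N2"))
  # events at 0, 1, 2 all in the first N2 epoch
  expect_equal(event_intervals(tibble::tibble(onset_s = c(0, 1, 2)), h, NULL, "N2"),
               c(1, 1))
  # stage transition between events: no interval
  expect_equal(length(event_intervals(tibble::tibble(onset_s = c(10, 40)),
                                      h, NULL, c("N2", "N3"))), 0)
  # same-stage but different runs (wake gap): excluded
  hw <- hypnogram(c("N2", "W", "N2"))
  expect_equal(length(event_intervals(tibble::tibble(onset_s = c(10, 70)),
                                      hw, NULL, "N2")), 0)
  # artifact between onsets breaks the pair
  h2 <- hypnogram(rep("N2", 2))
  expect_equal(length(event_intervals(tibble::tibble(onset_s = c(5, 25)),
                                      h2, artifact_mask(10, 12), "N2")), 0)
  expect_equal(event_intervals(tibble::tibble(onset_s = c(15, 25)),
                               h2, artifact_mask(10, 12), "N2"), 10)
})

test_that("log-survivor curve matches its definition and exponential slope", {
  sc1 <- log_survivor(5)
  expect_equal(sc1$survivor, 0)
  sc <- log_survivor(c(3, 1, 2))
  expect_equal(sc$interval_s, c(1, 2, 3))
  expect_equal(sc$survivor, c(2 / 3, 1 / 3, 0))
  # exponential intervals: slope of log S(t) ~ -lambda
  withr::with_seed(42, {
    iv <- rexp(10000, rate = 2)
    curve <- log_survivor(iv)
    keep <- curve$survivor > 0.01
    fit <- lm(log(curve$survivor[keep]) ~ curve$interval_s[keep])
    expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.05)
  })
})

test_that("burst segmentation equals the definitional oracle", {
  h <- hypnogram(rep("N2", 10))
  seg_of <- function(on) segment_bursts(tibble::tibble(onset_s = on), h, NULL, "N2")
  # worked cases
  s1 <- seg_of(c(0, 0.3, 0.6))
  expect_equal(s1$in_burst, rep(TRUE, 3))
  expect_equal(unique(s1$burst_id), 1L)
  s2 <- seg_of(c(0, 0.6))
  expect_equal(s2$in_burst, c(FALSE, FALSE))
  s3 <- seg_of(c(0, 0.4, 1.0, 1.3))
  expect_equal(s3$burst_id, c(1L, 1L, 2L, 2L))
  # tie at exactly 0.5 breaks the chain
  expect_equal(seg_of(c(0, 0.5))$in_burst, c(FALSE, FALSE))

  # exhaustive comparison over all subsets (size 1-5) of a 0.1-s grid
  grid <- seq(0, 0.9, by = 0.1)
  for (k in 1:5) {
    combos <- utils::combn(length(grid), k)
    for (j in seq_len(ncol(combos))) {
      on <- grid[combos[, j]]
      got <- seg_of(on)
      want <- oracle_bursts(on, gap = 0.5)
      expect_equal(got$in_burst, want$in_burst)
    }
  }
})

test_that("bursts never span stage, wake, or artifact boundaries", {
  h <- hypnogram(c("N2", "N3"))
  s <- segment_bursts(tibble::tibble(onset_s = c(29.8, 30.1)), h, NULL,
                      c("N2", "N3"))
  expect_equal(s$in_burst, c(FALSE, FALSE))
  h2 <- hypnogram(rep("N2", 2))
  s2 <- segment_bursts(tibble::tibble(onset_s = c(9.8, 10.1)), h2,
                       artifact_mask(9.9, 10.0), "N2")
  expect_equal(s2$in_burst, c(FALSE, FALSE))
})

test_that("burst statistics follow their arithmetic definition", {
  h <- hypnogram(rep("N2", 4))
  # 2 bursts of 2 + 1 single in 2 min -> (1/min, 4/5)
  on <- c(0, 0.3, 10, 10.4, 20)
  seg <- segment_bursts(tibble::tibble(onset_s = on), h, NULL, "N2")
  bs <- burst_stats(seg, 2)
  expect_equal(bs$burst_rate_per_min, 1)
  expect_equal(bs$prop_in_burst, 4 / 5)
  bs0 <- burst_stats(segment_bursts(tibble::tibble(onset_s = c(0, 5)), h, NULL, "N2"), 2)
  expect_equal(bs0$burst_rate_per_min, 0)
  expect_equal(bs0$prop_in_burst, 0)
  # every event is in exactly one burst or a single: partition is exhaustive
  expect_equal(sum(seg$in_burst) + sum(!seg$in_burst), length(on))
})

test_that("body-part proportions sum to one and match counts", {
  ev <- tibble::tibble(onset_s = 1:4,
                       body_part = c("fingers", "fingers", "fingers", "arm"))
  bp <- body_part_proportions(ev)
  expect_equal(sum(bp$proportion), 1)
  expect_equal(bp$proportion[bp$body_part == "fingers"], 0.75)
  expect_equal(bp$proportion[bp$body_part == "arm"], 0.25)
  one <- body_part_proportions(dplyr::mutate(ev, body_part = "leg"))
  expect_equal(one$proportion, 1)
})

test_that("inclusion rules are applied as data", {
  summary_tbl <- tibble::tibble(
    infant_id = rep(c("a", "b", "c"), each = 4),
    stage = rep(c("N2", "N3", "N2", "N3"), 3),
    metric = rep(c("n_twitches", "n_twitches", "n_spindles", "n_spindles"), 3),
    value = c(12, 15, 11, 10,   9, 20, 30, 30,   10, 10, 10, 10)
  )
  rules <- tibble::tibble(metric = rep(c("n_twitches", "n_spindles"), each = 2),
                          stage = rep(c("N2", "N3"), 2), min = 10)
  expect_equal(sort(inclusion_filter(summary_tbl, rules)), c("a", "c"))
  # all thresholds zero: everyone included
  rules0 <- dplyr::mutate(rules, min = 0)
  expect_equal(sort(inclusion_filter(summary_tbl, rules0)), c("a", "b", "c"))
  # brute-force cross-check
  bf <- sapply(c("a", "b", "c"), function(id) {
    sub <- summary_tbl[summary_tbl$infant_id == id, ]
    all(sub$value >= 10)
  })
  expect_equal(sort(inclusion_filter(summary_tbl, rules)), sort(names(bf)[bf]))
})

test_that("coder agreement kappa behaves at its anchors", {
  tr <- tibble::tibble(onset_s = c(5, 20, 33, 47, 60))
  expect_equal(agreement_kappa(tr, tr), 1)
  expect_lte(agreement_kappa(tr, tibble::tibble(onset_s = numeric(0))), 0)
  # near-miss onsets within 1 s still count as agreement
  tr2 <- tibble::tibble(onset_s = tr$onset_s + 0.8)
  expect_equal(agreement_kappa(tr, tr2), 1)
  # closed-form check on a constructed 2x2 table: a=40, b=5, c=5, d=50
  withr::with_seed(7, {
    both <- sort(sample(seq(0.5, 99.5, by = 1), 50))
    p_on <- both[1:45]
    s_on <- c(both[1:40], both[46:50])
  })
  k <- agreement_kappa(tibble::tibble(onset_s = p_on),
                       tibble::tibble(onset_s = s_on),
                       tol = 0.4, bin = 1, span = 99)
  expect_equal(k, oracle_kappa_2x2(40, 5, 5, 50), tolerance = 1e-10)
})
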