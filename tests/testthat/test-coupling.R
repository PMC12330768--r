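test_that("co-occurrence flags equal the brute-force overlap check", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      sp_on <- sort(runif(15, 0, 300))
      sp_off <- sp_on + runif(15, 0.5, 1.5)
      sp_on <- sp_on[c(TRUE, diff(sp_on) > 2)]   # keep non-overlapping
      sp_off <- sp_on + 1
      tw_on <- sort(runif(40, -5, 305))
      got <- co_occurrence(tibble::tibble(onset_s = tw_on),
                           tibble::tibble(onset_s = sp_on, offset_s = sp_off))
      want <- oracle_co_occur(tw_on, sp_on, sp_off)
      expect_equal(got$twitch_flag, want$twitch_flag)
      expect_equal(got$spindle_flag, want$spindle_flag)
    }
  })
  # boundary convention: onset inside [on, off), half-open
  g <- co_occurrence(tibble::tibble(onset_s = c(4.5, 6.0)),
                     tibble::tibble(onset_s = 4.5, offset_s = 6.0))
  expect_equal(g$twitch_flag, c(TRUE, FALSE))
})

test_that("conditional probabilities are the stated ratios", {
  tw <- tibble::tibble(onset_s = c(5, 10, 100))
  sp <- tibble::tibble(onset_s = c(4.5, 9.5), offset_s = c(6, 11))
  cp <- conditional_probs(tw, sp)
  expect_equal(cp$p_spindle_given_twitch, 2 / 3)
  expect_equal(cp$p_twitch_given_spindle, 1)
  none <- conditional_probs(tw, tibble::tibble(onset_s = numeric(0),
                                               offset_s = numeric(0)))
  expect_equal(none$p_spindle_given_twitch, 0)
  expect_true(is.na(none$p_twitch_given_spindle))
})

test_that("perievent curves match brute-force bin evaluation", {
  trig <- c(50, 120, 200)
  targ <- tibble::tibble(onset_s = c(45.2, 119.5), offset_s = c(46.6, 121.2))
  pc <- perievent_curve(trig, targ, half = 20, bin = 1)
  expect_equal(nrow(pc), 40)
  # brute force
  lo <- seq(-20, 19)
  bf <- sapply(lo, function(b) {
    mean(sapply(trig, function(tr) {
      any(targ$offset_s > tr + b & targ$onset_s < tr + b + 1)
    }))
  })
  expect_equal(pc$prob, bf)
  # triggers exactly at target onsets: center bin = 1 for onset targets
  pc2 <- perievent_curve(c(10, 20), tibble::tibble(onset_s = c(10, 20)),
                         target = "onset")
  expect_equal(pc2$prob[pc2$bin_center_s == 0.5], 1)
  # empty targets: all-zero curve
  pc0 <- perievent_curve(trig, targ[0, ])
  expect_equal(max(pc0$prob), 0)
  expect_error(perievent_curve(numeric(0), targ), "at least 1 trigger")
})

test_that("interval shuffles preserve the interval multiset exactly", {
  seg <- tibble::tibble(start_s = 0, end_s = 100)
  ev <- tibble::tibble(onset_s = c(3, 7, 20, 21, 50, 88),
                       offset_s = c(3, 7, 20, 21, 50, 88) + 1.2)
  surr <- interval_shuffle(ev, seg, n_perm = 50, seed = 5)
  for (s in surr) {
    expect_equal(sort(diff(s$onset_s)), sort(diff(ev$onset_s)))
    expect_equal(s$onset_s[1], ev$onset_s[1])
    expect_equal(max(s$onset_s), max(ev$onset_s))
    expect_equal(s$offset_s - s$onset_s, rep(1.2, 6))
  }
  # reproducible and order-independent streams
  surr2 <- interval_shuffle(ev, seg, n_perm = 50, seed = 5)
  expect_identical(surr[[37]], surr2[[37]])

  # with 2 intervals both orderings occur
  ev3 <- tibble::tibble(onset_s = c(0, 1, 4))
  s3 <- interval_shuffle(ev3, seg, n_perm = 40, seed = 2)
  seqs <- unique(vapply(s3, function(x) paste(diff(x$onset_s), collapse = ","),
                        character(1)))
  expect_setequal(seqs, c("1,3", "3,1"))

  # 4-event train: the 3! orderings are uniform (chi-square tolerance)
  ev4 <- tibble::tibble(onset_s = c(0, 1, 3, 6))
  s4 <- interval_shuffle(ev4, seg, n_perm = 6000, seed = 9)
  keys <- vapply(s4, function(x) paste(diff(x$onset_s), collapse = ","),
                 character(1))
  tab <- table(keys)
  expect_equal(length(tab), 6)
  chisq <- sum((tab - 1000)^2 / 1000)
  expect_lt(chisq, qchisq(0.999, df = 5))

  # short segments pass through with a warning
  expect_warning(
    pass <- interval_shuffle(tibble::tibble(onset_s = c(1, 2)), seg,
                             n_perm = 3, seed = 1),
    "unshuffled"
  )
  expect_equal(pass[[2]]$onset_s, c(1, 2))
})

test_that("null bands cover identical surrogates and summarize expectation", {
  obs <- perievent_curve(c(10, 30), tibble::tibble(onset_s = c(9, 29),
                                                   offset_s = c(11, 31)))
  banded <- null_band(obs, list(obs, obs, obs))
  expect_true(all(banded$prob >= banded$lower & banded$prob <= banded$upper))
  expect_equal(banded$expected, banded$prob)
  expect_equal(attr(banded, "expected_grand_mean"), mean(obs$prob))
})

test_that("electrode-group averages report means and missing channels", {
  pc <- tibble::tibble(channel = c("C3", "C4", "F3"), value = c(0.2, 0.4, 0.9))
  g <- electrode_group_average(pc, list(central = c("C3", "C4", "Cz"),
                                        frontal = c("F3")))
  expect_equal(g$mean_value, c(0.3, 0.9))
  expect_equal(g$missing_channels, c("Cz", ""))
  # all channels equal -> that value; single channel -> identity
  pc2 <- dplyr::mutate(pc, value = 7)
  expect_equal(electrode_group_average(pc2, list(all = pc$channel))$mean_value, 7)
})
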