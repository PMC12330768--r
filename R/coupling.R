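# Twitch-spindle coupling: co-occurrence flags, conditional probabilities,
# perievent time curves, interval-preserving surrogate shuffles, and the
# Monte-Carlo expected values / 95% bands derived from them.

#' Flag twitch-spindle co-occurrence
#'
#' A spindle co-occurs when at least one twitch onset lies inside its
#' `[onset, offset)` interval; a twitch co-occurs when its onset lies inside
#' at least one spindle interval. Co-occurrence is anchored on twitch onset
#' in both directions.
#'
#' @param twitches Tibble with `onset_s`.
#' @param spindles Tibble with `onset_s`, `offset_s` (non-overlapping).
#' @return List with logical vectors `twitch_flag` and `spindle_flag`.
#' @export
co_occurrence <- function(twitches, spindles) {
  if (nrow(spindles) == 0L) {
    return(list(twitch_flag = rep(FALSE, nrow(twitches)),
                spindle_flag = logical(0)))
  }
  ord <- order(spindles$onset_s)
  on <- spindles$onset_s[ord]; off <- spindles$offset_s[ord]
  idx <- findInterval(twitches$onset_s, on)
  twitch_flag <- idx > 0
  twitch_flag[twitch_flag] <-
    twitches$onset_s[twitch_flag] < off[idx[twitch_flag]]
  spindle_flag_sorted <- tabulate(idx[twitch_flag], nbins = length(on)) > 0
  spindle_flag <- logical(length(on))
  spindle_flag[ord] <- spindle_flag_sorted
  list(twitch_flag = twitch_flag, spindle_flag = spindle_flag)
}

#' Conditional co-occurrence probabilities
#'
#' `P(Spindle | Twitch)` is the fraction of twitches whose onset falls
#' inside a spindle; `P(Twitch | Spindle)` is the fraction of spindles
#' containing at least one twitch onset. Undefined ratios (zero denominator)
#' are returned as NA.
#'
#' @param twitches,spindles As in [co_occurrence()].
#' @param stage,channel Optional labels copied into the output.
#' @return One-row tibble of class `coupling_summary`.
#' @export
conditional_probs <- function(twitches, spindles, stage = NA_character_,
                              channel = NA_character_) {
  fl <- co_occurrence(twitches, spindles)
  out <- tibble::tibble(
    stage = stage, channel = channel,
    n_twitches = nrow(twitches), n_spindles = nrow(spindles),
    p_spindle_given_twitch = if (nrow(twitches)) mean(fl$twitch_flag) else NA_real_,
    p_twitch_given_spindle = if (nrow(spindles)) mean(fl$spindle_flag) else NA_real_
  )
  class(out) <- c("coupling_summary", class(out))
  out
}

#' Perievent time curve
#'
#' For each 1-s bin offset `b` in `[-half, +half)`, the fraction of triggers
#' for which a target is present in `[trigger + b, trigger + b + bin)`.
#' Presence means a target interval overlaps the bin (`target = "interval"`,
#' used for spindle targets) or a target onset falls in the bin
#' (`target = "onset"`, used for twitch targets).
#'
#' @param triggers Numeric vector of trigger times (twitch onsets or spindle
#'   midpoints).
#' @param targets Tibble with `onset_s` (and `offset_s` for
#'   `target = "interval"`).
#' @param half Half-width of the perievent window (s).
#' @param bin Bin width (s).
#' @param target Presence rule, `"interval"` or `"onset"`.
#' @return Tibble of class `perievent_curve` with `bin_center_s`, `prob`,
#'   and attribute `n_triggers`.
#' @export
perievent_curve <- function(triggers, targets, half = 20, bin = 1,
                            target = c("interval", "onset")) {
  target <- match.arg(target)
  if (length(triggers) == 0L) stop("perievent_curve needs at least 1 trigger")
  lo <- seq(-half, half - bin, by = bin)
  prob <- vapply(lo, function(b) {
    a0 <- triggers + b
    a1 <- a0 + bin
    if (nrow(targets) == 0L) return(0)
    hit <- vapply(seq_along(a0), function(i) {
      if (target == "interval") {
        any(targets$offset_s > a0[i] & targets$onset_s < a1[i])
      } else {
        any(targets$onset_s >= a0[i] & targets$onset_s < a1[i])
      }
    }, logical(1))
    mean(hit)
  }, numeric(1))
  out <- tibble::tibble(bin_center_s = lo + bin / 2, prob = prob)
  attr(out, "n_triggers") <- length(triggers)
  class(out) <- c("perievent_curve", class(out))
  out
}

#' Interval-preserving surrogate event trains
#'
#' Within each segment (maximal artifact-free same-stage run), the multiset
#' of successive onset intervals is preserved exactly and only its order is
#' permuted; the first onset stays anchored, so surrogate events never leave
#' the segment. Segments with fewer than 3 events are passed through
#' unshuffled with a warning. Permutation streams are seeded per surrogate
#' index, so results are reproducible and independent of evaluation order.
#'
#' @param events Tibble with `onset_s` (other columns, e.g. `offset_s`,
#'   travel with the event's position in the reordered train: durations are
#'   preserved per ordinal event).
#' @param segments Tibble with `start_s`, `end_s` (e.g. [stage_segments()]).
#' @param n_perm Number of surrogates.
#' @param seed Integer seed.
#' @return List of `n_perm` event tibbles.
#' @export
interval_shuffle <- function(events, segments, n_perm = 1000, seed = 1) {
  ev <- dplyr::arrange(events, .data$onset_s)
  seg_of <- rep(NA_integer_, nrow(ev))
  for (i in seq_len(nrow(segments))) {
    seg_of[ev$onset_s >= segments$start_s[i] &
             ev$onset_s < segments$end_s[i]] <- i
  }
  seg_groups <- split(seq_len(nrow(ev)), seg_of)
  small <- vapply(seg_groups, length, integer(1)) < 3L
  if (any(small)) {
    warning(sum(small), " segment(s) with < 3 events passed through unshuffled")
  }
  has_offset <- "offset_s" %in% names(ev)
  lapply(seq_len(n_perm), function(k) {
    out <- ev
    run_seeded(child_seed(seed, k), {
      for (g in seg_groups[!small]) {
        on <- ev$onset_s[g]
        gaps <- diff(on)
        new_on <- on[1] + c(0, cumsum(gaps[sample.int(length(gaps))]))
        out$onset_s[g] <- new_on
        if (has_offset) {
          out$offset_s[g] <- new_on + (ev$offset_s[g] - ev$onset_s[g])
        }
      }
    })
    dplyr::arrange(out, .data$onset_s)
  })
}

#' Monte-Carlo expected values and 95% bands from surrogates
#'
#' Attaches per-bin percentile bands (default 2.5/97.5) across surrogate
#' perievent curves to an observed curve, and records the grand-mean
#' expected probability over surrogates.
#'
#' @param observed A [perievent_curve()].
#' @param surrogates List of [perievent_curve()]s computed from shuffled
#'   trains.
#' @param level Band coverage (default 0.95).
#' @return The observed curve with `lower`, `upper`, and `expected` columns;
#'   attribute `expected_grand_mean`.
#' @export
null_band <- function(observed, surrogates, level = 0.95) {
  stopifnot(length(surrogates) > 0)
  mat <- vapply(surrogates, function(s) s$prob, numeric(nrow(observed)))
  mat <- matrix(mat, nrow = nrow(observed))
  a <- (1 - level) / 2
  observed$lower <- apply(mat, 1, quantile, probs = a, names = FALSE)
  observed$upper <- apply(mat, 1, quantile, probs = 1 - a, names = FALSE)
  observed$expected <- rowMeans(mat)
  attr(observed, "expected_grand_mean") <- mean(mat)
  observed
}

#' Shuffle-expected conditional probability
#'
#' Recomputes a conditional co-occurrence probability on each surrogate
#' train and returns its surrogate distribution summary: the Monte-Carlo
#' expected probability and percentile interval used to test the observed
#' value against chance.
#'
#' @param twitches,spindles Observed event tables.
#' @param segments Shuffle segments ([stage_segments()]).
#' @param shuffle Which train to shuffle (`"spindles"` or `"twitches"`).
#' @param statistic `"p_twitch_given_spindle"` or `"p_spindle_given_twitch"`.
#' @param n_perm,seed,level As in [interval_shuffle()] / [null_band()].
#' @return One-row tibble: `observed`, `expected`, `lower`, `upper`,
#'   `n_perm`, `exceeds_upper`.
#' @export
coupling_null <- function(twitches, spindles, segments,
                          shuffle = c("spindles", "twitches"),
                          statistic = c("p_twitch_given_spindle",
                                        "p_spindle_given_twitch"),
                          n_perm = 1000, seed = 1, level = 0.95) {
  shuffle <- match.arg(shuffle)
  statistic <- match.arg(statistic)
  obs <- conditional_probs(twitches, spindles)[[statistic]]
  base <- if (shuffle == "spindles") spindles else twitches
  surr <- interval_shuffle(base, segments, n_perm = n_perm, seed = seed)
  vals <- vapply(surr, function(s) {
    if (shuffle == "spindles") {
      conditional_probs(twitches, s)[[statistic]]
    } else {
      conditional_probs(s, spindles)[[statistic]]
    }
  }, numeric(1))
  a <- (1 - level) / 2
  tibble::tibble(
    statistic = statistic, observed = obs, expected = mean(vals),
    lower = quantile(vals, a, names = FALSE),
    upper = quantile(vals, 1 - a, names = FALSE),
    n_perm = n_perm,
    exceeds_upper = obs > quantile(vals, 1 - a, names = FALSE)
  )
}

#' Average a per-channel statistic over electrode groups
#'
#' Arithmetic mean over the available channels of each group (e.g. the
#' central and frontal electrode sets); channels listed in a group but
#' absent from the data are reported.
#'
#' @param per_channel Tibble with `channel` and `value`.
#' @param groups Named list of character vectors of channel labels.
#' @return Tibble with `group`, `mean_value`, `n_channels`,
#'   `missing_channels`.
#' @export
electrode_group_average <- function(per_channel, groups) {
  purrr::imap_dfr(groups, function(labels, gname) {
    have <- per_channel$channel %in% labels
    missing <- setdiff(labels, per_channel$channel)
    tibble::tibble(
      group = gname,
      mean_value = if (any(have)) mean(per_channel$value[have]) else NA_real_,
      n_channels = sum(have),
      missing_channels = paste(missing, collapse = ",")
    )
  })
}
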