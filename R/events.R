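# Stage-conditional metrics for any timestamped event train (twitches,
# spindles, rapid eye movements): rates, inter-event intervals with the
# exclusion rules, log-survivor curves, burst segmentation, inclusion
# filters, and two-coder agreement.

#' Stage-conditional event rate
#'
#' Onset count within artifact-free time of a stage divided by that time in
#' minutes. Undefined (NA, with a warning) when the denominator is zero.
#'
#' @param events Tibble with `onset_s`.
#' @param hyp A [hypnogram()].
#' @param mask Optional [artifact_mask()].
#' @param stage Stage label or vector of labels pooled together.
#' @return Events per minute (numeric scalar).
#' @export
stage_rate <- function(events, hyp, mask = NULL, stage) {
  mins <- artifact_free_duration(hyp, mask, stage) / 60
  if (mins <= 0) {
    warning("no artifact-free time in stage ", paste(stage, collapse = "/"),
            "; rate undefined")
    return(NA_real_)
  }
  n <- sum(stage_at(hyp, events$onset_s) %in% stage &
             !point_in_intervals(events$onset_s, mask))
  n / mins
}

#' Inter-event intervals with exclusion rules
#'
#' Onset-to-onset differences between successive events in the given stage.
#' An interval is excluded if the two events fall in different maximal
#' same-stage runs (an intervening stage change or wake period) or if a
#' masked artifact intersects the time between the onsets.
#'
#' @inheritParams stage_rate
#' @return Numeric vector of intervals (s).
#' @export
event_intervals <- function(events, hyp, mask = NULL, stage) {
  segs <- stage_segments(hyp, mask, stage = stage)
  on <- sort(events$onset_s)
  if (length(on) < 2L || nrow(segs) == 0L) return(numeric(0))
  seg_of <- rep(NA_integer_, length(on))
  for (i in seq_len(nrow(segs))) {
    seg_of[on >= segs$start_s[i] & on < segs$end_s[i]] <- segs$seg_id[i]
  }
  keep <- !is.na(seg_of)
  on <- on[keep]; seg_of <- seg_of[keep]
  if (length(on) < 2L) return(numeric(0))
  d <- diff(on)
  same <- diff(seg_of) == 0
  d[same]
}

#' Empirical log-survivor curve of intervals
#'
#' The survivor fraction `S(t) = #{intervals > t} / N` at each observed
#' interval value, the standard display for burst structure in event trains
#' (a Poisson process gives a straight line on a log ordinate; an early
#' steep segment indicates bursting).
#'
#' @param intervals Numeric vector of inter-event intervals (s), typically
#'   pooled across infants.
#' @return Tibble of class `survivor_curve` with `interval_s`, `survivor`.
#' @export
log_survivor <- function(intervals) {
  intervals <- sort(intervals[is.finite(intervals)])
  n <- length(intervals)
  out <- tibble::tibble(
    interval_s = intervals,
    survivor = if (n) (n - seq_len(n)) / n else numeric(0)
  )
  class(out) <- c("survivor_curve", class(out))
  out
}

#' Segment an event train into bursts and singles
#'
#' Greedy left-to-right chaining: successive events with onset gaps strictly
#' below `gap` (default 0.5 s) join a chain; chains of length >= 2 are
#' bursts, the rest singles. Chains never span stage transitions, wake, or
#' artifact boundaries (events are chained only within the same
#' artifact-free same-stage segment). Ties at exactly `gap` break the chain.
#'
#' @inheritParams stage_rate
#' @param gap Chaining threshold in seconds (strict `<`).
#' @return Tibble with one row per event in the stage: `onset_s`,
#'   `burst_id` (NA for singles), `in_burst`.
#' @export
segment_bursts <- function(events, hyp, mask = NULL, stage, gap = 0.5) {
  segs <- stage_segments(hyp, mask, stage = stage)
  on <- sort(events$onset_s)
  seg_of <- rep(NA_integer_, length(on))
  for (i in seq_len(nrow(segs))) {
    seg_of[on >= segs$start_s[i] & on < segs$end_s[i]] <- segs$seg_id[i]
  }
  keep <- !is.na(seg_of)
  on <- on[keep]; seg_of <- seg_of[keep]
  n <- length(on)
  if (n == 0L) {
    return(tibble::tibble(onset_s = numeric(0), burst_id = integer(0),
                          in_burst = logical(0)))
  }
  new_chain <- c(TRUE, diff(on) >= gap | diff(seg_of) != 0)
  chain <- cumsum(new_chain)
  size <- table(chain)[as.character(chain)]
  in_burst <- as.integer(size) >= 2L
  burst_id <- ifelse(in_burst, chain, NA_integer_)
  # renumber bursts consecutively
  burst_id <- as.integer(factor(burst_id, levels = unique(stats::na.omit(burst_id))))
  tibble::tibble(onset_s = on, burst_id = burst_id, in_burst = in_burst)
}

#' Burst rate and proportion of twitches in bursts
#'
#' @param segmented A [segment_bursts()] table.
#' @param stage_time_min Artifact-free stage time (minutes).
#' @return Tibble with `n_bursts`, `n_events`, `burst_rate_per_min`,
#'   `prop_in_burst`.
#' @export
burst_stats <- function(segmented, stage_time_min) {
  n_bursts <- length(unique(stats::na.omit(segmented$burst_id)))
  n_events <- nrow(segmented)
  tibble::tibble(
    n_bursts = n_bursts,
    n_events = n_events,
    burst_rate_per_min = if (stage_time_min > 0) n_bursts / stage_time_min else NA_real_,
    prop_in_burst = if (n_events > 0) mean(segmented$in_burst) else 0
  )
}

#' Body-part proportions of twitching
#'
#' Fraction of twitches in each body part, within a stage (or overall when
#' `stage` is NULL). Fractions sum to 1 when any twitches are present.
#'
#' @inheritParams stage_rate
#' @param stage Optional stage restriction.
#' @return Tibble with `body_part`, `n`, `proportion`.
#' @export
body_part_proportions <- function(events, hyp = NULL, stage = NULL) {
  ev <- events
  if (!is.null(stage)) {
    stopifnot(!is.null(hyp))
    ev <- ev[stage_at(hyp, ev$onset_s) %in% stage, , drop = FALSE]
  }
  ev |>
    dplyr::count(.data$body_part, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
}

#' Apply an inclusion rule to a per-infant summary
#'
#' Rules are data: a tibble of `(metric, stage, min)` rows. An infant is
#' included when, for every rule row, its value of that metric in that stage
#' meets the minimum (a missing metric/stage combination fails the rule).
#' `stage = NA` in a rule matches rows of the summary with `stage = NA`
#' (session-level metrics).
#'
#' @param summary_tbl Long tibble with `infant_id`, `stage`, `metric`,
#'   `value`.
#' @param rules Tibble with `metric`, `stage`, `min`.
#' @return Character vector of included infant ids.
#' @export
inclusion_filter <- function(summary_tbl, rules) {
  ids <- unique(summary_tbl$infant_id)
  ok <- vapply(ids, function(id) {
    sub <- summary_tbl[summary_tbl$infant_id == id, , drop = FALSE]
    all(vapply(seq_len(nrow(rules)), function(i) {
      r <- rules[i, ]
      hit <- sub$metric == r$metric &
        (if (is.na(r$stage)) is.na(sub$stage) else !is.na(sub$stage) & sub$stage == r$stage)
      any(hit) && all(sub$value[hit] >= r$min)
    }, logical(1)))
  }, logical(1))
  ids[ok]
}

#' Two-coder agreement (Cohen's kappa) for event trains
#'
#' Events from the two coders are matched greedily by onset within `tol`
#' seconds (each primary event to the nearest unmatched secondary event);
#' matched secondary events are aligned to the primary onsets. Both streams
#' are then binned at `bin`-second resolution over the common span and
#' scored present/absent per bin; kappa is computed from the resulting 2x2
#' table.
#'
#' @param primary,secondary Event tibbles with `onset_s`.
#' @param tol Matching tolerance (s).
#' @param bin Bin width (s).
#' @param span Optional total span (s); defaults to the maximum onset + tol.
#' @return Numeric kappa.
#' @export
agreement_kappa <- function(primary, secondary, tol = 1, bin = 1, span = NULL) {
  p <- sort(primary$onset_s)
  s <- sort(secondary$onset_s)
  span <- span %||% (max(c(p, s, 0)) + tol)
  matched_s <- rep(NA_real_, length(s))
  used <- rep(FALSE, length(s))
  aligned_s <- numeric(0)
  for (x in p) {
    cand <- which(!used & abs(s - x) <= tol)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(s[cand] - x))]
      used[j] <- TRUE
      aligned_s <- c(aligned_s, x)   # aligned to the primary onset
    }
  }
  aligned_s <- c(aligned_s, s[!used])
  edges <- seq(0, span + bin, by = bin)
  nb <- length(edges) - 1L
  occ <- function(on) {
    idx <- findInterval(on, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= nb]
    tabulate(idx, nb) > 0
  }
  b1 <- occ(p); b2 <- occ(aligned_s)
  po <- mean(b1 == b2)
  pe <- mean(b1) * mean(b2) + mean(!b1) * mean(!b2)
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}
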