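# Hypnogram and artifact-mask containers. Both are plain tibbles with light
# validation so they pipe through dplyr verbs; times are seconds, 0-based,
# and all intervals are half-open [start, end).

SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Construct a hypnogram of fixed-length epochs
#'
#' A hypnogram is a tibble with one row per scoring epoch: `epoch` (1-based
#' index), `stage` (one of W, N1, N2, N3, REM), and `onset_s` (epoch start in
#' seconds from recording start). The epoch length is carried as the
#' `epoch_len` attribute (30 s by convention).
#'
#' @param stages Character vector of epoch labels.
#' @param epoch_len Epoch length in seconds (default 30).
#' @return A tibble of class `hypnogram`.
#' @examples
#' hypnogram(c("W", "N2", "N2", "N3"))
#' @export
hypnogram <- function(stages, epoch_len = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad) > 0) {
    stop("Unknown sleep stage label(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(epoch_len > 0)
  out <- tibble::tibble(
    epoch = seq_along(stages),
    stage = stages,
    onset_s = (seq_along(stages) - 1) * epoch_len
  )
  attr(out, "epoch_len") <- epoch_len
  class(out) <- c("hypnogram", class(out))
  out
}

epoch_len <- function(hyp) attr(hyp, "epoch_len") %||% 30

hyp_duration <- function(hyp) nrow(hyp) * epoch_len(hyp)

#' Maximal same-stage runs of a hypnogram
#'
#' Collapses consecutive epochs with the same label into stage bouts.
#'
#' @param hyp A [hypnogram()].
#' @param stages Optional subset of labels; runs are computed on the full
#'   hypnogram first, then filtered.
#' @param collapse Optional character vector of labels to treat as one
#'   pseudo-stage before run-length encoding (e.g. `c("N2", "N3")` for NREM
#'   runs).
#' @return Tibble with `stage`, `start_s`, `end_s` (half-open).
#' @export
stage_runs <- function(hyp, stages = NULL, collapse = NULL) {
  el <- epoch_len(hyp)
  lab <- hyp$stage
  if (!is.null(collapse)) {
    lab[lab %in% collapse] <- paste(collapse, collapse = "+")
  }
  if (nrow(hyp) == 0L) {
    return(tibble::tibble(stage = character(0), start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(lab)
  end_epoch <- cumsum(r$lengths)
  start_epoch <- end_epoch - r$lengths
  out <- tibble::tibble(
    stage = r$values,
    start_s = start_epoch * el,
    end_s = end_epoch * el
  )
  if (!is.null(stages)) out <- dplyr::filter(out, .data$stage %in% stages)
  out
}

#' Stage label at given times
#'
#' @param hyp A [hypnogram()].
#' @param t Numeric vector of times (seconds).
#' @return Character vector; `NA` outside the hypnogram span.
#' @export
stage_at <- function(hyp, t) {
  el <- epoch_len(hyp)
  idx <- floor(t / el) + 1
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t) & idx >= 1 & idx <= nrow(hyp) & t >= 0
  out[ok] <- hyp$stage[idx[ok]]
  out
}

#' Construct an artifact mask
#'
#' Sorted, merged, half-open `[start_s, end_s)` intervals of time excluded
#' from every rate, power, and coupling computation.
#'
#' @param start_s,end_s Numeric vectors of interval edges (seconds).
#' @return Tibble of class `artifact_mask` with columns `start_s`, `end_s`.
#' @export
artifact_mask <- function(start_s = numeric(0), end_s = numeric(0)) {
  stopifnot(length(start_s) == length(end_s))
  if (any(end_s <= start_s)) stop("artifact intervals need start_s < end_s")
  out <- merge_intervals(start_s, end_s)
  class(out) <- c("artifact_mask", class(out))
  out
}

#' Artifact-free time spent in a sleep stage
#'
#' Total time in a stage minus its overlap with the artifact mask
#' (half-open interval arithmetic). This is the denominator of every
#' stage-conditional rate.
#'
#' @param hyp A [hypnogram()].
#' @param mask An [artifact_mask()] (or `NULL` for none).
#' @param stage Stage label, or a vector of labels pooled together
#'   (e.g. `c("N2","N3")`).
#' @return Seconds (numeric scalar).
#' @export
artifact_free_duration <- function(hyp, mask = NULL, stage) {
  runs <- stage_runs(hyp, stages = stage)
  if (nrow(runs) == 0L) return(0)
  tot <- sum(runs$end_s - runs$start_s)
  if (is.null(mask) || nrow(mask) == 0L) return(tot)
  lost <- sum(vapply(
    seq_len(nrow(runs)),
    function(i) interval_overlap(runs$start_s[i], runs$end_s[i], mask),
    numeric(1)
  ))
  tot - lost
}

# Artifact-free sub-intervals of each same-stage run: the segments used for
# interval shuffling and burst chaining.
stage_segments <- function(hyp, mask = NULL, stage = NULL, collapse = NULL) {
  runs <- stage_runs(hyp, stages = stage, collapse = collapse)
  if (is.null(mask) || nrow(mask) == 0L || nrow(runs) == 0L) {
    runs$seg_id <- seq_len(nrow(runs))
    return(runs)
  }
  pieces <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start_s[i]; e <- runs$end_s[i]
    cuts <- mask[mask$end_s > s & mask$start_s < e, , drop = FALSE]
    if (nrow(cuts) == 0L) {
      return(tibble::tibble(stage = runs$stage[i], start_s = s, end_s = e))
    }
    edges_s <- c(s, pmin(e, cuts$end_s))
    edges_e <- c(pmax(s, cuts$start_s), e)
    keep <- edges_e > edges_s
    tibble::tibble(stage = runs$stage[i], start_s = edges_s[keep], end_s = edges_e[keep])
  })
  out <- dplyr::bind_rows(pieces)
  out$seg_id <- seq_len(nrow(out))
  out
}
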