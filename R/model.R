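# Delta-twitch association: per-infant regressions, person-mean centering of
# delta power into within- and between-infant predictors (per 100 uV^2), the
# random-intercept REML model, and the intraclass correlation of delta.

#' Decompose delta power into within- and between-infant predictors
#'
#' Person-mean centering: each infant's mean delta is the between-infant
#' predictor (centered on the observed grand mean of infant means), and the
#' per-window deviation from the infant's own mean is the within-infant
#' predictor. Both are divided by 100 so a one-unit change is 100 uV^2.
#'
#' @param table Window table with `infant_id`, `mean_delta_uv2`,
#'   `n_twitches`.
#' @return The input with `within_delta`, `between_delta`, and
#'   `infant_mean_delta` columns; attribute `grand_mean_uv2`.
#' @export
decompose_delta <- function(table) {
  stopifnot(length(unique(table$infant_id)) >= 2)
  out <- table |>
    dplyr::group_by(.data$infant_id) |>
    dplyr::mutate(infant_mean_delta = mean(.data$mean_delta_uv2)) |>
    dplyr::ungroup()
  grand <- mean(unique(out[c("infant_id", "infant_mean_delta")])$infant_mean_delta)
  out <- out |>
    dplyr::mutate(
      within_delta = (.data$mean_delta_uv2 - .data$infant_mean_delta) / 100,
      between_delta = (.data$infant_mean_delta - grand) / 100
    )
  attr(out, "grand_mean_uv2") <- grand
  out
}

#' Intraclass correlation of window-level delta power
#'
#' Share of delta variance attributable to between-infant differences, from
#' the intercept-only random-intercept decomposition (REML).
#'
#' @param table Window table with `infant_id`, `mean_delta_uv2`.
#' @return Fraction in `[0, 1]`.
#' @export
delta_icc <- function(table) {
  fit <- lme4::lmer(mean_delta_uv2 ~ 1 + (1 | infant_id), data = table,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "infant_id"]
  ve <- vc$vcov[vc$grp == "Residual"]
  vb / (vb + ve)
}

#' Fit the random-intercept delta-twitch model
#'
#' Window twitch counts regressed on the within- and between-infant delta
#' predictors with an infant random intercept, estimated by REML.
#' Denominator degrees of freedom use the Satterthwaite approximation.
#' Singular fits (zero random-intercept variance) are flagged, not errors.
#'
#' @param decomposed A [decompose_delta()] table.
#' @return Object of class `delta_twitch_fit` wrapping the `lmerMod` fit;
#'   use [tidy()] for fixed effects and [glance()] for variance components.
#' @export
fit_delta_twitch <- function(decomposed) {
  fit <- lmerTest::lmer(
    n_twitches ~ within_delta + between_delta + (1 | infant_id),
    data = decomposed, REML = TRUE
  )
  structure(
    list(
      fit = fit,
      grand_mean_uv2 = attr(decomposed, "grand_mean_uv2"),
      singular = lme4::isSingular(fit),
      df_method = "Satterthwaite"
    ),
    class = "delta_twitch_fit"
  )
}

#' @export
print.delta_twitch_fit <- function(x, ...) {
  cat("<delta_twitch_fit> random-intercept REML model",
      if (x$singular) "(singular fit)" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed effects of a delta-twitch fit
#'
#' @param x A [fit_delta_twitch()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`; slopes are twitches per 100 uV^2.
#' @exportS3Method generics::tidy
tidy.delta_twitch_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "within_delta", "between_delta")[
      match(rownames(co), c("(Intercept)", "within_delta", "between_delta"))],
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    df = unname(co[, "df"]),
    statistic = unname(co[, "t value"]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
}

#' One-row summary of a delta-twitch fit
#'
#' @param x A [fit_delta_twitch()] object.
#' @param ... Unused.
#' @return Tibble with variance components, numbers of windows/infants, the
#'   grand-mean centering constant, REML criterion, and the singularity flag.
#' @exportS3Method generics::glance
glance.delta_twitch_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    var_intercept = vc$vcov[vc$grp == "infant_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    n_windows = stats::nobs(x$fit),
    n_infants = lme4::ngrps(x$fit)[["infant_id"]],
    grand_mean_uv2 = x$grand_mean_uv2,
    reml_criterion = stats::deviance(x$fit, REML = TRUE),
    df_method = x$df_method,
    singular = x$singular
  )
}

#' Per-infant linear regressions of twitches on delta power
#'
#' Ordinary least squares of window twitch counts on raw mean delta power,
#' fitted separately for each infant.
#'
#' @param table Window table with `infant_id`, `mean_delta_uv2`,
#'   `n_twitches`.
#' @return Tibble with `infant_id`, `slope` (twitches per uV^2),
#'   `slope_per_100`, `intercept`, `r_squared`, `n_windows`.
#' @export
per_infant_ols <- function(table) {
  table |>
    dplyr::group_by(.data$infant_id) |>
    dplyr::group_modify(function(d, key) {
      if (stats::var(d$n_twitches) == 0) {
        # constant response: flat fit, no variance explained
        return(tibble::tibble(
          slope = 0, slope_per_100 = 0, intercept = d$n_twitches[1],
          r_squared = 0, n_windows = nrow(d)
        ))
      }
      m <- lm(n_twitches ~ mean_delta_uv2, data = d)
      tibble::tibble(
        slope = coef(m)[["mean_delta_uv2"]],
        slope_per_100 = coef(m)[["mean_delta_uv2"]] * 100,
        intercept = coef(m)[["(Intercept)"]],
        r_squared = summary(m)$r.squared,
        n_windows = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}
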