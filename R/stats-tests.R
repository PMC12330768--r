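# Group-comparison layer: normality-gated paired comparisons, the Friedman
# test with Conover all-pairs post hocs, two-way repeated-measures ANOVA
# with sphericity gating and Huynh-Feldt correction, and the Dunn-Sidak
# multiple-comparison adjustment. Numerics are delegated to vetted routines
# (stats, car); this layer owns the gating logic, effect sizes, and the
# report schema.

test_result <- function(test, statistic, df, p, effect_size = NA_real_,
                        correction = "none", gate = list()) {
  tibble::tibble(
    test = test, statistic = statistic, df = df, p = p,
    effect_size = effect_size, correction = correction,
    gate = list(gate)
  )
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences decides the path: below `alpha`
#' the Wilcoxon matched-pairs signed-rank test is used, otherwise the paired
#' t test (the quantity the t test assumes normal is the differences).
#'
#' @param a,b Paired numeric vectors of equal length (>= 3).
#' @param alpha Gate level for the normality test (default 0.05).
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `effect_size`,
#'   `correction`, `gate` (list column holding the Shapiro-Wilk result).
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  sw <- if (stats::sd(d) == 0) {
    list(p.value = 1)   # constant differences: trivially non-significant gate
  } else {
    shapiro.test(d)
  }
  if (sw$p.value < alpha) {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    test_result("wilcoxon_signed_rank", unname(wt$statistic), NA_real_,
                wt$p.value, gate = list(shapiro_p = sw$p.value))
  } else {
    if (stats::sd(d) == 0) {
      return(test_result("paired_t", 0, length(a) - 1, 1,
                         gate = list(shapiro_p = sw$p.value)))
    }
    tt <- t.test(a, b, paired = TRUE)
    test_result("paired_t", unname(tt$statistic), unname(tt$parameter),
                tt$p.value, gate = list(shapiro_p = sw$p.value))
  }
}

#' Friedman test with Conover all-pairs post hocs
#'
#' Friedman chi-square on within-subject ranks of a subjects x conditions
#' matrix, followed by the Conover pairwise test (rank sums compared on a t
#' distribution with (n-1)(k-1) degrees of freedom), with Dunn-Sidak
#' adjustment of the pairwise p values.
#'
#' @param conditions Numeric matrix, subjects in rows, k >= 3 conditions in
#'   columns (complete).
#' @return List with `omnibus` (one-row test tibble) and `pairwise` (tibble
#'   of condition pairs with raw and adjusted p values).
#' @export
friedman_conover <- function(conditions) {
  m <- as.matrix(conditions)
  stopifnot(nrow(m) >= 3, ncol(m) >= 3, all(is.finite(m)))
  n <- nrow(m); k <- ncol(m)
  labs0 <- colnames(m) %||% paste0("cond", seq_len(k))
  if (all(m == m[, 1])) {
    # fully tied design: no evidence of any difference
    pairs0 <- utils::combn(k, 2)
    pw0 <- tibble::tibble(
      cond1 = labs0[pairs0[1, ]], cond2 = labs0[pairs0[2, ]],
      statistic = 0, p_raw = 1, p_adj = 1
    )
    return(list(omnibus = test_result("friedman", 0, k - 1, 1),
                pairwise = pw0))
  }
  fr <- friedman.test(m)
  ranks <- t(apply(m, 1, rank))
  R <- colSums(ranks)
  A <- sum(ranks^2)
  B <- sum(R^2) / n
  dfree <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A - B) / dfree)
  labs <- colnames(m) %||% paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tstat <- abs(R[i1] - R[i2]) / denom
    tibble::tibble(
      cond1 = labs[i1], cond2 = labs[i2],
      statistic = tstat,
      p_raw = 2 * pt(tstat, dfree, lower.tail = FALSE)
    )
  })
  pw$p_adj <- dunn_sidak(pw$p_raw)$p_adj
  list(
    omnibus = test_result("friedman", unname(fr$statistic),
                          unname(fr$parameter), fr$p.value),
    pairwise = pw
  )
}

#' Two-way repeated-measures ANOVA with sphericity gating
#'
#' Both factors within-subject. Mauchly's test gates each multi-level
#' within effect; when sphericity is violated (p < `alpha`) the Huynh-Feldt
#' correction is applied to that effect's degrees of freedom. Effect size is
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`. Numerics
#' (including Mauchly and Huynh-Feldt epsilon) come from the multivariate
#' linear-model machinery in `car::Anova`.
#'
#' @param data Long tibble with columns `subject`, `a`, `b` (factors) and
#'   `value`; the design must be complete (one value per cell).
#' @param alpha Gate level for Mauchly's test.
#' @return Tibble with one row per effect (`a`, `b`, `a:b`): uncorrected and
#'   reported df, F, p, partial eta squared, sphericity gate details.
#' @export
rm_anova2 <- function(data, alpha = 0.05) {
  data <- dplyr::mutate(data, subject = factor(.data$subject),
                        a = factor(.data$a), b = factor(.data$b))
  wide <- tidyr::pivot_wider(
    data, id_cols = "subject",
    names_from = c("a", "b"), values_from = "value",
    names_sep = "."
  )
  Y <- as.matrix(wide[, -1])
  if (anyNA(Y)) stop("rm_anova2 requires a complete subject x a x b design")
  cells <- do.call(rbind, strsplit(colnames(Y), ".", fixed = TRUE))
  idata <- data.frame(a = factor(cells[, 1]), b = factor(cells[, 2]))
  mlm <- lm(Y ~ 1)
  an <- car::Anova(mlm, idata = idata, idesign = ~ a * b, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  uni <- as.data.frame(unclass(s$univariate.tests))
  uni <- uni[rownames(uni) != "(Intercept)", , drop = FALSE]
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  purrr::map_dfr(rownames(uni), function(eff) {
    df1 <- uni[eff, "num Df"]; df2 <- uni[eff, "den Df"]
    Fv <- uni[eff, "F value"]
    ss_eff <- uni[eff, "Sum Sq"]; ss_err <- uni[eff, "Error SS"]
    mauchly_p <- if (!is.null(sph) && eff %in% rownames(sph)) {
      sph[eff, "p-value"]
    } else NA_real_
    hf_eps <- if (!is.null(adj) && eff %in% rownames(adj)) {
      min(1, adj[eff, "HF eps"])
    } else NA_real_
    violated <- !is.na(mauchly_p) && mauchly_p < alpha
    use_eps <- if (violated) hf_eps else 1
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    tibble::tibble(
      effect = eff,
      df1 = df1, df2 = df2,
      df1_reported = df1 * use_eps, df2_reported = df2 * use_eps,
      statistic = Fv,
      p = stats::pf(Fv, df1 * use_eps, df2 * use_eps, lower.tail = FALSE),
      p_uncorrected = p_unc,
      partial_eta_sq = ss_eff / (ss_eff + ss_err),
      mauchly_p = mauchly_p,
      hf_epsilon = if (violated) hf_eps else NA_real_,
      correction = if (violated) "huynh-feldt" else "none"
    )
  })
}

#' Dunn-Sidak multiple-comparison adjustment
#'
#' Adjusted p values are `1 - (1 - p)^m` (clipped to 1), and the per-test
#' alpha for family level `alpha` is `1 - (1 - alpha)^(1/m)`.
#'
#' @param p_values Raw p values.
#' @param m Number of comparisons (defaults to `length(p_values)`).
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble with `p_raw`, `p_adj`, `per_test_alpha`, `significant`.
#' @export
dunn_sidak <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p_adj <- pmin(1, 1 - (1 - p_values)^m)
  per_test <- 1 - (1 - alpha)^(1 / m)
  tibble::tibble(
    p_raw = p_values, p_adj = p_adj,
    per_test_alpha = per_test,
    significant = p_adj < alpha
  )
}
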