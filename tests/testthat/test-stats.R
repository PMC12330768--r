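test_that("paired comparison gates on normality of the differences", {
  withr::with_seed(6, {
    a <- rnorm(12); b <- a + rnorm(12, 0.1, 0.2)
  })
  res <- paired_compare(a, b)
  expect_equal(res$test, "paired_t")
  expect_true(res$p >= 0 && res$p <= 1)
  # heavily skewed differences take the nonparametric path
  withr::with_seed(2, {
    d <- rexp(15)^3
  })
  res2 <- paired_compare(d, rep(0, 15))
  expect_equal(res2$test, "wilcoxon_signed_rank")
  # identical samples: t path with t = 0, p = 1
  res3 <- paired_compare(1:5, 1:5)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
  expect_error(paired_compare(1:2, 1:3), "length")
})

test_that("wilcoxon path matches a brute-force signed-rank statistic", {
  a <- c(3.1, 4.0, 2.2, 5.5, 1.0, 6.3)
  b <- c(2.0, 4.4, 1.1, 2.2, 0.5, 1.9)
  d <- a - b
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
  expect_equal(unname(wt$statistic), V)
})

test_that("friedman omnibus and conover post hocs follow the rank formulas", {
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  colnames(m) <- c("x", "y", "z")
  # strictly ordered conditions reach the rank-formula maximum n*(k-1)
  res <- friedman_conover(m)
  expect_equal(res$omnibus$statistic, 4 * (3 - 1))
  # identical conditions: chi-square 0
  expect_equal(friedman_conover(matrix(5, 4, 3))$omnibus$statistic, 0)

  # hand-ranked 4-subject toy
  toy <- matrix(c(2, 1, 3,
                  3, 1, 2,
                  2, 1, 3,
                  3, 2, 1), 4, 3, byrow = TRUE)
  fr <- friedman_conover(toy)
  expect_equal(fr$omnibus$statistic, unname(friedman.test(toy)$statistic))
  # Conover: compare to direct computation
  ranks <- t(apply(toy, 1, rank))
  R <- colSums(ranks)
  A <- sum(ranks^2); B <- sum(R^2) / 4
  dfree <- 3 * 2
  denom <- sqrt(2 * 4 * (A - B) / dfree)
  t12 <- abs(R[1] - R[2]) / denom
  got <- fr$pairwise$statistic[fr$pairwise$cond1 == "cond1" &
                                 fr$pairwise$cond2 == "cond2"]
  expect_equal(unname(got), unname(t12))
  expect_true(all(fr$pairwise$p_adj >= fr$pairwise$p_raw - 1e-12))
})

test_that("two-way repeated-measures ANOVA matches the SS-decomposition oracle", {
  withr::with_seed(10, {
    d <- expand.grid(subject = sprintf("s%d", 1:6), a = c("a1", "a2"),
                     b = c("b1", "b2", "b3"))
    d$value <- rnorm(nrow(d)) +
      as.numeric(d$a == "a2") * 0.8 +
      as.numeric(d$b == "b3") * 0.5
  })
  res <- rm_anova2(d)
  oracle <- oracle_rm_anova_ss(d)
  expect_equal(res$statistic[res$effect == "a"], oracle$F_a, tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "b"], oracle$F_b, tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "a:b"], oracle$F_ab, tolerance = 1e-8)
  expect_equal(res$partial_eta_sq[res$effect == "a"], oracle$peta_a,
               tolerance = 1e-8)
  expect_equal(res$partial_eta_sq[res$effect == "b"], oracle$peta_b,
               tolerance = 1e-8)
  # two-level effect: sphericity trivially holds, no correction applied
  expect_equal(res$correction[res$effect == "a"], "none")
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))

  # all cells equal: F = 0 for every effect
  d0 <- dplyr::mutate(d, value = 3)
  res0 <- rm_anova2(d0)
  expect_true(all(abs(res0$statistic) < 1e-10 | is.nan(res0$statistic)))
})

test_that("Huynh-Feldt correction engages when sphericity is violated", {
  withr::with_seed(21, {
    n <- 10
    base <- rnorm(n)
    d <- expand.grid(subject = sprintf("s%d", 1:n), a = c("a1", "a2"),
                     b = c("b1", "b2", "b3"))
    # strongly heterogeneous covariance across b to break sphericity
    d$value <- base[as.integer(factor(d$subject))] *
      (1 + 4 * as.numeric(d$b == "b3")) + rnorm(nrow(d), 0, 0.2)
  })
  res <- rm_anova2(d)
  rb <- res[res$effect == "b", ]
  if (!is.na(rb$mauchly_p) && rb$mauchly_p < 0.05) {
    expect_equal(rb$correction, "huynh-feldt")
    expect_lt(rb$df1_reported, rb$df1)
    expect_true(is.finite(rb$p) && rb$p >= 0 && rb$p <= 1)
  } else {
    succeed("sphericity not violated in this draw")
  }
})

test_that("Dunn-Sidak adjustment follows its closed form and is monotone", {
  expect_equal(dunn_sidak(0.5, m = 2)$p_adj, 0.75)
  expect_equal(dunn_sidak(0.2, m = 1)$p_adj, 0.2)
  expect_equal(dunn_sidak(0.1, m = 3)$per_test_alpha,
               1 - (1 - 0.05)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(dunn_sidak(0.1, m = 3)$per_test_alpha, 6), 0.016952)
  p <- c(0.001, 0.02, 0.3, 0.8)
  adj <- dunn_sidak(p)$p_adj
  expect_true(all(diff(adj) > 0))
  expect_true(all(adj <= 1))
})

test_that("gated tests hold their nominal type-I error under the null", {
  withr::with_seed(99, {
    n_rep <- 400
    rej <- replicate(n_rep, {
      a <- rnorm(10); b <- rnorm(10)
      paired_compare(a, b)$p < 0.05
    })
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
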