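# Independent brute-force oracles used to check the package's vectorized
# implementations on small inputs.

# Burst chaining straight from the definition: walk the sorted onsets and
# split whenever the gap to the previous onset is >= gap.
oracle_bursts <- function(onsets, gap = 0.5) {
  onsets <- sort(onsets)
  n <- length(onsets)
  if (n == 0) return(list(chain = integer(0), in_burst = logical(0)))
  chain <- integer(n)
  chain[1] <- 1L
  for (i in seq_len(n)[-1]) {
    chain[i] <- if (onsets[i] - onsets[i - 1] < gap) chain[i - 1] else chain[i - 1] + 1L
  }
  sizes <- table(chain)
  list(chain = chain, in_burst = as.integer(sizes[as.character(chain)]) >= 2L)
}

# O(n*m) co-occurrence check.
oracle_co_occur <- function(tw_on, sp_on, sp_off) {
  twitch_flag <- vapply(tw_on, function(x) any(x >= sp_on & x < sp_off),
                        logical(1))
  spindle_flag <- vapply(seq_along(sp_on), function(j) {
    any(tw_on >= sp_on[j] & tw_on < sp_off[j])
  }, logical(1))
  list(twitch_flag = twitch_flag, spindle_flag = spindle_flag)
}

# Cell-mean sums-of-squares decomposition for a fully within-subject
# two-way design (long data: subject, a, b, value).
oracle_rm_anova_ss <- function(data) {
  g <- mean(data$value)
  subj <- tapply(data$value, data$subject, mean)
  ma <- tapply(data$value, data$a, mean)
  mb <- tapply(data$value, data$b, mean)
  mab <- tapply(data$value, interaction(data$a, data$b), mean)
  msa <- tapply(data$value, interaction(data$subject, data$a), mean)
  msb <- tapply(data$value, interaction(data$subject, data$b), mean)
  n_s <- length(unique(data$subject))
  n_a <- length(unique(data$a))
  n_b <- length(unique(data$b))
  ss_a <- n_s * n_b * sum((ma - g)^2)
  ss_b <- n_s * n_a * sum((mb - g)^2)
  ss_ab <- n_s * sum((mab - g)^2) - ss_a - ss_b
  ss_subj <- n_a * n_b * sum((subj - g)^2)
  ss_err_a <- n_b * sum((msa - g)^2) - ss_a - ss_subj
  ss_err_b <- n_a * sum((msb - g)^2) - ss_b - ss_subj
  ss_tot <- sum((data$value - g)^2)
  ss_err_ab <- ss_tot - ss_a - ss_b - ss_ab - ss_subj - ss_err_a - ss_err_b
  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  list(
    F_a = f_of(ss_a, n_a - 1, ss_err_a, (n_s - 1) * (n_a - 1)),
    F_b = f_of(ss_b, n_b - 1, ss_err_b, (n_s - 1) * (n_b - 1)),
    F_ab = f_of(ss_ab, (n_a - 1) * (n_b - 1), ss_err_ab,
                (n_s - 1) * (n_a - 1) * (n_b - 1)),
    peta_a = ss_a / (ss_a + ss_err_a),
    peta_b = ss_b / (ss_b + ss_err_b),
    peta_ab = ss_ab / (ss_ab + ss_err_ab)
  )
}

# Closed-form Cohen's kappa from a 2x2 table (a = both present,
# b = only coder 1, c = only coder 2, d = both absent).
oracle_kappa_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

# Small helper: a single-channel recording from a waveform.
toy_recording <- function(x, fs = 250, label = "C3") {
  eeg_recording(matrix(x, nrow = 1), fs, label)
}
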