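# Independent brute-force oracles, deliberately written with different
# numerics than the package (plain Riemann sums on a fine grid, direct
# textbook formulas) so agreement is evidence, not tautology.

# Zeroth and first moments of the net curve by midpoint Riemann sum at a
# fine step. `fun(t)` returns raw intensity; `baseline` is subtracted and
# the result clipped at zero (same net-curve convention as the package —
# the oracle checks the integration, not the baseline estimator).
oracle_moments <- function(fun, baseline, t_end, dt = 1e-3) {
  t <- seq(dt / 2, t_end - dt / 2, by = dt)
  net <- pmax(fun(t) - baseline, 0)
  auc <- sum(net) * dt
  list(auc = auc, mtt = sum(t * net) * dt / auc)
}

# Classical one-way ANOVA F from sums of squares, textbook form.
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  k <- nlevels(groups); N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Pearson chi-square from expected counts, direct formula.
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Samples with exactly prescribed mean and SD (for summary-statistic
# ANOVA reconstruction).
moments_sample <- function(mean, sd, n) {
  z <- seq_len(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# Compact fixtures -----------------------------------------------------------

# Symmetric triangular pulse with a flat zero lead-in; steep = TRUE makes
# the first rising sample cross the 10%-range threshold so the estimated
# baseline is exactly zero.
triangle_curve <- function(lead = 20, half = 50, height = 100, dt = 1,
                           total = 200) {
  t <- seq(0, total, by = dt)
  apex <- lead + half
  y <- pmax(0, height * (1 - abs(t - apex) / half))
  intensity_curve(t, y)
}

protocol_times <- function() (0:119) * 5

# The default profile takes a couple of seconds to calibrate; share one
# instance across test files.
group_profiles_cached <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) prof <<- group_profiles()
    prof
  }
})
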