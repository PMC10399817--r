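# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Mann-Whitney oracle enumerates labelings
# with combn and counts pairs directly; the KS oracle evaluates the
# empirical CDF at every sample point and its left limit.

# U statistic by direct pair counting (no ranks).
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided p by full enumeration of all choose(n1+n2, n1) labelings.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_obs <- oracle_u(x, y)
  u_min <- min(u_obs, n1 * (N - n1) - u_obs)
  labelings <- utils::combn(N, n1)
  us <- apply(labelings, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  min(1, 2 * mean(us <= u_min + 1e-9))
}

# sup_x |F_emp(x) - Phi((x - mean)/sd)| over sample points and left limits.
oracle_ks_stat <- function(x) {
  n <- length(x)
  mu <- mean(x); s <- sd(x)
  d <- 0
  for (xi in x) {
    Fi <- sum(x <= xi) / n
    Fi_left <- sum(x < xi) / n
    P <- pnorm((xi - mu) / s)
    d <- max(d, abs(Fi - P), abs(Fi_left - P))
  }
  d
}

# FFT amplitude of the dominant component over a window.
fft_amplitude <- function(y) {
  n <- length(y)
  2 * max(Mod(stats::fft(y))[2:floor(n / 2)]) / n
}

# Small scenarios shared by tests: durations are short so a test replicate
# costs well under a second; statistical structure is unchanged.
tiny_scenario <- function(...) {
  vc_scenario(duration_on = 2, duration_off = 1, ...)
}

null_scenario <- function(seed = 424242, ...) {
  tiny_scenario(
    stiffness_multipliers_experimental = rep(1, 7),
    emg_amplitude_factors_experimental = rep(1, 7),
    emg_amplitude_factors_control = rep(1, 7),
    seed = seed, ...)
}

const_emg <- function(values, fs = 1000, ...) {
  vc_recording(values, fs = fs, channel = "EMG", ...)
}
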