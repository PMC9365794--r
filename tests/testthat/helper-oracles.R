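# Independent oracles used across tests.

# Two-sided Fisher exact p for a 2x2 table by direct enumeration of the
# hypergeometric distribution (binomial coefficients only; independent
# of stats::fisher.test). Table: rows = groups, cols = outcome.
fisher_exact_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  probs <- choose(m, kk) * choose(n, k - kk) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A bare current trace holding a single instantaneous-rise exponential
# EPSC, for detector unit tests.
single_event_trace <- function(amp_pa = 20, tau_ms = 2, onset_ms = 500,
                               duration_ms = 2000, dt_ms = 0.05,
                               noise_sd = 0, baseline_pa = 0, seed = 1) {
  n <- as.integer(duration_ms / dt_ms)
  y <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n, 0, noise_sd))
       else numeric(n)
  y <- y + baseline_pa
  i0 <- as.integer(onset_ms / dt_ms) + 1L
  k <- exp(-(seq_len(n - i0 + 1L) - 1L) * dt_ms / tau_ms)
  y[i0:n] <- y[i0:n] - amp_pa * k
  trace(y, dt_ms, "current")
}

# Symmetric triangular "spike" rising from a flat baseline, for
# template-shape unit tests.
triangle_spike_trace <- function(base_mv = -60, thr_mv = -30, amp_mv = 60,
                                 rise_ms = 1, fall_ms = 2, dt_ms = 0.05,
                                 pre_ms = 50, post_ms = 50,
                                 ramp_ms = 10) {
  t <- seq(0, pre_ms + ramp_ms + rise_ms + fall_ms + post_ms, by = dt_ms)
  v <- rep(base_mv, length(t))
  s1 <- pre_ms; s2 <- s1 + ramp_ms; s3 <- s2 + rise_ms; s4 <- s3 + fall_ms
  i <- t >= s1 & t < s2
  v[i] <- base_mv + (thr_mv - base_mv) * (t[i] - s1) / ramp_ms
  i <- t >= s2 & t < s3
  v[i] <- thr_mv + amp_mv * (t[i] - s2) / rise_ms
  i <- t >= s3 & t < s4
  v[i] <- thr_mv + amp_mv * (1 - (t[i] - s3) / fall_ms)
  i <- t >= s4
  v[i] <- thr_mv - (t[i] - s4) * 0.5  # gentle repolarization below threshold
  trace(v, dt_ms, "voltage")
}
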