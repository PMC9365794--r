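# Internal numeric and RNG helpers shared across modules.

# Deterministically split a root seed into n child seeds (all < 2^31).
# Used so every neuron/sweep in a cohort gets an independent, reproducible
# stream regardless of how many random draws its siblings consumed.
split_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Least-squares mono-exponential y(t) = A * exp(-t / tau) by variable
# projection: for fixed tau the amplitude is linear, so only tau is
# profiled (1-D golden-section search). t in ms, tau bounded to
# [tau_min, tau_max]. Returns A, tau_ms, r2 (vs. the zero model).
fit_monoexp <- function(t_ms, y, tau_min = 0.05, tau_max = 100) {
  sse <- function(log_tau) {
    k <- exp(-t_ms / exp(log_tau))
    a <- sum(y * k) / sum(k * k)
    sum((y - a * k)^2)
  }
  opt <- stats::optimize(sse, lower = log(tau_min), upper = log(tau_max))
  tau <- exp(opt$minimum)
  k <- exp(-t_ms / tau)
  a <- sum(y * k) / sum(k * k)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  list(A = a, tau_ms = tau, r2 = r2)
}

# Linear interpolation of the time at which a sampled signal crosses
# `level`, between samples i and i+1.
interp_crossing <- function(t1, t2, v1, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

# Indices of strict local maxima of x (plateau-tolerant on the right).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
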