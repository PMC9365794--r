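test_that("a noiseless 20 pA event is detected at full amplitude", {
  tr <- single_event_trace(amp_pa = 20, tau_ms = 2.3)
  ev <- suppressWarnings(detect_epscs(tr))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amp_pa, 20, tolerance = 0.5 / 20)
  expect_lte(ev$onset_ms, ev$peak_ms)
  expect_error(detect_epscs(trace(rep(-60, 1000), 0.05, "voltage")), "current")
})

test_that("pure-noise traces yield essentially no false events", {
  fp <- 0
  for (s in 1:10) {
    g <- gen_epsc_trace(rate_hz = 0, noise_sd_pa = 2, duration_s = 60, seed = s)
    fp <- fp + nrow(detect_epscs(g$recording$sweeps[[1]]$response))
  }
  # <= 0.02 events/s specificity over 600 s of noise
  expect_lte(fp, 12)
})

test_that("detector recall and precision reach 0.98 on generator traces", {
  rec <- prec <- numeric(0)
  for (s in 1:5) {
    g <- gen_epsc_trace(rate_hz = 1, amp_mean_pa = 20, amp_cv = 0.3,
                        tau_ms = 2.3, noise_sd_pa = 2, duration_s = 60,
                        seed = s)
    ev <- detect_epscs(g$recording$sweeps[[1]]$response)
    m <- match_events(ev, g$truth$event_times_ms)
    rec <- c(rec, m$recall); prec <- c(prec, m$precision)
  }
  expect_gte(mean(rec), 0.98)
  expect_gte(mean(prec), 0.98)
})

test_that("detection is invariant under baseline offset and slow drift", {
  g <- gen_epsc_trace(rate_hz = 1, noise_sd_pa = 2, duration_s = 30, seed = 8)
  tr <- g$recording$sweeps[[1]]$response
  n0 <- nrow(detect_epscs(tr))
  tr_off <- trace(tr$samples - 50, tr$dt_ms, "current")
  expect_equal(nrow(detect_epscs(tr_off)), n0)
  drift <- seq(0, 30, length.out = length(tr$samples))  # 1 pA/s
  tr_dr <- trace(tr$samples + drift, tr$dt_ms, "current")
  n_dr <- nrow(detect_epscs(tr_dr))
  expect_lte(abs(n_dr - n0), max(1, 0.02 * n0))
})

test_that("noiseless decay fits recover tau to one hundredth of a ms", {
  tr <- single_event_trace(amp_pa = 20, tau_ms = 2.0)
  ev <- suppressWarnings(detect_epscs(tr))
  ft <- fit_decay_tau(tr, ev, 1)
  expect_equal(ft$tau_ms, 2.0, tolerance = 0.01)
  expect_gt(ft$r2, 0.99)
})

test_that("a decay contaminated by a larger following event is not fitted", {
  dt <- 0.05
  n <- as.integer(2000 / dt)
  y <- numeric(n)
  k <- function(i0, amp) {
    idx <- i0:n
    y[idx] <<- y[idx] - amp * exp(-(idx - i0) * dt / 2.3)
  }
  k(as.integer(500 / dt), 15)
  k(as.integer(503 / dt), 30)  # 3 ms later, twice as large
  tr <- trace(y, dt, "current")
  ev <- suppressWarnings(detect_epscs(tr, tail_dead_ms = 0))
  ev <- fit_events_tau(tr, ev)
  first <- which.min(ev$onset_ms)
  expect_true(is.na(ev$decay_tau_ms[first]))
  # an isolated control event in the same trace fits fine
  y2 <- numeric(n); y2[as.integer(500 / dt):n] <-
    -20 * exp(-(0:(n - as.integer(500 / dt))) * dt / 2.3)
  tr2 <- trace(y2, dt, "current")
  ev2 <- fit_events_tau(tr2, suppressWarnings(detect_epscs(tr2)))
  expect_equal(ev2$decay_tau_ms[1], 2.3, tolerance = 0.01)
})

test_that("mean fitted tau is within 5% under recording noise", {
  taus <- c()
  for (s in 1:3) {
    g <- gen_epsc_trace(rate_hz = 1, tau_ms = 2.3, noise_sd_pa = 2,
                        duration_s = 60, seed = s)
    tr <- g$recording$sweeps[[1]]$response
    ev <- fit_events_tau(tr, detect_epscs(tr))
    taus <- c(taus, ev$decay_tau_ms[is.finite(ev$decay_tau_ms)])
  }
  expect_gt(length(taus), 100)
  expect_equal(mean(taus), 2.3, tolerance = 0.05)
})

test_that("event summaries obey rate = n / duration and the activity rule", {
  mk <- function(n) {
    if (n == 0) return(empty_ev <- synaptoprobe:::empty_events())
    structure(data.frame(onset_ms = seq_len(n) * 100,
                         peak_ms = seq_len(n) * 100 + 1,
                         amp_pa = rep(20, n), local_baseline_pa = 0,
                         decay_tau_ms = NA_real_, tau_r2 = NA_real_),
              class = c("epsc_events", "data.frame"))
  }
  s <- summarize_events(mk(63), 60)
  expect_equal(s$rate_hz, 1.05)
  expect_equal(s$rate_hz * s$duration_s, s$n_events)
  expect_false(summarize_events(mk(19), 60)$active)
  expect_false(summarize_events(mk(20), 60)$active)  # exact 20: inactive
  expect_true(summarize_events(mk(21), 60)$active)
  # duration scaling: 10 events in 30 s is a normalized count of 20
  s30 <- summarize_events(mk(10), 30)
  expect_false(s30$active)
  expect_match(s30$notes, "normalized")
  s11 <- summarize_events(mk(11), 30)
  expect_true(s11$active)
  # empty events: zero rate, inactive, missing amplitude statistics
  s0 <- summarize_events(mk(0), 60)
  expect_equal(s0$rate_hz, 0)
  expect_false(s0$active)
  expect_true(is.na(s0$mean_amp_pa))
})

test_that("amplitude ECDF comparison flags direction and rejects shifted samples", {
  x <- seq(10, 30, length.out = 50)
  same <- amplitude_ecdf_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(amplitude_ecdf_compare(numeric(0), x), "non-empty")
  rejected <- 0
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(a = rnorm(200, 20, 2), b = rnorm(200, 16, 2)))
    cmp <- amplitude_ecdf_compare(ab$a, ab$b)
    if (cmp$p_value < 0.01) rejected <- rejected + 1
    expect_equal(cmp$direction, -1)
  }
  expect_gte(rejected, 10 * 0.95)
})
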