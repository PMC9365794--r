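# The generators must agree with their own closed forms and be exactly
# reproducible: they are the oracle every analysis stage is scored
# against.

test_that("zero-rate EPSC generator produces pure noise and an empty inventory", {
  g <- gen_epsc_trace(rate_hz = 0, noise_sd_pa = 0, duration_s = 2, seed = 1)
  expect_equal(g$truth$n_events, 0L)
  expect_length(g$truth$event_times_ms, 0)
  expect_true(all(g$recording$sweeps[[1]]$response$samples == 0))
})

test_that("EPSC event counts follow the Poisson law across seeds", {
  counts <- vapply(1:500, function(s)
    gen_epsc_trace(rate_hz = 1, noise_sd_pa = 0, duration_s = 60,
                   seed = s)$truth$n_events, numeric(1))
  # mean of 500 Poisson(60) draws: SE = sqrt(60/500)
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / 500))
  expect_gt(var(counts) / mean(counts), 0.7)  # dispersion consistent with Poisson
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("noiseless kernel: trace minimum is baseline - amplitude at onset", {
  g <- gen_epsc_trace(rate_hz = 1, amp_mean_pa = 20, amp_cv = 0,
                      noise_sd_pa = 0, duration_s = 5, seed = 3)
  y <- g$recording$sweeps[[1]]$response$samples
  expect_gt(g$truth$n_events, 0)
  if (g$truth$n_events == 1) {
    expect_equal(min(y), -20)
    on_i <- floor(g$truth$event_times_ms[1] / 0.05) + 1
    expect_equal(which.min(y), on_i)
  }
  # single isolated event constructed directly
  tr <- single_event_trace(amp_pa = 20, tau_ms = 2)
  expect_equal(min(tr$samples), -20)
})

test_that("EPSC generator rejects invalid parameters", {
  expect_error(gen_epsc_trace(rate_hz = -1), "rate_hz")
  expect_error(gen_epsc_trace(1, duration_s = 0), "duration")
  expect_error(gen_epsc_trace(1, dt_ms = 0), "dt_ms")
  expect_error(gen_epsc_trace(1, amp_cv = -0.1), "amp_cv")
  expect_error(gen_epsc_trace(1, tau_ms = 0), "tau_ms")
})

test_that("no silent truncation: every inventoried event lies within the trace", {
  for (s in 1:20) {
    g <- gen_epsc_trace(rate_hz = 5, noise_sd_pa = 0, duration_s = 2, seed = s)
    expect_true(all(g$truth$event_times_ms >= 0))
    expect_true(all(floor(g$truth$event_times_ms / 0.05) <
                      length(g$recording$sweeps[[1]]$response$samples)))
    expect_equal(g$truth$n_events, length(g$truth$event_times_ms))
    expect_equal(g$truth$n_events, length(g$truth$event_amps_pa))
  }
})

test_that("generation is exactly reproducible from the seed", {
  a <- gen_epsc_trace(rate_hz = 1, duration_s = 2, seed = 11)
  b <- gen_epsc_trace(rate_hz = 1, duration_s = 2, seed = 11)
  expect_identical(a$recording$sweeps[[1]]$response$samples,
                   b$recording$sweeps[[1]]$response$samples)
  expect_identical(a$truth$event_times_ms, b$truth$event_times_ms)
  c <- gen_current_clamp(seed = 11)
  d <- gen_current_clamp(seed = 11)
  expect_identical(c$recording$sweeps[[5]]$response$samples,
                   d$recording$sweeps[[5]]$response$samples)
})

test_that("current-clamp commands follow the 3 pA / 35-step protocol", {
  g <- gen_current_clamp(holding_pa = -20, noise_mv = 0, seed = 1)
  expect_length(g$recording$sweeps, 35)
  proto <- g$recording$protocol
  win <- c(proto$pre_ms, proto$pre_ms + proto$step_ms)
  for (i in c(1, 10, 35)) {
    cmd <- g$recording$sweeps[[i]]$command
    t <- trace_times_ms(cmd)
    lvl <- unique(cmd$samples[t >= win[1] & t < win[2]])
    expect_equal(lvl, -20 - 12 + 3 * (i - 1))
  }
})

test_that("zero F-I gain silences every sweep", {
  g <- gen_current_clamp(f_i_gain = 0, noise_mv = 0, seed = 2)
  expect_true(all(g$truth$spikes_per_step == 0L))
  expect_equal(g$truth$total_evoked, 0L)
  expect_equal(count_total_evoked(g$recording), 0L)
})

test_that("stored template closed forms: FWHM = (rise + fall) / 2", {
  g <- gen_current_clamp(sp = spike_params(rise_ms = 1, fall_ms = 2),
                         noise_mv = 0, seed = 1)
  expect_equal(g$truth$fwhm_ms, 1.5)
  expect_error(gen_current_clamp(sp = spike_params(rise_ms = 200, fall_ms = 250)),
               "wider than the step")
})

test_that("membrane-test trace decays with tau = RC and carries Q = C dV", {
  g <- gen_membrane_test(capacitance_pf = 30, resistance_mohm = 500,
                         step_mv = -5, noise_sd_pa = 0)
  tr <- g$recording$sweeps[[1]]$response
  t <- trace_times_ms(tr)
  in_step <- t >= 50 & t < 200
  y <- tr$samples[in_step]
  plateau <- -5 / 500 * 1000
  # log-linear fit of the transient recovers tau = 500 MOhm * 30 pF = 15 ms
  ts <- t[in_step] - 50
  sel <- ts <= 30
  fit <- lm(log((y - plateau)[sel] / (y[1] - plateau)) ~ 0 + ts[sel])
  expect_equal(-1 / unname(coef(fit)), 15, tolerance = 1e-3)
  # numerical charge integral above plateau equals C * dV = -100 fC at 20 pF
  g2 <- gen_membrane_test(capacitance_pf = 20, resistance_mohm = 500,
                          step_mv = -5, noise_sd_pa = 0)
  tr2 <- g2$recording$sweeps[[1]]$response
  y2 <- tr2$samples[in_step] - (-10)
  q <- sum((y2[-1] + y2[-length(y2)]) / 2) * tr2$dt_ms
  expect_equal(q, -100, tolerance = 0.005)
  expect_equal(g2$truth$q_fc, -100)
})

test_that("zero-amplitude membrane test step yields a flat trace", {
  g <- gen_membrane_test(step_mv = 0, noise_sd_pa = 0)
  expect_true(all(g$recording$sweeps[[1]]$response$samples == 0))
})

test_that("leak-only voltage-clamp response is a flat Ohmic offset", {
  g <- gen_voltage_clamp_iv(na_gmax = 0, kfast_gmax = 0, kslow_gmax = 0,
                            leak_ns = 1, noise_sd_pa = 0, seed = 1)
  k <- which(g$truth$step_mv == -40)
  tr <- g$recording$sweeps[[k]]$response
  t <- trace_times_ms(tr)
  in_step <- t >= 100 & t < 500
  expect_true(all(abs(tr$samples[in_step] - 20) < 1e-9))
  expect_equal(g$truth$kslow_pa[k], 20)
})

test_that("sodium-only truth peaks where Boltzmann x driving force is most negative", {
  g <- gen_voltage_clamp_iv(na_gmax = 5, kfast_gmax = 0, kslow_gmax = 0,
                            leak_ns = 0, noise_sd_pa = 0, seed = 1)
  v <- g$truth$step_mv
  closed_form <- (1 / (1 + exp(-(v + 25) / 6))) * (v - 60)  # unit peak alpha
  expect_equal(which.min(g$truth$na_peak_pa), which.min(closed_form))
  # density is peak / capacitance
  expect_equal(g$truth$na_peak_density, g$truth$na_peak_pa / 20)
})

test_that("cohort configuration enforces group structure", {
  expect_error(cohort_config(groups = list(a = group_spec(5))), "two group")
  expect_error(group_spec(n = 0), "at least one neuron")
  cc <- cohort_config(groups = list(a = group_spec(3), b = group_spec(4)))
  p <- draw_cohort_params(cc, seed = 5)
  expect_equal(nrow(p), 7)
  expect_equal(sum(p$group_label == "a"), 3)
  expect_identical(p, draw_cohort_params(cc, seed = 5))
  expect_false(identical(p$epsc_rate_hz,
                         draw_cohort_params(cc, seed = 6)$epsc_rate_hz))
})

test_that("gen_cohort bundles carry per-component ground truth", {
  cc <- cohort_config(groups = list(a = group_spec(2), b = group_spec(2)),
                      epsc_duration_s = 2)
  co <- gen_cohort(cc, seed = 9)
  expect_length(co$bundles, 4)
  b <- co$bundles[[1]]
  expect_s3_class(b$epsc, "recording")
  expect_s3_class(b$cc, "recording")
  expect_s3_class(b$vc, "recording")
  expect_s3_class(b$mtest, "recording")
  expect_equal(co$truth$true_n_events[1], b$truth$epsc$n_events)
  expect_equal(co$truth$true_total_evoked[1], b$truth$cc$total_evoked)
})
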