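test_that("a flat trace contains no spikes", {
  tr <- trace(rep(-60, 10000), 0.05, "voltage")
  expect_length(detect_spikes(tr), 0)
  expect_error(detect_spikes(trace(rep(0, 100), 0.05, "current")), "voltage")
})

test_that("detected peaks match generator ground truth to within one sample", {
  g <- gen_current_clamp(f_i_gain = 0.2, noise_mv = 0, seed = 3)
  win <- c(100, 500)
  for (k in seq_along(g$recording$sweeps)) {
    pk <- detect_spikes(g$recording$sweeps[[k]]$response, win)
    truth <- g$truth$peak_times_ms[[k]]
    expect_length(pk, length(truth))
    if (length(truth)) expect_true(all(abs(pk - truth) <= 0.05 + 1e-9))
  }
})

test_that("two spikes one refractory apart merge into one detection", {
  dt <- 0.05
  t <- seq(0, 100, by = dt)
  v <- rep(-60, length(t))
  bump <- function(v, at, amp = 55) {
    i <- t >= at & t < at + 0.5
    v[i] <- -60 + amp * (t[i] - at) / 0.5
    j <- t >= at + 0.5 & t < at + 1
    v[j] <- -60 + amp * (1 - (t[j] - at - 0.5) / 0.5)
    v
  }
  v <- bump(v, 50); v <- bump(v, 51)
  n <- length(detect_spikes(trace(v, dt, "voltage"), refractory_ms = 2))
  expect_equal(n, 1)
  # with a permissive refractory the two excursions resolve
  n2 <- length(detect_spikes(trace(v, dt, "voltage"), refractory_ms = 0.2))
  expect_equal(n2, 2)
})

test_that("spike count is invariant under voltage offset and 1-sample shift", {
  g <- gen_current_clamp(f_i_gain = 0.25, noise_mv = 0, seed = 7)
  win <- c(100, 500)
  base <- vapply(g$recording$sweeps,
                 function(s) length(detect_spikes(s$response, win)), numeric(1))
  for (off in c(-10, 5)) {
    shifted <- vapply(g$recording$sweeps, function(s) {
      tr <- s$response; tr$samples <- tr$samples + off
      length(detect_spikes(tr, win))
    }, numeric(1))
    expect_identical(shifted, base)
  }
  shifted1 <- vapply(g$recording$sweeps, function(s) {
    tr <- s$response
    tr$samples <- c(tr$samples[1], tr$samples[-length(tr$samples)])
    length(detect_spikes(tr, win))
  }, numeric(1))
  expect_identical(shifted1, base)
})

test_that("total evoked count respects the first-17-step window", {
  # rheobase above the largest current reached within the count window:
  # spikes appear only in later steps, so the windowed total is zero
  g <- gen_current_clamp(f_i_gain = 0.3, rheobase_pa = 48, noise_mv = 0, seed = 1)
  expect_gt(sum(g$truth$spikes_per_step), 0)
  expect_equal(count_total_evoked(g$recording), 0L)
  expect_equal(count_total_evoked(g$recording, count_steps = 35L),
               sum(g$truth$spikes_per_step))
  expect_error(count_total_evoked(g$recording, count_steps = 40L), "40")
})

test_that("spike shape of a triangular template matches its closed form", {
  tr <- triangle_spike_trace(thr_mv = -30, amp_mv = 60, rise_ms = 1, fall_ms = 2)
  sh <- measure_spike_shape(tr)
  expect_equal(sh$threshold_mv, -30, tolerance = 0.5)
  expect_equal(sh$amplitude_mv, 60, tolerance = 1)
  # half-max crossings at 0.5 ms (rise) and 2.0 ms (fall): FWHM 1.5 ms
  expect_equal(sh$width_fwhm_ms, 1.5, tolerance = 2 * tr$dt_ms)
  expect_error(measure_spike_shape(trace(rep(-60, 1000), 0.05, "voltage")),
               "no spike")
})

test_that("FWHM and amplitude are invariant under time reversal of a symmetric template", {
  tr <- triangle_spike_trace(rise_ms = 1.5, fall_ms = 1.5)
  sh <- measure_spike_shape(tr)
  rev_tr <- trace(rev(tr$samples), tr$dt_ms, "voltage")
  # reversed trace: the "rise" is the old fall; same width and height
  sh_r <- measure_spike_shape(rev_tr)
  expect_equal(sh_r$width_fwhm_ms, sh$width_fwhm_ms, tolerance = 2 * tr$dt_ms)
  expect_equal(sh_r$amplitude_mv, sh$amplitude_mv, tolerance = 1)
})

test_that("all four shape fields match generator ground truth on noiseless sweeps", {
  for (s in 1:5) {
    sp <- spike_params(threshold_mv = -32 + s, amplitude_mv = 55 + s,
                       rise_ms = 0.5 + 0.3 * s, fall_ms = 3 + 0.4 * s,
                       ahp_mv = -5 - s)
    g <- gen_current_clamp(sp = sp, noise_mv = 0, seed = s)
    sh <- first_spike_shape(g$recording)
    expect_equal(sh$threshold_mv, g$truth$threshold_mv, tolerance = 0.5)
    expect_equal(sh$amplitude_mv, g$truth$amplitude_mv, tolerance = 1)
    expect_equal(sh$width_fwhm_ms, g$truth$fwhm_ms, tolerance = 0.1)
    expect_equal(sh$fast_ahp_mv, g$truth$ahp_mv, tolerance = 0.5)
  }
})

test_that("threshold localization stays within a sample across rise times", {
  errs <- vapply(seq(0.5, 2, by = 0.25), function(r) {
    g <- gen_current_clamp(sp = spike_params(rise_ms = r), noise_mv = 0,
                           seed = 1)
    abs(first_spike_shape(g$recording)$threshold_mv - g$truth$threshold_mv)
  }, numeric(1))
  # 1 sample on the shallow pre-ramp (1 mV/ms at 20 kHz) is 0.05 mV
  expect_true(all(errs <= 0.06))
})

test_that("holding-current QC applies the >50 pA rule strictly", {
  mk <- function(h) {
    g <- gen_current_clamp(holding_pa = h, noise_mv = 0, seed = 1)
    qc_holding(g$recording)
  }
  expect_true(mk(-30)$passed)
  expect_false(mk(-51)$passed)
  expect_true(mk(50)$passed)   # "more than 50" is strict
  expect_true(mk(-50)$passed)
  # holding read from the command baseline when metadata is absent
  g <- gen_current_clamp(holding_pa = -60, noise_mv = 0, seed = 1)
  g$recording$metadata$holding_pa <- NULL
  q <- qc_holding(g$recording)
  expect_equal(q$holding_pa, -60)
  expect_false(q$passed)
  # indeterminate defaults to exclusion
  r <- recording("x", mode = "voltage_clamp",
                 sweeps = list(list(response = trace(rep(0, 100), 0.05, "current"))),
                 protocol = "gap_free")
  expect_false(qc_holding(r)$passed)
  expect_true(qc_holding(r, indeterminate_passes = TRUE)$passed)
})
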