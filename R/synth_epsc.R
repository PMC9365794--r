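#' Simulate a gap-free spontaneous EPSC recording
#'
#' Generates a voltage-clamp current trace at a -60 mV command containing
#' a homogeneous-Poisson train of spontaneous excitatory postsynaptic
#' currents on a Gaussian-noise baseline, together with the complete
#' ground truth (exact event times and amplitudes) needed to score any
#' detector against it.
#'
#' Each event is an instantaneous-rise, mono-exponential-decay *inward*
#' (negative) current deflection; amplitudes are drawn from a lognormal
#' distribution parameterized by its mean and coefficient of variation.
#' Overlapping events sum linearly; the ground-truth inventory still
#' lists them individually. Events drawn past the recording end are
#' excluded from both the trace and the inventory (no silent truncation).
#'
#' @param rate_hz Event rate in events/s (>= 0). A rate of 0 yields a
#'   pure-noise trace with an empty inventory.
#' @param amp_mean_pa Mean event amplitude (magnitude, pA, > 0).
#' @param amp_cv Coefficient of variation of the amplitude distribution
#'   (>= 0; 0 gives identical amplitudes).
#' @param tau_ms Decay time constant in ms (> 0).
#' @param noise_sd_pa Standard deviation of the additive white Gaussian
#'   baseline noise, pA.
#' @param duration_s Recording duration in s (> 0; 60 s is the duration
#'   over which the ">20 events" activity rule is defined).
#' @param dt_ms Sampling interval, ms (default 0.05 = 20 kHz).
#' @param seed Integer seed; the recording is exactly reproducible from
#'   its arguments plus this seed.
#' @param baseline_pa Constant holding-current offset added to the whole
#'   trace (pA); detection must be invariant to it.
#' @param cell_id,group_label Metadata passed through to the recording.
#' @return A list with elements `recording` (a gap-free voltage-clamp
#'   [recording()]) and `truth` (class `synth_truth`: `event_times_ms`,
#'   `event_amps_pa`, the generative parameters, and `n_events`).
#' @examples
#' g <- gen_epsc_trace(rate_hz = 1, duration_s = 2, seed = 1)
#' g$truth$n_events
#' @export
gen_epsc_trace <- function(rate_hz, amp_mean_pa = 20, amp_cv = 0.3,
                           tau_ms = 2.3, noise_sd_pa = 2,
                           duration_s = 60, dt_ms = 0.05, seed = 1,
                           baseline_pa = 0,
                           cell_id = "synth", group_label = "synthetic") {
  if (!is.finite(rate_hz) || rate_hz < 0) stop("`rate_hz` must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (dt_ms <= 0) stop("`dt_ms` must be positive", call. = FALSE)
  if (amp_mean_pa <= 0) stop("`amp_mean_pa` must be positive", call. = FALSE)
  if (amp_cv < 0) stop("`amp_cv` must be >= 0", call. = FALSE)
  if (tau_ms <= 0) stop("`tau_ms` must be positive", call. = FALSE)

  dur_ms <- duration_s * 1000
  n <- as.integer(round(dur_ms / dt_ms))

  out <- with_seed(seed, {
    n_ev <- stats::rpois(1, rate_hz * duration_s)
    times <- sort(stats::runif(n_ev, 0, dur_ms))
    amps <- draw_lognormal(n_ev, amp_mean_pa, amp_cv)
    # events whose onset sample falls past the last sample are dropped
    keep <- floor(times / dt_ms) < n
    times <- times[keep]; amps <- amps[keep]
    y <- if (noise_sd_pa > 0) stats::rnorm(n, 0, noise_sd_pa) else numeric(n)
    list(times = times, amps = amps, y = y)
  })

  y <- out$y + baseline_pa
  # kernel support: decay to < 1e-4 of peak
  klen <- as.integer(ceiling(tau_ms * log(1e4) / dt_ms)) + 1L
  kern <- exp(-(seq_len(klen) - 1L) * dt_ms / tau_ms)
  for (i in seq_along(out$times)) {
    i0 <- as.integer(floor(out$times[i] / dt_ms)) + 1L
    i1 <- min(n, i0 + klen - 1L)
    y[i0:i1] <- y[i0:i1] - out$amps[i] * kern[seq_len(i1 - i0 + 1L)]
  }

  resp <- trace(y, dt_ms = dt_ms, channel = "current")
  rec <- recording(cell_id = cell_id, group_label = group_label,
                   mode = "voltage_clamp",
                   sweeps = list(list(command = NULL, response = resp)),
                   protocol = "gap_free",
                   metadata = list(holding_mv = -60, bicuculline = TRUE,
                                   duration_s = duration_s))
  truth <- structure(
    list(kind = "epsc", seed = seed, rate_hz = rate_hz,
         amp_mean_pa = amp_mean_pa, amp_cv = amp_cv, tau_ms = tau_ms,
         noise_sd_pa = noise_sd_pa, duration_s = duration_s,
         baseline_pa = baseline_pa,
         n_events = length(out$times),
         event_times_ms = out$times, event_amps_pa = out$amps),
    class = "synth_truth"
  )
  list(recording = rec, truth = truth)
}

# Lognormal draws parameterized by arithmetic mean m and CV.
draw_lognormal <- function(n, m, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}
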