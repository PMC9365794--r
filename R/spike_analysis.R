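#' Detect action potentials in a current-clamp sweep
#'
#' Detection criterion (the classical dV/dt rule, every constant a
#' configuration key): a spike is a local maximum of the lightly smoothed
#' voltage whose peak exceeds `min_peak_mv` and which is preceded, within
#' 2 ms, by a smoothed dV/dt crossing of `dvdt_thresh` mV/ms. Peaks
#' closer together than `refractory_ms` are merged (the earlier, larger
#' excursion wins), preventing double counts on noisy repolarizations.
#'
#' @param tr A voltage [trace()].
#' @param window_ms Length-2 numeric, the analysis window in
#'   sweep-relative ms (typically the current step); `NULL` = whole trace.
#' @param dvdt_thresh Rising-slope criterion, mV/ms.
#' @param min_peak_mv Absolute peak requirement, mV.
#' @param refractory_ms Merge window, ms.
#' @param sg_window_ms Savitzky-Golay smoothing window used before
#'   differentiation, ms.
#' @return Numeric vector of spike peak times (sweep-relative ms, sorted).
#' @export
detect_spikes <- function(tr, window_ms = NULL,
                          dvdt_thresh = 10, min_peak_mv = -20,
                          refractory_ms = 2, sg_window_ms = 0.5) {
  assert_channel(tr, "voltage", "detect_spikes")
  v <- tr$samples
  dt <- tr$dt_ms
  n <- length(v)
  vs <- sg_smooth(v, dt, sg_window_ms)
  dvdt <- c(0, diff(vs)) / dt

  # one detection per suprathreshold excursion, with 5 mV hysteresis:
  # an excursion opens when vs reaches min_peak_mv and closes only when
  # vs falls 5 mV below it, so noise wiggles around the criterion level
  # cannot split one spike into several excursions
  hyst_mv <- 5
  near <- vs >= min_peak_mv - hyst_mv
  peaks <- integer(0)
  if (any(vs >= min_peak_mv)) {
    r <- rle(near)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    look <- max(1L, as.integer(round(2 / dt)))
    for (ri in which(r$values)) {
      a <- starts[ri]; b <- ends[ri]
      p <- a + which.max(vs[a:b]) - 1L
      if (vs[p] >= min_peak_mv &&
          max(dvdt[max(1L, a - look):p]) >= dvdt_thresh) {
        # refine to the raw local maximum (smoothing biases the argmax
        # of an asymmetric peak toward its shallower flank)
        rr <- max(a, p - 5L):min(b, p + 5L)
        peaks <- c(peaks, rr[which.max(v[rr])])
      }
    }
  }
  if (!is.null(window_ms)) {
    t <- trace_times_ms(tr)[peaks]
    peaks <- peaks[t >= window_ms[1] & t <= window_ms[2]]
  }
  if (length(peaks) > 1L) {
    refr <- refractory_ms / dt
    keep <- peaks[1]
    for (p in peaks[-1]) {
      if (p - keep[length(keep)] >= refr) keep <- c(keep, p)
    }
    peaks <- keep
  }
  tr$t0_ms + (peaks - 1L) * dt
}

sg_smooth <- function(x, dt_ms, window_ms, order = 3) {
  nw <- max(order + 2, as.integer(round(window_ms / dt_ms)) + 1L)
  if (nw %% 2L == 0L) nw <- nw + 1L
  if (nw >= length(x)) return(x)
  signal::sgolayfilt(x, p = order, n = nw)
}

step_window_ms <- function(protocol) {
  c(protocol$pre_ms, protocol$pre_ms + protocol$step_ms)
}

#' Total evoked action potentials over the first steps of a family
#'
#' Sums the spikes detected during the step window of the first
#' `count_steps` sweeps — the excitability measure used for group
#' comparisons (by convention the first 17 of 35 depolarization steps).
#' Spikes outside the step window (rebound spikes) are not counted.
#'
#' @param rec A current-clamp [recording()] with a step protocol.
#' @param count_steps Number of initial steps to total; defaults to the
#'   protocol's `count_steps`.
#' @param ... Detection parameters forwarded to [detect_spikes()].
#' @return Integer total spike count.
#' @export
count_total_evoked <- function(rec, count_steps = NULL, ...) {
  if (!inherits(rec, "recording") || rec$mode != "current_clamp")
    stop("`rec` must be a current-clamp recording", call. = FALSE)
  if (identical(rec$protocol, "gap_free"))
    stop("a step protocol is required to count evoked spikes", call. = FALSE)
  count_steps <- as.integer(count_steps %||% rec$protocol$count_steps)
  if (length(rec$sweeps) < count_steps)
    stop("recording has ", length(rec$sweeps), " sweeps but count_steps = ",
         count_steps, call. = FALSE)
  win <- step_window_ms(rec$protocol)
  total <- 0L
  for (k in seq_len(count_steps))
    total <- total + length(detect_spikes(rec$sweeps[[k]]$response, win, ...))
  total
}

#' Measure spike shape on the first evoked action potential
#'
#' Shape metrics follow the operational definitions used for the
#' reported spike statistics:
#' * **threshold** — the membrane potential at the first maximum of the
#'   second derivative of voltage vs. time before the peak. The second
#'   derivative is computed by central differences after Savitzky-Golay
#'   smoothing (raw second differences at 20 kHz are noise-dominated);
#'   "first maximum" means the earliest local maximum exceeding 10% of
#'   the largest second-derivative value in the 10 ms pre-peak search
#'   window; ties go to the earliest.
#' * **amplitude** — peak voltage minus threshold.
#' * **width_fwhm** — time between the half-amplitude crossings
#'   bracketing the peak, with sub-sample linear interpolation.
#' * **fast_ahp** — voltage 5 ms after the falling phase re-crosses the
#'   threshold, minus the threshold (typically negative); `NA` if the
#'   sweep ends first.
#'
#' @param tr Voltage [trace()] of the lowest-current sweep containing at
#'   least one spike.
#' @param window_ms Analysis window passed to [detect_spikes()].
#' @param search_ms Pre-peak window searched for the threshold, ms.
#' @param sg_window_ms Savitzky-Golay window, ms.
#' @param ... Further arguments for [detect_spikes()].
#' @return A list of class `spike_shape`: `threshold_mv`, `amplitude_mv`,
#'   `width_fwhm_ms`, `fast_ahp_mv`, `peak_time_ms`.
#' @export
measure_spike_shape <- function(tr, window_ms = NULL, search_ms = 10,
                                sg_window_ms = 0.5, ...) {
  assert_channel(tr, "voltage", "measure_spike_shape")
  pk_times <- detect_spikes(tr, window_ms, sg_window_ms = sg_window_ms, ...)
  if (length(pk_times) == 0L)
    stop("no spike found in sweep; spike shape undefined", call. = FALSE)
  dt <- tr$dt_ms
  v <- tr$samples
  p <- as.integer(round((pk_times[1] - tr$t0_ms) / dt)) + 1L
  # refine to the raw local peak (detection works on smoothed voltage)
  r <- max(1L, p - 5L):min(length(v), p + 5L)
  p <- r[which.max(v[r])]

  vs <- sg_smooth(v, dt, sg_window_ms)
  d2 <- c(0, diff(vs, differences = 2), 0) / dt^2
  lo <- max(2L, p - as.integer(round(search_ms / dt)))
  seg <- lo:(p - 1L)
  cand <- seg[local_maxima(d2[seg])]
  if (length(cand) == 0L) cand <- seg[which.max(d2[seg])]
  gmax <- max(d2[seg])
  cand <- cand[d2[cand] >= 0.1 * gmax]
  ti <- cand[1]  # earliest qualifying maximum
  threshold <- v[ti]
  amplitude <- v[p] - threshold
  if (amplitude <= 0)
    stop("degenerate spike: peak does not exceed threshold", call. = FALSE)

  half <- threshold + amplitude / 2
  t_all <- trace_times_ms(tr)
  # rising half-crossing: last upward crossing before the peak
  i <- p
  while (i > 1L && v[i - 1L] > half) i <- i - 1L
  t_rise <- if (i > 1L)
    interp_crossing(t_all[i - 1L], t_all[i], v[i - 1L], v[i], half)
  else t_all[1]
  # falling half-crossing: first downward crossing after the peak
  j <- p
  while (j < length(v) && v[j + 1L] > half) j <- j + 1L
  t_fall <- if (j < length(v))
    interp_crossing(t_all[j], t_all[j + 1L], v[j], v[j + 1L], half)
  else t_all[length(v)]
  width <- t_fall - t_rise

  # threshold re-crossing on the falling phase, then +5 ms
  k <- p
  while (k < length(v) && v[k] > threshold) k <- k + 1L
  fast_ahp <- NA_real_
  if (k < length(v)) {
    ahp_i <- k + as.integer(round(5 / dt))
    if (ahp_i <= length(v)) fast_ahp <- v[ahp_i] - threshold
  }

  structure(list(threshold_mv = threshold, amplitude_mv = amplitude,
                 width_fwhm_ms = width, fast_ahp_mv = fast_ahp,
                 peak_time_ms = t_all[p]),
            class = "spike_shape")
}

#' Spike shape of a step-family recording
#'
#' Convenience wrapper: finds the lowest-current sweep containing at
#' least one spike (the first evoked action potential) and measures its
#' shape.
#' @param rec Current-clamp [recording()].
#' @param ... Forwarded to [measure_spike_shape()]/[detect_spikes()].
#' @return A `spike_shape`, or `NULL` if no sweep spikes.
#' @export
first_spike_shape <- function(rec, ...) {
  if (!inherits(rec, "recording") || rec$mode != "current_clamp")
    stop("`rec` must be a current-clamp recording", call. = FALSE)
  win <- if (identical(rec$protocol, "gap_free")) NULL
         else step_window_ms(rec$protocol)
  for (s in rec$sweeps) {
    if (length(detect_spikes(s$response, win, ...)) > 0L)
      return(measure_spike_shape(s$response, win, ...))
  }
  NULL
}

#' Holding-current quality control
#'
#' Neurons that needed more than `max_holding_pa` (default 50 pA) of
#' steady current to be held at the target potential are discarded from
#' group statistics ("more than" is read strictly: exactly 50 pA
#' passes). The holding current is taken from the recording metadata or,
#' failing that, from the mean of the command channel's pre-step
#' baseline. If it cannot be determined the result is indeterminate and,
#' by default, the neuron is excluded.
#'
#' @param rec A [recording()].
#' @param max_holding_pa QC limit, pA.
#' @param indeterminate_passes Treat an unknown holding current as a
#'   pass? Default `FALSE` (exclude).
#' @return A list of class `qc_result`: `holding_pa`, `passed`,
#'   `reasons` (character).
#' @export
qc_holding <- function(rec, max_holding_pa = 50, indeterminate_passes = FALSE) {
  holding <- rec$metadata$holding_pa
  if (is.null(holding) && !identical(rec$protocol, "gap_free") &&
      rec$mode == "current_clamp") {
    cmd <- rec$sweeps[[1]]$command
    if (!is.null(cmd)) {
      pre_n <- as.integer(round(rec$protocol$pre_ms / cmd$dt_ms))
      if (pre_n >= 1L) holding <- mean(cmd$samples[seq_len(pre_n)])
    }
  }
  if (is.null(holding) || !is.finite(holding)) {
    return(structure(list(holding_pa = NA_real_,
                          passed = indeterminate_passes,
                          reasons = "holding current indeterminate"),
                     class = "qc_result"))
  }
  passed <- abs(holding) <= max_holding_pa
  structure(list(holding_pa = holding, passed = passed,
                 reasons = if (passed) character(0)
                           else sprintf("|holding| = %.1f pA exceeds %.0f pA",
                                        abs(holding), max_holding_pa)),
            class = "qc_result")
}
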