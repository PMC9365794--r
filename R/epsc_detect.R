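# Spontaneous EPSC detection on gap-free voltage-clamp current traces.

# Median-filter baseline tracker: the trace is decimated, median-filtered
# over `window_ms`, and interpolated back to full resolution. Tracks the
# holding level and slow drift without following fast synaptic events.
track_baseline <- function(y, dt_ms, window_ms = 200, decim = 10L) {
  n <- length(y)
  idx <- seq(1L, n, by = decim)
  k <- as.integer(round(window_ms / (dt_ms * decim)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L) k <- 3L
  yd <- y[idx]
  if (k >= length(yd)) return(rep(stats::median(y), n))
  m <- stats::runmed(yd, k, endrule = "median")
  stats::approx(idx, m, xout = seq_len(n), rule = 2)$y
}

# Zero-phase low-pass filter (2nd-order Butterworth applied forward and
# backward, i.e. 4th-order zero-lag response).
lowpass <- function(y, dt_ms, cutoff_hz = 1000) {
  fs <- 1000 / dt_ms
  w <- cutoff_hz / (fs / 2)
  if (w >= 1) return(y)
  bf <- signal::butter(2, w)
  signal::filtfilt(bf, y)
}

#' Detect spontaneous EPSCs in a gap-free current trace
#'
#' Detection pipeline (every constant a configuration key): a
#' median-filter baseline tracker (window `baseline_ms`) removes the
#' holding level and slow drift; the baseline-subtracted current is
#' low-pass filtered (`lowpass_hz`, zero-phase Butterworth); inward
#' (negative) deflections exceeding `max(min_amp_pa, noise_k * robust
#' noise SD)` are events, where the robust SD is the median absolute
#' deviation of the filtered trace. Overlapping events are split at
#' intervening local minima when the dip between two filtered peaks
#' falls below half the smaller peak. The reported amplitude is the raw
#' baseline-subtracted extremum near the filtered peak (magnitude, pA);
#' the onset is the last preceding crossing of 10% of the peak.
#'
#' @param tr A gap-free current [trace()] (voltage-clamp EPSC recording,
#'   typically at a -60 mV command with bicuculline).
#' @param min_amp_pa Absolute detection floor, pA.
#' @param noise_k Multiplier on the robust noise SD.
#' @param baseline_ms Baseline-tracker median window, ms.
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param tail_dead_ms A smaller detection within this window after a
#'   peak is treated as a noise excursion on the decay tail and merged
#'   into it; a *larger* later peak (a genuinely stacked event) is kept.
#' @param min_duration_s Below this duration a warning is issued (short
#'   recordings give unstable rates).
#' @return A data.frame of class `epsc_events`, one row per event:
#'   `onset_ms`, `peak_ms`, `amp_pa` (magnitude > 0), `local_baseline_pa`.
#'   Decay constants are added by [fit_events_tau()].
#' @export
detect_epscs <- function(tr, min_amp_pa = 5, noise_k = 4,
                         baseline_ms = 200, lowpass_hz = 1000,
                         tail_dead_ms = 4, min_duration_s = 10) {
  assert_channel(tr, "current", "detect_epscs")
  dt <- tr$dt_ms
  y <- tr$samples
  n <- length(y)
  if (n * dt / 1000 < min_duration_s)
    warning("recording shorter than ", min_duration_s,
            " s; event rate will be unstable", call. = FALSE)

  base <- track_baseline(y, dt, baseline_ms)
  d <- y - base
  f <- lowpass(d, dt, lowpass_hz)
  s <- -f  # inward deflections positive
  sigma <- stats::mad(s)
  thr <- max(min_amp_pa, noise_k * sigma)

  above <- s > thr
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])

  refine_w <- as.integer(round(1 / dt))  # +-1 ms raw-peak refinement
  out_on <- out_pk <- out_amp <- out_bl <- numeric(0)
  for (ri in seq_len(nrow(reg))) {
    a <- reg[ri, 1]; b <- reg[ri, 2]
    seg <- s[a:b]
    if (b - a < 2L) {
      pks <- which.max(seg)
    } else {
      pks <- local_maxima(seg)
      if (length(pks) == 0L) pks <- which.max(seg)
      # split only at a genuine intervening trough: both neighbours must
      # rise above the valley by at least the detection threshold and
      # the valley must dip below half the smaller peak — noise ripples
      # on a decay tail fail both and are merged into the larger peak
      while (length(pks) > 1L) {
        merged <- FALSE
        for (j in seq_len(length(pks) - 1L)) {
          valley <- min(seg[pks[j]:pks[j + 1L]])
          lesser <- min(seg[pks[j]], seg[pks[j + 1L]])
          if (valley > 0.5 * lesser || lesser - valley < thr) {
            drop_j <- if (seg[pks[j]] >= seg[pks[j + 1L]]) j + 1L else j
            pks <- pks[-drop_j]
            merged <- TRUE
            break
          }
        }
        if (!merged) break
      }
    }
    for (p in pks) {
      pi <- a + p - 1L
      # raw-peak refinement on the unfiltered baseline-subtracted trace
      lo <- max(1L, pi - refine_w); hi <- min(n, pi + refine_w)
      praw <- lo + which.min(d[lo:hi]) - 1L
      amp <- -d[praw]
      if (amp < thr) amp <- s[pi]  # fall back to filtered height
      # onset: last preceding crossing of 10% of the filtered peak
      lvl <- 0.10 * s[pi]
      o <- pi
      floor_i <- max(1L, pi - as.integer(round(20 / dt)))
      while (o > floor_i && s[o - 1L] > lvl) o <- o - 1L
      out_on <- c(out_on, (o - 1L) * dt)
      out_pk <- c(out_pk, (praw - 1L) * dt)
      out_amp <- c(out_amp, amp)
      out_bl <- c(out_bl, base[praw])
    }
  }
  ord <- order(out_pk)
  out_on <- out_on[ord]; out_pk <- out_pk[ord]
  out_amp <- out_amp[ord]; out_bl <- out_bl[ord]
  # tail dead-time: drop smaller peaks riding the decay of the previous one
  if (length(out_pk) > 1L && tail_dead_ms > 0) {
    keep <- rep(TRUE, length(out_pk))
    last <- 1L
    for (i in 2L:length(out_pk)) {
      if (out_pk[i] - out_pk[last] < tail_dead_ms && out_amp[i] < out_amp[last]) {
        keep[i] <- FALSE
      } else last <- i
    }
    out_on <- out_on[keep]; out_pk <- out_pk[keep]
    out_amp <- out_amp[keep]; out_bl <- out_bl[keep]
  }
  # an onset walked back through a predecessor's tail cannot precede it
  if (length(out_on) > 1L)
    for (i in 2L:length(out_on))
      out_on[i] <- max(out_on[i], out_pk[i - 1L])
  ord <- order(out_on)
  structure(data.frame(onset_ms = tr$t0_ms + out_on[ord],
                       peak_ms = tr$t0_ms + out_pk[ord],
                       amp_pa = out_amp[ord],
                       local_baseline_pa = out_bl[ord],
                       decay_tau_ms = NA_real_,
                       tau_r2 = NA_real_),
            class = c("epsc_events", "data.frame"))
}

empty_events <- function() {
  structure(data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                       amp_pa = numeric(0), local_baseline_pa = numeric(0),
                       decay_tau_ms = numeric(0), tau_r2 = numeric(0)),
            class = c("epsc_events", "data.frame"))
}

#' Score detected events against a ground-truth inventory
#'
#' Greedy one-to-one matching of detected peaks to true event times
#' within `match_ms`. Used to compute detector recall/precision against
#' the synthetic generator's inventories.
#'
#' @param events An `epsc_events` data.frame (detections).
#' @param truth_times_ms True event onset times, ms.
#' @param match_ms Matching half-window, ms.
#' @return List: `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_events <- function(events, truth_times_ms, match_ms = 2) {
  det <- events$peak_ms
  used <- rep(FALSE, length(det))
  matched <- 0L
  for (tt in truth_times_ms) {
    dists <- abs(det - tt)
    dists[used] <- Inf
    j <- which.min(dists)
    if (length(j) && is.finite(dists[j]) && dists[j] <= match_ms) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = length(truth_times_ms), n_detected = length(det),
       n_matched = matched,
       recall = if (length(truth_times_ms)) matched / length(truth_times_ms) else NA_real_,
       precision = if (length(det)) matched / length(det) else NA_real_)
}
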