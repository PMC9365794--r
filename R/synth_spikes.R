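#' Parametric spike template parameters
#'
#' Spikes in the current-clamp generator are piecewise-linear templates so
#' that every shape metric has a closed form: threshold is the corner
#' where the slow pre-depolarization breaks into the fast rise; amplitude
#' is `amplitude_mv`; full width at half maximum is
#' `(rise_ms + fall_ms) / 2` (half-amplitude crossings of two linear
#' flanks); and the fast afterhyperpolarization, sampled 5 ms after the
#' falling flank re-crosses threshold, is `ahp_mv` (the template holds a
#' flat AHP plateau spanning that instant).
#'
#' @param threshold_mv Spike threshold, mV.
#' @param amplitude_mv Peak height above threshold, mV (> 0).
#' @param rise_ms Duration of the linear rise threshold -> peak, ms.
#' @param fall_ms Duration of the linear fall peak -> threshold, ms.
#' @param ahp_mv Fast-AHP depth relative to threshold, mV (typically < 0).
#' @return A list of class `spike_params`.
#' @export
spike_params <- function(threshold_mv = -30, amplitude_mv = 60,
                         rise_ms = 2, fall_ms = 5, ahp_mv = -8) {
  if (amplitude_mv <= 0) stop("`amplitude_mv` must be positive", call. = FALSE)
  if (rise_ms <= 0 || fall_ms <= 0) stop("rise/fall must be positive", call. = FALSE)
  structure(list(threshold_mv = threshold_mv, amplitude_mv = amplitude_mv,
                 rise_ms = rise_ms, fall_ms = fall_ms, ahp_mv = ahp_mv),
            class = "spike_params")
}

# Fixed template plumbing (ms): slow depolarization into threshold
# (kept shallow so the threshold corner dominates the second
# derivative), post-fall drop into the AHP plateau, plateau long enough
# to cover the +5 ms fast-AHP sample, then return to the inter-spike
# level.
.tpl_pre_ramp_ms <- 5
.tpl_drop_ms <- 1
.tpl_hold_ms <- 8
.tpl_return_ms <- 2

template_span_ms <- function(sp) {
  .tpl_pre_ramp_ms + sp$rise_ms + sp$fall_ms + .tpl_drop_ms +
    .tpl_hold_ms + .tpl_return_ms
}

# Template voltage at local time t (ms), t = 0 at the threshold crossing
# of the fast rise; v_inter is the inter-spike baseline voltage.
template_voltage <- function(t, sp, v_inter) {
  thr <- sp$threshold_mv; amp <- sp$amplitude_mv
  t_r <- sp$rise_ms; t_f <- sp$fall_ms
  ahp_v <- thr + sp$ahp_mv
  v <- numeric(length(t))
  seg <- function(lo, hi) t >= lo & t < hi
  i <- seg(-.tpl_pre_ramp_ms, 0)
  v[i] <- v_inter + (thr - v_inter) * (t[i] + .tpl_pre_ramp_ms) / .tpl_pre_ramp_ms
  i <- seg(0, t_r)
  v[i] <- thr + amp * t[i] / t_r
  i <- seg(t_r, t_r + t_f)
  v[i] <- thr + amp * (1 - (t[i] - t_r) / t_f)
  i <- seg(t_r + t_f, t_r + t_f + .tpl_drop_ms)
  v[i] <- thr + sp$ahp_mv * (t[i] - t_r - t_f) / .tpl_drop_ms
  i <- seg(t_r + t_f + .tpl_drop_ms, t_r + t_f + .tpl_drop_ms + .tpl_hold_ms)
  v[i] <- ahp_v
  t0 <- t_r + t_f + .tpl_drop_ms + .tpl_hold_ms
  i <- seg(t0, t0 + .tpl_return_ms)
  v[i] <- ahp_v + (v_inter - ahp_v) * (t[i] - t0) / .tpl_return_ms
  v
}

#' Simulate a current-clamp step family with template spikes
#'
#' One sweep per protocol step. The number of spikes on each sweep is
#' deterministic, given by a thresholded-linear frequency-current (F-I)
#' rule: zero at or below rheobase, otherwise
#' `floor(f_i_gain * (I - rheobase))` spikes (capped at the number of
#' templates that fit in the step), evenly spaced within the step.
#' Sub-rheobase sweeps show a passive charging response. Ground truth
#' records spikes per step, every spike's peak time, and the closed-form
#' shape metrics of the template (see [spike_params()]).
#'
#' @param protocol A current-clamp [step_protocol()]; the default is the
#'   excitability protocol (35 steps of 3 pA, 400 ms, starting 12 pA
#'   below holding).
#' @param sp Spike template parameters ([spike_params()]).
#' @param f_i_gain F-I slope in spikes/pA (>= 0; 0 silences every sweep).
#' @param rheobase_pa Rheobase relative to the holding current, pA.
#' @param holding_pa Steady holding current, pA (stored in metadata and
#'   used by the holding-current QC rule).
#' @param noise_mv SD of additive Gaussian voltage noise, mV.
#' @param dt_ms Sampling interval, ms.
#' @param seed Integer seed.
#' @param v_rest_mv Baseline membrane potential between steps, mV.
#' @param g_in_ns Passive input conductance shaping the subthreshold
#'   response, nS.
#' @param cell_id,group_label Metadata.
#' @return List with `recording` and `truth` (`spikes_per_step`,
#'   `peak_times_ms` per sweep, `total_evoked` over the protocol's
#'   `count_steps`, and closed-form shape values).
#' @export
gen_current_clamp <- function(protocol = step_protocol(),
                              sp = spike_params(),
                              f_i_gain = 0.3, rheobase_pa = 6,
                              holding_pa = -20, noise_mv = 0.5,
                              dt_ms = 0.05, seed = 1,
                              v_rest_mv = -60, g_in_ns = 1,
                              cell_id = "synth", group_label = "synthetic") {
  if (protocol$mode != "current_clamp")
    stop("`protocol` must be a current-clamp protocol", call. = FALSE)
  if (f_i_gain < 0) stop("`f_i_gain` must be >= 0", call. = FALSE)
  span <- template_span_ms(sp)
  if (span > protocol$step_ms)
    stop("spike template (", round(span, 2), " ms) is wider than the step",
         call. = FALSE)

  v_inter <- sp$threshold_mv - 5
  tau_m <- 20  # passive membrane time constant, ms
  sweep_ms <- protocol$pre_ms + protocol$step_ms + protocol$post_ms
  n_samp <- as.integer(round(sweep_ms / dt_ms))
  t_ms <- (seq_len(n_samp) - 1L) * dt_ms
  in_step <- t_ms >= protocol$pre_ms & t_ms < protocol$pre_ms + protocol$step_ms
  t_step <- t_ms[in_step] - protocol$pre_ms
  post <- t_ms >= protocol$pre_ms + protocol$step_ms
  t_post <- t_ms[post] - (protocol$pre_ms + protocol$step_ms)

  rel_currents <- protocol$start_offset +
    protocol$increment * (seq_len(protocol$n_steps) - 1L)
  n_fit <- floor(protocol$step_ms / span)
  n_spikes <- ifelse(rel_currents > rheobase_pa,
                     pmin(floor(f_i_gain * (rel_currents - rheobase_pa)), n_fit),
                     0L)
  n_spikes <- as.integer(n_spikes)

  seeds <- split_seeds(seed, protocol$n_steps)
  sweeps <- vector("list", protocol$n_steps)
  peak_times <- vector("list", protocol$n_steps)
  for (k in seq_len(protocol$n_steps)) {
    v <- rep(v_rest_mv, n_samp)
    nk <- n_spikes[k]
    if (nk == 0L) {
      # passive charging toward an always-subthreshold target
      target <- v_rest_mv + min(rel_currents[k] / g_in_ns, v_inter - v_rest_mv)
      v[in_step] <- v_rest_mv + (target - v_rest_mv) * (1 - exp(-t_step / tau_m))
      v_end <- v_rest_mv + (target - v_rest_mv) * (1 - exp(-protocol$step_ms / tau_m))
      v[post] <- v_rest_mv + (v_end - v_rest_mv) * exp(-t_post / tau_m)
      peak_times[[k]] <- numeric(0)
    } else {
      v[in_step] <- v_inter
      onsets <- (seq_len(nk) - 0.5) * protocol$step_ms / nk
      vs <- v[in_step]
      for (on in onsets) {
        loc <- t_step - on
        idx <- which(loc >= -.tpl_pre_ramp_ms & loc < span - .tpl_pre_ramp_ms)
        vs[idx] <- template_voltage(loc[idx], sp, v_inter)
      }
      v[in_step] <- vs
      v[post] <- v_rest_mv + (v_inter - v_rest_mv) * exp(-t_post / tau_m)
      peak_times[[k]] <- protocol$pre_ms + onsets + sp$rise_ms
    }
    if (noise_mv > 0) v <- v + with_seed(seeds[k], stats::rnorm(n_samp, 0, noise_mv))
    cmd <- rep(holding_pa, n_samp)
    cmd[in_step] <- holding_pa + rel_currents[k]
    sweeps[[k]] <- list(command = trace(cmd, dt_ms, "current"),
                        response = trace(v, dt_ms, "voltage"))
  }

  rec <- recording(cell_id = cell_id, group_label = group_label,
                   mode = "current_clamp", sweeps = sweeps,
                   protocol = protocol,
                   metadata = list(holding_pa = holding_pa))
  truth <- structure(
    list(kind = "current_clamp", seed = seed,
         spikes_per_step = n_spikes,
         peak_times_ms = peak_times,
         total_evoked = sum(n_spikes[seq_len(protocol$count_steps)]),
         threshold_mv = sp$threshold_mv,
         amplitude_mv = sp$amplitude_mv,
         fwhm_ms = (sp$rise_ms + sp$fall_ms) / 2,
         ahp_mv = sp$ahp_mv,
         f_i_gain = f_i_gain, rheobase_pa = rheobase_pa,
         holding_pa = holding_pa, noise_mv = noise_mv),
    class = "synth_truth"
  )
  list(recording = rec, truth = truth)
}
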