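#' Input conductance from two-level holding currents
#'
#' The slope conductance around rest: the cell is voltage-clamped first
#' at -70 mV and then at -50 mV, and the input conductance is the
#' difference of the steady-state currents divided by the 20 mV
#' difference in membrane potential. With currents in pA and the voltage
#' difference in mV the ratio is directly in nS.
#'
#' @param i_at_minus70_pa Steady-state current at -70 mV, pA.
#' @param i_at_minus50_pa Steady-state current at -50 mV, pA.
#' @param delta_mv Voltage difference, mV (20 by construction).
#' @return Input conductance in nS.
#' @examples
#' input_conductance(-10, 10)  # 20 pA / 20 mV = 1 nS
#' @export
input_conductance <- function(i_at_minus70_pa, i_at_minus50_pa, delta_mv = 20) {
  if (!is.finite(i_at_minus70_pa) || !is.finite(i_at_minus50_pa))
    stop("input currents must be finite", call. = FALSE)
  (i_at_minus50_pa - i_at_minus70_pa) / delta_mv
}

#' Estimate membrane capacitance from a membrane-test recording
#'
#' Primary estimator: charge integration. Sweeps are averaged, the
#' pre-step baseline is subtracted, the post-step Ohmic plateau is taken
#' as the mean over the final fraction of the step, and the capacitive
#' charge is the trapezoidal integral of the transient current above the
#' plateau; `C = Q / dV`. Charge integration is robust to
#' series-resistance distortion of the transient time course, which is
#' why it is preferred over fitting. A mono-exponential fit of the
#' transient is retained as a consistency check: `C_fit = tau / R_m`
#' with `R_m = dV / I_plateau`; both estimates and their relative
#' discrepancy are reported.
#'
#' @param rec A membrane-test [recording()] (single voltage step; the
#'   step amplitude is read from the protocol).
#' @param baseline_frac Fraction of the step's end used as the plateau
#'   window (and of the pre-step epoch used as baseline), default 0.25.
#' @param fit_window_frac Portion of the transient (in units of its
#'   estimated decay) used in the exponential cross-check fit.
#' @return A list of class `passive_props`: `capacitance_pf` (charge
#'   estimate), `capacitance_fit_pf`, `tau_ms`, `resistance_mohm`,
#'   `discrepancy`, `q_fc`, `n_sweeps_averaged`.
#' @export
estimate_capacitance <- function(rec, baseline_frac = 0.25,
                                 fit_window_frac = 5) {
  if (!inherits(rec, "recording")) stop("`rec` must be a recording", call. = FALSE)
  if (identical(rec$protocol, "gap_free"))
    stop("membrane-test estimation needs a step protocol", call. = FALSE)
  proto <- rec$protocol
  step_mv <- rec$metadata$step_mv %||% proto$start_offset
  if (!is.finite(step_mv) || step_mv == 0)
    stop("no voltage step (step_mv = 0): no transient to integrate", call. = FALSE)

  dt <- recording_dt_ms(rec)
  i_avg <- Reduce(`+`, lapply(rec$sweeps, function(s) s$response$samples)) /
    length(rec$sweeps)
  n <- length(i_avg)
  t_ms <- (seq_len(n) - 1L) * dt
  pre <- t_ms < proto$pre_ms
  in_step <- t_ms >= proto$pre_ms & t_ms < proto$pre_ms + proto$step_ms
  if (!any(pre) || sum(in_step) < 4L)
    stop("step and baseline epochs not resolvable", call. = FALSE)

  base_idx <- which(pre)
  base_idx <- base_idx[base_idx > (1 - baseline_frac) * length(base_idx)]
  baseline <- mean(i_avg[base_idx])

  step_idx <- which(in_step)
  plat_idx <- step_idx[(t_ms[step_idx] - proto$pre_ms) >=
                         (1 - baseline_frac) * proto$step_ms]
  plateau <- mean(i_avg[plat_idx]) - baseline

  y <- i_avg[step_idx] - baseline - plateau  # transient above plateau
  # transient must be resolvable: the jump should exceed plateau noise
  jump <- y[1]
  if (!is.finite(jump) || abs(jump) < 4 * stats::sd(i_avg[plat_idx]) + 1e-12)
    stop("no resolvable capacitive transient", call. = FALSE)

  ts <- t_ms[step_idx] - proto$pre_ms
  r_mohm <- 1000 * step_mv / plateau  # mV / pA * 1000 = MOhm

  # crude decay scale: time for the transient to fall below jump/e
  below <- which(abs(y) < abs(jump) / exp(1))
  crude_tau <- if (length(below)) max(dt, ts[below[1]]) else ts[length(ts)] / 2
  fit_idx <- ts <= fit_window_frac * crude_tau
  fit <- fit_monoexp(ts[fit_idx], y[fit_idx])
  cap_fit <- fit$tau_ms / r_mohm * 1000  # ms / MOhm * 1000 = pF

  # trapezoidal charge over ~6 decay constants plus the analytic tail
  # (integrating far beyond the transient only accumulates noise)
  t_int <- min(5 * fit$tau_ms, ts[plat_idx[1] - step_idx[1] + 1L])
  ii <- which(ts <= t_int)
  if (length(ii) < 3L) ii <- seq_len(min(3L, length(ts)))
  yy <- y[ii]
  q_fc <- sum((yy[-1] + yy[-length(yy)]) / 2) * dt  # pA * ms = fC
  q_fc <- q_fc + fit$A * fit$tau_ms * exp(-max(ts[ii]) / fit$tau_ms)
  cap_q <- q_fc / step_mv  # fC / mV = pF

  if (!is.finite(cap_q) || cap_q <= 0)
    stop("capacitance estimate is not positive; check step polarity metadata",
         call. = FALSE)
  structure(list(capacitance_pf = cap_q,
                 capacitance_fit_pf = cap_fit,
                 tau_ms = fit$tau_ms,
                 resistance_mohm = r_mohm,
                 discrepancy = abs(cap_fit - cap_q) / cap_q,
                 q_fc = q_fc,
                 n_sweeps_averaged = length(rec$sweeps)),
            class = "passive_props")
}
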