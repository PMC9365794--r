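# Voltage-clamp generators: Boltzmann-gated current families and the
# ideal-RC membrane test.

# Boltzmann steady-state activation
boltzmann <- function(v, v_half, slope) 1 / (1 + exp(-(v - v_half) / slope))

# Alpha-function time course, unit peak at t = t_peak (t in ms, t >= 0)
alpha_fun <- function(t, t_peak) (t / t_peak) * exp(1 - t / t_peak)

# Noiseless model current during a step to v_step (mV) from v_hold,
# at step-relative times t (ms). Units: nS * mV = pA.
vc_model_current <- function(t, v_step, v_hold, na_gmax, kfast_gmax,
                             kslow_gmax, leak_ns,
                             e_na = 60, e_k = -90,
                             na_vhalf = -25, na_slope = 6, na_tpeak = 1,
                             k_vhalf = -10, k_slope = 10, kf_tpeak = 3,
                             ks_tau = 20) {
  leak <- leak_ns * (v_step - v_hold)
  i_na <- na_gmax * boltzmann(v_step, na_vhalf, na_slope) * (v_step - e_na) *
    alpha_fun(t, na_tpeak)
  i_kf <- kfast_gmax * boltzmann(v_step, k_vhalf, k_slope) * (v_step - e_k) *
    alpha_fun(t, kf_tpeak)
  i_ks <- kslow_gmax * boltzmann(v_step, k_vhalf, k_slope) * (v_step - e_k) *
    (1 - exp(-t / ks_tau))
  leak + i_na + i_kf + i_ks
}

#' Simulate a voltage-clamp current-voltage step family
#'
#' Per-step current response = linear leak (reversing at the holding
#' potential) + a transient inward sodium-like component (Boltzmann
#' steady-state activation over voltage, alpha-function time course
#' peaking ~1 ms after step onset) + an early-peaking outward
#' potassium-like component (alpha-function peaking ~3 ms) + a sustained
#' outward component rising with a 20 ms time constant, plus optional
#' Gaussian noise. The ground truth stores, per step, the values the
#' extraction windows should recover from a noiseless trace: transient
#' inward peak (relative to the sustained level, clamped to <= 0), early
#' outward peak, and late-window mean, each also as a capacitance
#' density in pA/pF.
#'
#' @param protocol A voltage-clamp [step_protocol()]; default
#'   [vc_iv_protocol()] (-90..+80 mV, 400 ms, from -60 mV hold).
#' @param na_gmax,kfast_gmax,kslow_gmax Conductance scales, nS (>= 0).
#' @param leak_ns Linear leak conductance, nS.
#' @param capacitance_pf Cell capacitance used for density normalization
#'   in the ground truth (> 0).
#' @param noise_sd_pa SD of additive Gaussian current noise, pA.
#' @param dt_ms Sampling interval, ms.
#' @param seed Integer seed.
#' @param early_ms,blank_ms,late_ms Windows used to compute the ground
#'   truth (match the extractor defaults: early 0.5-10 ms post-onset
#'   with the first 0.5 ms blanked, late = final 50 ms of the step).
#' @param cell_id,group_label Metadata.
#' @return List with `recording` and `truth` (`step_mv`, `na_peak_pa`,
#'   `kfast_pa`, `kslow_pa` and `*_density` fields).
#' @export
gen_voltage_clamp_iv <- function(protocol = vc_iv_protocol(),
                                 na_gmax = 6, kfast_gmax = 4, kslow_gmax = 3,
                                 leak_ns = 1, capacitance_pf = 20,
                                 noise_sd_pa = 2, dt_ms = 0.05, seed = 1,
                                 early_ms = 10, blank_ms = 0.5, late_ms = 50,
                                 cell_id = "synth", group_label = "synthetic") {
  if (protocol$mode != "voltage_clamp")
    stop("`protocol` must be a voltage-clamp protocol", call. = FALSE)
  if (any(c(na_gmax, kfast_gmax, kslow_gmax) < 0))
    stop("conductance scales must be >= 0", call. = FALSE)
  if (capacitance_pf <= 0) stop("`capacitance_pf` must be positive", call. = FALSE)

  v_hold <- protocol$holding
  levels <- step_levels(protocol)
  sweep_ms <- protocol$pre_ms + protocol$step_ms + protocol$post_ms
  n_samp <- as.integer(round(sweep_ms / dt_ms))
  t_ms <- (seq_len(n_samp) - 1L) * dt_ms
  in_step <- t_ms >= protocol$pre_ms & t_ms < protocol$pre_ms + protocol$step_ms
  t_step <- t_ms[in_step] - protocol$pre_ms

  early <- t_step >= blank_ms & t_step <= early_ms
  late <- t_step >= protocol$step_ms - late_ms

  seeds <- split_seeds(seed, protocol$n_steps)
  sweeps <- vector("list", protocol$n_steps)
  na_peak <- kfast <- kslow <- numeric(protocol$n_steps)
  for (k in seq_len(protocol$n_steps)) {
    model <- vc_model_current(t_step, levels[k], v_hold,
                              na_gmax, kfast_gmax, kslow_gmax, leak_ns)
    kslow[k] <- mean(model[late])
    kfast[k] <- max(model[early])
    na_peak[k] <- min(0, min(model[early]) - kslow[k])
    i <- numeric(n_samp)
    i[in_step] <- model
    if (noise_sd_pa > 0)
      i <- i + with_seed(seeds[k], stats::rnorm(n_samp, 0, noise_sd_pa))
    cmd <- rep(v_hold, n_samp); cmd[in_step] <- levels[k]
    sweeps[[k]] <- list(command = trace(cmd, dt_ms, "voltage"),
                        response = trace(i, dt_ms, "current"))
  }

  rec <- recording(cell_id = cell_id, group_label = group_label,
                   mode = "voltage_clamp", sweeps = sweeps,
                   protocol = protocol,
                   metadata = list(holding_mv = v_hold,
                                   capacitance_pf = capacitance_pf))
  truth <- structure(
    list(kind = "vc_iv", seed = seed, step_mv = levels,
         na_peak_pa = na_peak, kfast_pa = kfast, kslow_pa = kslow,
         na_peak_density = na_peak / capacitance_pf,
         kfast_density = kfast / capacitance_pf,
         kslow_density = kslow / capacitance_pf,
         capacitance_pf = capacitance_pf, leak_ns = leak_ns,
         na_gmax = na_gmax, kfast_gmax = kfast_gmax, kslow_gmax = kslow_gmax,
         noise_sd_pa = noise_sd_pa),
    class = "synth_truth"
  )
  list(recording = rec, truth = truth)
}

#' Simulate a membrane-test recording (ideal RC cell)
#'
#' Current response of an ideal RC membrane to a small voltage step:
#' an instantaneous jump of `dV/R` above the Ohmic plateau, relaxing
#' exponentially with `tau = R * C` to the plateau `dV/R`. The charge in
#' the transient above the plateau is exactly `Q = C * dV`, which is the
#' identity the charge-integration capacitance estimator relies on.
#'
#' @param capacitance_pf Membrane capacitance, pF (> 0).
#' @param resistance_mohm Membrane resistance, MOhm (> 0).
#' @param step_mv Test-step amplitude, mV (0 produces a flat trace,
#'   which the estimator rejects).
#' @param step_ms Step duration, ms (> 0).
#' @param pre_ms,post_ms Baseline before/after the step, ms.
#' @param n_sweeps Number of identical-protocol sweeps (averaged by the
#'   estimator when noisy).
#' @param noise_sd_pa SD of additive Gaussian current noise, pA.
#' @param dt_ms Sampling interval, ms.
#' @param seed Integer seed.
#' @param cell_id,group_label Metadata.
#' @return List with `recording` and `truth` (`capacitance_pf`,
#'   `resistance_mohm`, `tau_ms`, `q_fc`, `plateau_pa`).
#' @export
gen_membrane_test <- function(capacitance_pf = 30, resistance_mohm = 500,
                              step_mv = -5, step_ms = 150,
                              pre_ms = 50, post_ms = 50, n_sweeps = 1,
                              noise_sd_pa = 0, dt_ms = 0.05, seed = 1,
                              cell_id = "synth", group_label = "synthetic") {
  if (capacitance_pf <= 0 || resistance_mohm <= 0 || step_ms <= 0)
    stop("capacitance, resistance and step duration must be positive", call. = FALSE)
  tau_ms <- capacitance_pf * resistance_mohm / 1000
  plateau <- 1000 * step_mv / resistance_mohm  # mV / MOhm = nA -> pA

  sweep_ms <- pre_ms + step_ms + post_ms
  n_samp <- as.integer(round(sweep_ms / dt_ms))
  t_ms <- (seq_len(n_samp) - 1L) * dt_ms
  in_step <- t_ms >= pre_ms & t_ms < pre_ms + step_ms
  post <- t_ms >= pre_ms + step_ms
  base_i <- numeric(n_samp)
  base_i[in_step] <- plateau * (1 + exp(-(t_ms[in_step] - pre_ms) / tau_ms))
  base_i[post] <- -plateau * exp(-(t_ms[post] - pre_ms - step_ms) / tau_ms)

  seeds <- split_seeds(seed, n_sweeps)
  cmd <- rep(-60, n_samp); cmd[in_step] <- -60 + step_mv
  sweeps <- lapply(seq_len(n_sweeps), function(k) {
    i <- base_i
    if (noise_sd_pa > 0)
      i <- i + with_seed(seeds[k], stats::rnorm(n_samp, 0, noise_sd_pa))
    list(command = trace(cmd, dt_ms, "voltage"),
         response = trace(i, dt_ms, "current"))
  })

  proto <- step_protocol(mode = "voltage_clamp", holding = -60,
                         start_offset = step_mv,
                         increment = if (step_mv == 0) 1 else step_mv,
                         step_ms = step_ms, n_steps = 1L,
                         pre_ms = pre_ms, post_ms = post_ms, count_steps = 1L)
  # one protocol entry per sweep family; sweeps are repeats of step 1
  rec <- recording(cell_id = cell_id, group_label = group_label,
                   mode = "voltage_clamp", sweeps = sweeps,
                   protocol = proto,
                   metadata = list(holding_mv = -60, membrane_test = TRUE,
                                   step_mv = step_mv))
  truth <- structure(
    list(kind = "membrane_test", seed = seed,
         capacitance_pf = capacitance_pf, resistance_mohm = resistance_mohm,
         tau_ms = tau_ms, q_fc = capacitance_pf * step_mv,
         plateau_pa = plateau, noise_sd_pa = noise_sd_pa),
    class = "synth_truth"
  )
  list(recording = rec, truth = truth)
}
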