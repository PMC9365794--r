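#' Per-group distribution parameters for a synthetic cohort
#'
#' Defines the neuron-to-neuron distributions of one experimental group.
#' Defaults describe a healthy-control population: spontaneous EPSC rate
#' ~1 event/s (lognormal across neurons with CV 0.8 — rates in culture
#' are strongly right-skewed), 20 pA mean amplitude, 2.3 ms decay,
#' ~20 pF cells, ~1 nS input conductance. A disease-like group is
#' expressed through the `*_scale` multipliers (e.g. `rate_scale = 0.2`
#' reproduces the ~5x depression of event rate reported for PD-derived
#' neurons).
#'
#' @param n Number of neurons (> 0).
#' @param rate_scale,excitability_scale,na_scale,kfast_scale,kslow_scale
#'   Multiplicative group effects on EPSC rate, F-I gain and conductance
#'   scales.
#' @param epsc_rate_mean_hz,epsc_rate_cv Lognormal across-neuron EPSC
#'   rate distribution.
#' @param epsc_amp_mean_pa,epsc_amp_cv Event amplitude distribution
#'   (within neuron).
#' @param epsc_tau_ms EPSC decay constant.
#' @param epsc_noise_sd_pa Recording noise SD.
#' @param f_i_gain_mean,f_i_gain_cv F-I slope distribution (spikes/pA).
#' @param na_gmax_mean,kfast_gmax_mean,kslow_gmax_mean,leak_ns_mean,gmax_cv
#'   Conductance-scale distributions (normal, truncated at 0).
#' @param capacitance_mean_pf,capacitance_cv Capacitance (lognormal).
#' @param resistance_mohm Membrane resistance for the membrane test.
#' @param holding_pa_mean,holding_pa_sd Steady holding current (pA);
#'   occasional neurons exceeding the 50 pA QC rule are part of
#'   realistic cohorts.
#' @param spike Spike template parameters ([spike_params()]).
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(n,
                       rate_scale = 1, excitability_scale = 1,
                       na_scale = 1, kfast_scale = 1, kslow_scale = 1,
                       epsc_rate_mean_hz = 1.0, epsc_rate_cv = 0.8,
                       epsc_amp_mean_pa = 20, epsc_amp_cv = 0.3,
                       epsc_tau_ms = 2.3, epsc_noise_sd_pa = 2,
                       f_i_gain_mean = 0.3, f_i_gain_cv = 0.25,
                       na_gmax_mean = 6, kfast_gmax_mean = 4,
                       kslow_gmax_mean = 3, leak_ns_mean = 1, gmax_cv = 0.25,
                       capacitance_mean_pf = 20, capacitance_cv = 0.15,
                       resistance_mohm = 500,
                       holding_pa_mean = -15, holding_pa_sd = 15,
                       spike = spike_params()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("every group needs at least one neuron", call. = FALSE)
  structure(as.list(environment()), class = "group_spec")
}

#' Synthetic cohort configuration
#'
#' @param groups Named list of [group_spec()]s; at least two groups
#'   (a comparison needs a reference).
#' @param epsc_duration_s Gap-free EPSC recording duration per neuron, s.
#' @param mtest_sweeps Membrane-test sweeps per neuron.
#' @param mtest_noise_sd_pa Membrane-test noise SD, pA.
#' @param cc_noise_mv Current-clamp voltage noise SD, mV.
#' @param vc_noise_sd_pa Voltage-clamp current noise SD, pA.
#' @param dt_ms Sampling interval, ms.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups, epsc_duration_s = 60,
                          mtest_sweeps = 5, mtest_noise_sd_pa = 2,
                          cc_noise_mv = 0.5, vc_noise_sd_pa = 2,
                          dt_ms = 0.05) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)) ||
      any(names(groups) == ""))
    stop("`groups` must be a named list of at least two group_spec()s",
         call. = FALSE)
  for (g in groups)
    if (!inherits(g, "group_spec"))
      stop("every group must be a group_spec()", call. = FALSE)
  structure(list(groups = groups, epsc_duration_s = epsc_duration_s,
                 mtest_sweeps = as.integer(mtest_sweeps),
                 mtest_noise_sd_pa = mtest_noise_sd_pa,
                 cc_noise_mv = cc_noise_mv, vc_noise_sd_pa = vc_noise_sd_pa,
                 dt_ms = dt_ms),
            class = "cohort_config")
}

#' Draw per-neuron generative parameters for a cohort
#'
#' The parameter-drawing stage of [gen_cohort()], exposed on its own so
#' that distribution-level properties (group effects, type-I error of
#' downstream tests under identical groups) can be studied over many
#' replicate cohorts without synthesizing full traces. One root seed is
#' split deterministically per neuron; [gen_cohort()] consumes exactly
#' this table.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @return Data.frame, one row per neuron: group, cell id, per-neuron
#'   EPSC rate/amplitude/decay parameters, F-I gain, conductance scales,
#'   capacitance, holding current and the neuron's child seed.
#' @export
draw_cohort_params <- function(config, seed = 1) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config", call. = FALSE)
  n_total <- sum(vapply(config$groups, function(g) g$n, integer(1)))
  seeds <- split_seeds(seed, n_total + 1L)
  draw_seed <- seeds[1]
  rows <- list()
  idx <- 0L
  with_seed(draw_seed, {
    for (gname in names(config$groups)) {
      g <- config$groups[[gname]]
      for (j in seq_len(g$n)) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          cell_id = sprintf("%s_%03d", gname, j),
          group_label = gname,
          epsc_rate_hz = draw_lognormal(1, g$epsc_rate_mean_hz * g$rate_scale,
                                        g$epsc_rate_cv),
          epsc_amp_mean_pa = g$epsc_amp_mean_pa,
          epsc_amp_cv = g$epsc_amp_cv,
          epsc_tau_ms = g$epsc_tau_ms,
          epsc_noise_sd_pa = g$epsc_noise_sd_pa,
          f_i_gain = draw_lognormal(1, g$f_i_gain_mean * g$excitability_scale,
                                    g$f_i_gain_cv),
          na_gmax = max(0, stats::rnorm(1, g$na_gmax_mean * g$na_scale,
                                        g$gmax_cv * g$na_gmax_mean * g$na_scale)),
          kfast_gmax = max(0, stats::rnorm(1, g$kfast_gmax_mean * g$kfast_scale,
                                           g$gmax_cv * g$kfast_gmax_mean * g$kfast_scale)),
          kslow_gmax = max(0, stats::rnorm(1, g$kslow_gmax_mean * g$kslow_scale,
                                           g$gmax_cv * g$kslow_gmax_mean * g$kslow_scale)),
          leak_ns = draw_lognormal(1, g$leak_ns_mean, 0.2),
          capacitance_pf = draw_lognormal(1, g$capacitance_mean_pf,
                                          g$capacitance_cv),
          resistance_mohm = g$resistance_mohm,
          holding_pa = stats::rnorm(1, g$holding_pa_mean, g$holding_pa_sd),
          neuron_seed = seeds[idx + 1L],
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort with ground truth
#'
#' For every synthetic neuron, generates the complete recording bundle
#' of the study design — a gap-free EPSC recording, a current-clamp
#' step family, a voltage-clamp I-V family and a membrane test — from
#' per-neuron parameters drawn by [draw_cohort_params()]. Exactly
#' reproducible from `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @param components Subset of `c("epsc", "cc", "vc", "mtest")` to
#'   generate (all by default).
#' @return List with `bundles` (per neuron: `cell_id`, `group_label`,
#'   recordings by component, and each component's `synth_truth`) and
#'   `truth`, the parameter table augmented with realized ground-truth
#'   columns (`true_n_events`, `true_total_evoked`, ...).
#' @export
gen_cohort <- function(config, seed = 1,
                       components = c("epsc", "cc", "vc", "mtest")) {
  params <- draw_cohort_params(config, seed)
  spikes_by_group <- lapply(config$groups, function(g) g$spike)
  bundles <- vector("list", nrow(params))
  params$true_n_events <- NA_integer_
  params$true_total_evoked <- NA_integer_
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    sub <- split_seeds(p$neuron_seed, 4)
    b <- list(cell_id = p$cell_id, group_label = p$group_label, truth = list())
    if ("epsc" %in% components) {
      ge <- gen_epsc_trace(rate_hz = p$epsc_rate_hz,
                           amp_mean_pa = p$epsc_amp_mean_pa,
                           amp_cv = p$epsc_amp_cv, tau_ms = p$epsc_tau_ms,
                           noise_sd_pa = p$epsc_noise_sd_pa,
                           duration_s = config$epsc_duration_s,
                           dt_ms = config$dt_ms, seed = sub[1],
                           cell_id = p$cell_id, group_label = p$group_label)
      b$epsc <- ge$recording; b$truth$epsc <- ge$truth
      params$true_n_events[i] <- ge$truth$n_events
    }
    if ("cc" %in% components) {
      gc <- gen_current_clamp(sp = spikes_by_group[[p$group_label]],
                              f_i_gain = p$f_i_gain,
                              holding_pa = p$holding_pa,
                              noise_mv = config$cc_noise_mv,
                              dt_ms = config$dt_ms, seed = sub[2],
                              g_in_ns = p$leak_ns,
                              cell_id = p$cell_id, group_label = p$group_label)
      b$cc <- gc$recording; b$truth$cc <- gc$truth
      params$true_total_evoked[i] <- gc$truth$total_evoked
    }
    if ("vc" %in% components) {
      gv <- gen_voltage_clamp_iv(na_gmax = p$na_gmax,
                                 kfast_gmax = p$kfast_gmax,
                                 kslow_gmax = p$kslow_gmax,
                                 leak_ns = p$leak_ns,
                                 capacitance_pf = p$capacitance_pf,
                                 noise_sd_pa = config$vc_noise_sd_pa,
                                 dt_ms = config$dt_ms, seed = sub[3],
                                 cell_id = p$cell_id, group_label = p$group_label)
      b$vc <- gv$recording; b$truth$vc <- gv$truth
    }
    if ("mtest" %in% components) {
      gm <- gen_membrane_test(capacitance_pf = p$capacitance_pf,
                              resistance_mohm = p$resistance_mohm,
                              n_sweeps = config$mtest_sweeps,
                              noise_sd_pa = config$mtest_noise_sd_pa,
                              dt_ms = config$dt_ms, seed = sub[4],
                              cell_id = p$cell_id, group_label = p$group_label)
      b$mtest <- gm$recording; b$truth$mtest <- gm$truth
    }
    bundles[[i]] <- b
  }
  list(bundles = bundles, truth = params)
}
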