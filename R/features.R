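#' Extract all per-neuron features from a recording bundle
#'
#' Runs the full single-neuron analysis chain: holding-current QC,
#' capacitance from the membrane test, total evoked spikes and
#' first-spike shape from the current-clamp family, I-V densities (and
#' input conductance from the -70/-50 mV steady-state currents) from
#' the voltage-clamp family, and EPSC detection / decay fitting /
#' activity classification from the gap-free recording. Any component
#' may be absent; its metrics are reported missing (`NA`), never 0.
#'
#' @param bundle List with `cell_id`, `group_label` and any of the
#'   recordings `epsc`, `cc`, `vc`, `mtest` (as produced by
#'   [gen_cohort()] or assembled from [read_recording()] calls).
#' @param config A `synapto_config` ([default_config()]).
#' @return List: `features` (one-row data.frame), `iv` (`iv_curves` or
#'   `NULL`), `events` (`epsc_events` with a `cell_id` column, or
#'   `NULL`), `qc` (`qc_result`).
#' @export
extract_neuron_features <- function(bundle, config = default_config()) {
  cid <- bundle$cell_id %||% "unknown"
  grp <- bundle$group_label %||% "unknown"

  qc_src <- bundle$cc %||% bundle$epsc %||% bundle$vc %||% bundle$mtest
  if (is.null(qc_src)) stop("bundle for ", cid, " has no recordings", call. = FALSE)
  qc <- qc_holding(qc_src, max_holding_pa = config$qc$max_holding_pa)

  row <- data.frame(cell_id = cid, group_label = grp,
                    qc_passed = qc$passed, holding_pa = qc$holding_pa,
                    total_evoked_ap = NA_integer_,
                    spike_threshold_mv = NA_real_, spike_amplitude_mv = NA_real_,
                    spike_width_ms = NA_real_, spike_ahp_mv = NA_real_,
                    capacitance_pf = NA_real_, input_conductance_ns = NA_real_,
                    na_peak_density = NA_real_, kfast_peak_density = NA_real_,
                    kslow_peak_density = NA_real_, na_density_m20 = NA_real_,
                    epsc_n_events = NA_integer_, epsc_rate_hz = NA_real_,
                    epsc_mean_amp_pa = NA_real_, epsc_mean_tau_ms = NA_real_,
                    epsc_active = NA, stringsAsFactors = FALSE)

  if (!is.null(bundle$mtest)) {
    cap <- tryCatch(
      estimate_capacitance(bundle$mtest,
                           baseline_frac = config$passive$baseline_frac,
                           fit_window_frac = config$passive$fit_window_frac),
      error = function(e) NULL)
    if (!is.null(cap)) row$capacitance_pf <- cap$capacitance_pf
  }

  if (!is.null(bundle$cc)) {
    sp_cfg <- config$spike
    row$total_evoked_ap <- count_total_evoked(
      bundle$cc, count_steps = config$protocol$count_steps,
      dvdt_thresh = sp_cfg$dvdt_thresh, min_peak_mv = sp_cfg$min_peak_mv,
      refractory_ms = sp_cfg$refractory_ms, sg_window_ms = sp_cfg$sg_window_ms)
    shape <- first_spike_shape(
      bundle$cc, dvdt_thresh = sp_cfg$dvdt_thresh,
      min_peak_mv = sp_cfg$min_peak_mv,
      refractory_ms = sp_cfg$refractory_ms, sg_window_ms = sp_cfg$sg_window_ms)
    if (!is.null(shape)) {
      row$spike_threshold_mv <- shape$threshold_mv
      row$spike_amplitude_mv <- shape$amplitude_mv
      row$spike_width_ms <- shape$width_fwhm_ms
      row$spike_ahp_mv <- shape$fast_ahp_mv
    }
  }

  iv <- NULL
  if (!is.null(bundle$vc)) {
    cap_for_iv <- row$capacitance_pf %||% NA_real_
    if (!is.finite(cap_for_iv))
      cap_for_iv <- bundle$vc$metadata$capacitance_pf %||% NA_real_
    if (is.finite(cap_for_iv)) {
      iv <- extract_iv_curves(bundle$vc, cap_for_iv,
                              early_ms = config$vc$early_ms,
                              blank_ms = config$vc$blank_ms,
                              late_ms = config$vc$late_ms)
      row$na_peak_density <- iv_extreme_density(iv, "na")
      row$kfast_peak_density <- iv_extreme_density(iv, "kfast")
      row$kslow_peak_density <- iv_extreme_density(iv, "kslow")
      row$na_density_m20 <- tryCatch(density_at_voltage(iv, -20, "na"),
                                     error = function(e) NA_real_)
      # input conductance from the -70 / -50 mV steady-state currents
      i70 <- which(abs(iv$step_mv - (-70)) < 1e-6)
      i50 <- which(abs(iv$step_mv - (-50)) < 1e-6)
      if (length(i70) == 1L && length(i50) == 1L)
        row$input_conductance_ns <-
          input_conductance(iv$kslow_pa[i70], iv$kslow_pa[i50])
    }
  }

  events <- NULL
  if (!is.null(bundle$epsc)) {
    tr <- bundle$epsc$sweeps[[1]]$response
    ep <- config$epsc
    events <- detect_epscs(tr, min_amp_pa = ep$min_amp_pa,
                           noise_k = ep$noise_k,
                           baseline_ms = ep$baseline_ms,
                           lowpass_hz = ep$lowpass_hz,
                           tail_dead_ms = ep$tail_dead_ms)
    events <- fit_events_tau(tr, events, window_ms = ep$tau_window_ms,
                             min_r2 = ep$min_r2, baseline_ms = ep$baseline_ms)
    dur_s <- bundle$epsc$metadata$duration_s %||%
      (trace_duration_ms(tr) / 1000)
    smry <- summarize_events(events, dur_s)
    row$epsc_n_events <- smry$n_events
    row$epsc_rate_hz <- smry$rate_hz
    row$epsc_mean_amp_pa <- smry$mean_amp_pa
    row$epsc_mean_tau_ms <- smry$mean_decay_tau_ms
    row$epsc_active <- smry$active
    if (nrow(events)) events <- cbind(cell_id = cid, events)
  }

  list(features = row, iv = iv, events = events, qc = qc)
}

#' Extract features for a whole cohort of bundles
#'
#' Maps [extract_neuron_features()] over a list of bundles and binds
#' the per-neuron rows. The per-neuron `iv_curves` are attached as the
#' `iv_list` attribute (keyed by cell id) for per-voltage analyses;
#' per-event tables are concatenated.
#'
#' @param bundles List of bundles (see [extract_neuron_features()]).
#' @param config A `synapto_config`.
#' @return List: `features` (data.frame, attribute `iv_list`),
#'   `events` (data.frame over all neurons).
#' @export
extract_cohort_features <- function(bundles, config = default_config()) {
  if (length(bundles) == 0L) stop("no recordings found", call. = FALSE)
  res <- lapply(bundles, extract_neuron_features, config = config)
  feats <- do.call(rbind, lapply(res, `[[`, "features"))
  ivl <- lapply(res, `[[`, "iv")
  names(ivl) <- feats$cell_id
  attr(feats, "iv_list") <- ivl
  ev <- do.call(rbind, Filter(Negate(is.null), lapply(res, `[[`, "events")))
  list(features = feats, events = ev)
}
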