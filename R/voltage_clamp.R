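#' Extract sodium and potassium current-voltage curves
#'
#' Operational definitions (windows are configuration keys):
#' * **baseline** — mean current over the pre-step epoch of each sweep,
#'   subtracted from everything.
#' * **fast K** — maximum current in the early window immediately after
#'   the step (default 0-10 ms, excluding a 0.5 ms capacitive-artifact
#'   blank).
#' * **slow K** — mean current over the late window (default the final
#'   50 ms of the 400 ms step).
#' * **Na peak** — minimum over the early window of the current relative
#'   to the sustained (late-window) level, clamped to <= 0, so a purely
#'   Ohmic cell reports zero sodium current at every step. Where the
#'   inward transient overlaps the potassium rise, the measurement is the
#'   net extremum — an operational, not ionic, decomposition.
#'
#' All three are divided by the cell capacitance to give densities in
#' pA/pF. Step voltages are inferred from the command channel when
#' present, else from the protocol.
#'
#' @param rec A voltage-clamp step-family [recording()].
#' @param capacitance_pf Cell capacitance, pF (> 0). Required; pass the
#'   estimate from [estimate_capacitance()].
#' @param early_ms,blank_ms,late_ms Extraction windows, ms.
#' @return A list of class `iv_curves`: `step_mv`, `na_peak_density`,
#'   `kfast_density`, `kslow_density` (pA/pF), the raw pA versions, and
#'   `capacitance_used`.
#' @export
extract_iv_curves <- function(rec, capacitance_pf,
                              early_ms = 10, blank_ms = 0.5, late_ms = 50) {
  if (!inherits(rec, "recording") || rec$mode != "voltage_clamp")
    stop("`rec` must be a voltage-clamp recording", call. = FALSE)
  if (identical(rec$protocol, "gap_free"))
    stop("a step protocol is required", call. = FALSE)
  if (!is.finite(capacitance_pf) || capacitance_pf <= 0)
    stop("`capacitance_pf` must be positive", call. = FALSE)
  proto <- rec$protocol
  dt <- recording_dt_ms(rec)
  n_steps <- length(rec$sweeps)

  step_mv <- vapply(seq_len(n_steps), function(k) {
    cmd <- rec$sweeps[[k]]$command
    if (!is.null(cmd)) {
      t <- trace_times_ms(cmd)
      mean(cmd$samples[t >= proto$pre_ms & t < proto$pre_ms + proto$step_ms])
    } else step_levels(proto)[k]
  }, numeric(1))

  na_pa <- kf_pa <- ks_pa <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    y <- rec$sweeps[[k]]$response$samples
    t <- (seq_along(y) - 1L) * dt
    pre <- t < proto$pre_ms
    if (!any(pre)) stop("sweep ", k, " has no pre-step baseline", call. = FALSE)
    y <- y - mean(y[pre])
    ts <- t - proto$pre_ms
    early <- ts >= blank_ms & ts <= early_ms
    late <- ts >= proto$step_ms - late_ms & ts < proto$step_ms
    ks_pa[k] <- mean(y[late])
    kf_pa[k] <- max(y[early])
    na_pa[k] <- min(0, min(y[early]) - ks_pa[k])
  }

  structure(list(step_mv = step_mv,
                 na_peak_density = na_pa / capacitance_pf,
                 kfast_density = kf_pa / capacitance_pf,
                 kslow_density = ks_pa / capacitance_pf,
                 na_peak_pa = na_pa, kfast_pa = kf_pa, kslow_pa = ks_pa,
                 capacitance_used = capacitance_pf),
            class = "iv_curves")
}

#' Current density at a given step voltage
#'
#' Nearest-grid lookup (no interpolation): the entry whose step voltage
#' is closest to `v_mv`, provided it lies within half the grid spacing.
#' This is how per-voltage densities (e.g. the sodium density at -20 mV)
#' are read off an I-V family.
#'
#' @param iv An `iv_curves` object from [extract_iv_curves()].
#' @param v_mv Query voltage, mV.
#' @param component One of `"na"`, `"kfast"`, `"kslow"`.
#' @return Density in pA/pF.
#' @export
density_at_voltage <- function(iv, v_mv, component = c("na", "kfast", "kslow")) {
  component <- match.arg(component)
  if (!inherits(iv, "iv_curves")) stop("`iv` must be an iv_curves object", call. = FALSE)
  d <- abs(iv$step_mv - v_mv)
  k <- which.min(d)
  spacing <- if (length(iv$step_mv) > 1L) min(diff(sort(iv$step_mv))) else Inf
  if (d[k] > spacing / 2)
    stop(sprintf("%g mV is outside the step grid (nearest step %g mV)",
                 v_mv, iv$step_mv[k]), call. = FALSE)
  switch(component,
         na = iv$na_peak_density[k],
         kfast = iv$kfast_density[k],
         kslow = iv$kslow_density[k])
}

# Per-neuron extreme density of one component: Na = most negative across
# steps, K = largest across steps. Used by the group-level ANOVA.
iv_extreme_density <- function(iv, component) {
  switch(component,
         na = min(iv$na_peak_density),
         kfast = max(iv$kfast_density),
         kslow = max(iv$kslow_density))
}
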