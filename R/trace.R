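#' Sampled electrophysiology trace
#'
#' A `trace` is the basic signal container: one regularly sampled channel,
#' either membrane voltage (mV) or membrane/clamp current (pA), with its
#' sampling interval in ms. All analyses in the package operate on traces
#' in these units; unit normalization is the job of [read_recording()].
#'
#' @param samples Numeric vector of samples (mV for voltage, pA for current).
#' @param dt_ms Sampling interval in ms (> 0). The default 0.05 ms is a
#'   20 kHz acquisition rate.
#' @param channel One of `"voltage"` or `"current"`.
#' @param t0_ms Time of the first sample in sweep-relative ms.
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(rep(-60, 2000), dt_ms = 0.05, channel = "voltage")
#' trace_duration_ms(tr)
#' @export
trace <- function(samples, dt_ms = 0.05, channel = c("voltage", "current"),
                  t0_ms = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || !is.finite(dt_ms) || dt_ms <= 0)
    stop("`dt_ms` must be a single positive number", call. = FALSE)
  if (length(samples) < 1L)
    stop("a trace needs at least one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite", call. = FALSE)
  structure(
    list(samples = samples, dt_ms = dt_ms, channel = channel, t0_ms = t0_ms),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s, %d samples @ %.4g ms (%.4g s), range [%.3g, %.3g] %s\n",
              x$channel, length(x$samples), x$dt_ms,
              length(x$samples) * x$dt_ms / 1000,
              min(x$samples), max(x$samples),
              if (x$channel == "voltage") "mV" else "pA"))
  invisible(x)
}

#' Trace duration in ms
#' @param tr A [trace()].
#' @return Duration in ms (`n * dt`).
#' @export
trace_duration_ms <- function(tr) length(tr$samples) * tr$dt_ms

#' Time axis of a trace
#' @param tr A [trace()].
#' @return Numeric vector of sample times in ms (sweep-relative).
#' @export
trace_times_ms <- function(tr) tr$t0_ms + (seq_along(tr$samples) - 1L) * tr$dt_ms

is_trace <- function(x) inherits(x, "trace")

assert_channel <- function(tr, channel, what) {
  if (!is_trace(tr)) stop(what, " requires a trace object", call. = FALSE)
  if (tr$channel != channel)
    stop(what, " requires a ", channel, " trace, got a ", tr$channel, " trace",
         call. = FALSE)
  invisible(tr)
}

#' Step-family stimulation protocol
#'
#' Describes a family of square command steps delivered from a holding
#' level: current-clamp excitability families (e.g. 35 steps of 3 pA,
#' 400 ms, starting 12 pA below the holding current) or voltage-clamp
#' step families (e.g. -90 to +80 mV from a -60 mV hold). Times are
#' sweep-relative ms; the step occupies
#' `[pre_ms, pre_ms + step_ms)` in every sweep.
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding Holding level (pA in current clamp, mV in voltage clamp).
#' @param start_offset First step's offset from holding (pA or mV).
#' @param increment Per-step increment (pA or mV, nonzero).
#' @param step_ms Step duration in ms.
#' @param n_steps Number of steps/sweeps.
#' @param pre_ms Baseline before the step, ms.
#' @param post_ms Baseline after the step, ms.
#' @param count_steps Number of initial steps over which evoked action
#'   potentials are totalled (defaults to 17, the window used for the
#'   excitability measure).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                          holding = 0,
                          start_offset = -12,
                          increment = 3,
                          step_ms = 400,
                          n_steps = 35,
                          pre_ms = 100,
                          post_ms = 100,
                          count_steps = min(17L, n_steps)) {
  mode <- match.arg(mode)
  if (increment == 0) stop("`increment` must be nonzero", call. = FALSE)
  if (step_ms <= 0) stop("`step_ms` must be positive", call. = FALSE)
  n_steps <- as.integer(n_steps)
  count_steps <- as.integer(count_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  if (count_steps < 1L || count_steps > n_steps)
    stop("`count_steps` must lie in [1, n_steps]", call. = FALSE)
  structure(
    list(mode = mode, holding = holding, start_offset = start_offset,
         increment = increment, step_ms = step_ms, n_steps = n_steps,
         pre_ms = pre_ms, post_ms = post_ms, count_steps = count_steps),
    class = "step_protocol"
  )
}

#' Command level of each step in a protocol
#' @param protocol A [step_protocol()].
#' @return Numeric vector of absolute command levels (holding + offset),
#'   one per step.
#' @export
step_levels <- function(protocol) {
  protocol$holding + protocol$start_offset +
    protocol$increment * (seq_len(protocol$n_steps) - 1L)
}

#' Default voltage-clamp step family (-90 to +80 mV from -60 mV hold)
#'
#' The ionic-current protocol: 400 ms steps spanning -90 to +80 mV in
#' 10 mV increments from a -60 mV holding potential. The increment is a
#' configuration choice (the published range only fixes the endpoints).
#' @param increment_mv Step increment in mV.
#' @return A [step_protocol()].
#' @export
vc_iv_protocol <- function(increment_mv = 10) {
  n <- as.integer(round((80 - (-90)) / increment_mv)) + 1L
  step_protocol(mode = "voltage_clamp", holding = -60, start_offset = -30,
                increment = increment_mv, step_ms = 400, n_steps = n,
                pre_ms = 100, post_ms = 50, count_steps = n)
}

#' Whole-cell recording: sweeps plus protocol and cell metadata
#'
#' Bundles the sweeps of one acquisition (each sweep a command/response
#' trace pair sharing dt and length), the stimulation protocol (or the
#' marker `"gap_free"` for continuous EPSC recordings), and cell-level
#' metadata such as the holding current used for quality control and
#' pharmacology flags (e.g. 40 uM bicuculline during EPSC recordings).
#'
#' @param cell_id Cell identifier.
#' @param group_label Group/condition label (e.g. `"control"`).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param sweeps List of `list(command = trace|NULL, response = trace)`.
#' @param protocol A [step_protocol()] or the string `"gap_free"`.
#' @param metadata Named list; recognized fields include `holding_pa`
#'   (steady holding current in pA), `bicuculline` (logical),
#'   `junction_mv` (liquid-junction correction, recorded but not applied
#'   by default), `temperature` and free-text notes.
#' @return An object of class `recording`.
#' @export
recording <- function(cell_id, group_label = "unknown",
                      mode = c("current_clamp", "voltage_clamp"),
                      sweeps, protocol = "gap_free", metadata = list()) {
  mode <- match.arg(mode)
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("`sweeps` must be a non-empty list", call. = FALSE)
  dts <- vapply(sweeps, function(s) s$response$dt_ms, numeric(1))
  if (length(unique(dts)) != 1L)
    stop("all sweeps must share the same sampling interval", call. = FALSE)
  for (s in sweeps) {
    if (!is_trace(s$response)) stop("every sweep needs a response trace", call. = FALSE)
    if (!is.null(s$command)) {
      if (!is_trace(s$command)) stop("sweep command must be a trace or NULL", call. = FALSE)
      if (length(s$command$samples) != length(s$response$samples))
        stop("command and response lengths must match within a sweep", call. = FALSE)
    }
  }
  if (!(identical(protocol, "gap_free") || inherits(protocol, "step_protocol")))
    stop("`protocol` must be a step_protocol or \"gap_free\"", call. = FALSE)
  structure(
    list(cell_id = as.character(cell_id), group_label = as.character(group_label),
         mode = mode, sweeps = sweeps, protocol = protocol, metadata = metadata),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  pd <- if (identical(x$protocol, "gap_free")) "gap-free"
        else sprintf("%d steps x %.4g (%s)", x$protocol$n_steps,
                     x$protocol$increment,
                     if (x$mode == "current_clamp") "pA" else "mV")
  cat(sprintf("<recording> %s [%s], %s, %d sweep(s), %s\n",
              x$cell_id, x$group_label, x$mode, length(x$sweeps), pd))
  invisible(x)
}

recording_dt_ms <- function(rec) rec$sweeps[[1]]$response$dt_ms
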