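#' Default analysis configuration
#'
#' Every operational constant of the pipeline lives here, grouped by
#' stage. Values are the package defaults used throughout the
#' documentation; any of them can be overridden from a YAML/JSON file
#' via [load_config()].
#'
#' @return Nested named list of class `synapto_config`.
#' @export
default_config <- function() {
  structure(list(
    spike = list(dvdt_thresh = 10,       # mV/ms rising-slope criterion
                 min_peak_mv = -20,      # absolute peak requirement
                 refractory_ms = 2,      # merge window
                 sg_window_ms = 0.5),    # Savitzky-Golay smoothing
    qc = list(max_holding_pa = 50),      # the >50 pA discard rule
    passive = list(baseline_frac = 0.25, # steady-state window fraction
                   fit_window_frac = 5),
    vc = list(early_ms = 10, blank_ms = 0.5, late_ms = 50),
    epsc = list(min_amp_pa = 5, noise_k = 4, baseline_ms = 200,
                lowpass_hz = 1000, tail_dead_ms = 4, tau_window_ms = 20,
                min_r2 = 0.5, match_ms = 2),
    protocol = list(n_steps = 35L, count_steps = 17L,
                    start_offset_pa = -12, increment_pa = 3,
                    step_ms = 400),
    io = list(apply_junction_correction = FALSE, junction_mv = 10)
  ), class = "synapto_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every missing key
#' with its documented default, and rejects unknown keys — a typo in a
#' detector constant should fail loudly, not fall back silently. An
#' empty or missing file yields the full default configuration.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for defaults.
#' @return A validated `synapto_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stop("config file must contain a mapping: ", path, call. = FALSE)
  bad_sections <- setdiff(names(user), names(cfg))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  for (sec in names(user)) {
    if (!is.list(user[[sec]]))
      stop("config section '", sec, "' must be a mapping", call. = FALSE)
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  p <- cfg$protocol
  p$n_steps <- as.integer(p$n_steps)
  p$count_steps <- as.integer(p$count_steps)
  if (p$count_steps < 1L || p$count_steps > p$n_steps)
    stop("config error: protocol.count_steps (", p$count_steps,
         ") must lie in [1, n_steps = ", p$n_steps, "]", call. = FALSE)
  cfg$protocol <- p
  must_pos <- list(c("spike", "refractory_ms"), c("epsc", "min_amp_pa"),
                   c("epsc", "lowpass_hz"), c("epsc", "baseline_ms"),
                   c("vc", "early_ms"), c("vc", "late_ms"),
                   c("qc", "max_holding_pa"))
  for (m in must_pos) {
    v <- cfg[[m[1]]][[m[2]]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config error: ", m[1], ".", m[2], " must be a positive number",
           call. = FALSE)
  }
  cfg
}
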