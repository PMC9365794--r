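# Recording interchange (HDF5) and feature-table I/O.
#
# Interchange layout (one file per recording):
#   /meta                          JSON string: cell_id, group_label,
#                                  mode, protocol, metadata, dt_ms
#   /sweeps/s0001/response         float64 samples (mV or pA)
#   /sweeps/s0001/command          float64 samples (optional)
# Units are always mV / pA / ms: normalization is total, no trace
# leaves this module in other units.

FEATURES_SCHEMA_VERSION <- "synaptoprobe_features_v1"

#' Write a recording to the HDF5 interchange format
#'
#' @param rec A [recording()].
#' @param path Output file path (conventionally `.h5`); overwritten if
#'   present.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "recording")) stop("`rec` must be a recording", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  proto <- if (identical(rec$protocol, "gap_free")) "gap_free"
           else unclass(rec$protocol)
  meta <- list(cell_id = rec$cell_id, group_label = rec$group_label,
               mode = rec$mode, protocol = proto, metadata = rec$metadata,
               dt_ms = recording_dt_ms(rec),
               format = "synaptoprobe_interchange_v1")
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)),
                 path, "meta")
  rhdf5::h5createGroup(path, "sweeps")
  for (k in seq_along(rec$sweeps)) {
    g <- sprintf("sweeps/s%04d", k)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(rec$sweeps[[k]]$response$samples, path,
                   paste0(g, "/response"))
    if (!is.null(rec$sweeps[[k]]$command))
      rhdf5::h5write(rec$sweeps[[k]]$command$samples, path,
                     paste0(g, "/command"))
  }
  invisible(path)
}

#' Read a recording
#'
#' Reads a whole-cell recording into the package's uniform
#' representation (mV / pA / ms). Only the package interchange format
#' can be parsed in this build: no ABF or NWB (icephys) parser is
#' available to link against, so those formats raise an explicit error
#' asking for conversion to the interchange rather than guessing at a
#' binary layout. Sweep ordering is preserved; the protocol is restored
#' from the file metadata, with the channel kind of each trace inferred
#' from the recording mode.
#'
#' @param path Path to a recording file.
#' @param format One of `"interchange"`, `"abf"`, `"nwb"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("interchange", "abf", "nwb")) {
  format <- match.arg(format)
  if (format %in% c("abf", "nwb"))
    stop("no ", toupper(format), " parser is available in this build; ",
         "convert '", path, "' to the synaptoprobe HDF5 interchange first",
         call. = FALSE)
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  on.exit(rhdf5::H5close(), add = TRUE)
  meta <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta")),
                             simplifyVector = TRUE)
  if (!identical(meta$format, "synaptoprobe_interchange_v1"))
    stop("not a synaptoprobe interchange file: ", path, call. = FALSE)
  dt <- meta$dt_ms
  resp_kind <- if (meta$mode == "current_clamp") "voltage" else "current"
  cmd_kind <- if (meta$mode == "current_clamp") "current" else "voltage"
  top <- rhdf5::h5ls(path, recursive = TRUE)
  sweep_names <- sort(top$name[top$group == "/sweeps"])
  sweeps <- lapply(sweep_names, function(nm) {
    resp <- as.numeric(rhdf5::h5read(path, paste0("sweeps/", nm, "/response")))
    has_cmd <- any(top$group == paste0("/sweeps/", nm) & top$name == "command")
    cmd <- if (has_cmd)
      trace(as.numeric(rhdf5::h5read(path, paste0("sweeps/", nm, "/command"))),
            dt, cmd_kind)
    else NULL
    list(command = cmd, response = trace(resp, dt, resp_kind))
  })
  proto <- if (identical(meta$protocol, "gap_free")) "gap_free"
           else step_protocol(mode = meta$protocol$mode,
                              holding = meta$protocol$holding,
                              start_offset = meta$protocol$start_offset,
                              increment = meta$protocol$increment,
                              step_ms = meta$protocol$step_ms,
                              n_steps = meta$protocol$n_steps,
                              pre_ms = meta$protocol$pre_ms,
                              post_ms = meta$protocol$post_ms,
                              count_steps = meta$protocol$count_steps)
  md <- meta$metadata
  if (length(md) == 0L) md <- list()
  recording(cell_id = meta$cell_id, group_label = meta$group_label,
            mode = meta$mode, sweeps = sweeps, protocol = proto,
            metadata = md)
}

#' Write a per-neuron feature table to CSV
#'
#' One row per neuron; the first line carries the schema version as a
#' `#` comment. Missing metrics are written as empty fields, never as 0.
#'
#' @param features Non-empty per-neuron feature data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_table <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("`features` must be a non-empty data.frame", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", FEATURES_SCHEMA_VERSION), con)
  utils::write.csv(features, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_features_table()]
#' @param path CSV path.
#' @return Data.frame of per-neuron features.
#' @export
read_features_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", na.strings = "",
                  stringsAsFactors = FALSE)
}
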