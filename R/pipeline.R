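#' Run the end-to-end analysis pipeline
#'
#' Orchestrates generate-or-read -> QC -> extract -> summarize ->
#' compare with deterministic provenance. Inputs are either a synthetic
#' cohort specification (`synthetic = cohort_config(...)`) or a
#' directory of interchange recordings laid out as
#' `<cell_id>__<component>.h5` with `component` one of `epsc`, `cc`,
#' `vc`, `mtest`; unrecognized files are logged and skipped, not fatal.
#'
#' Outputs written to `out_dir`: `features.csv`, `events.csv`,
#' `group_table.csv`, `stats.json` (all pairwise comparisons against
#' the first group: Welch t per feature, Fisher exact on the active
#' fraction, one-way ANOVA per current component, Kolmogorov-Smirnov on
#' pooled EPSC amplitudes), `manifest.json` and `run.log`. Every output
#' is deterministic given `(config, seed)` — no timestamps — so a rerun
#' is byte-identical; the manifest lists each file with its MD5.
#'
#' @param synthetic A [cohort_config()], or `NULL` to read recordings.
#' @param input_dir Directory of interchange recordings (used when
#'   `synthetic` is `NULL`).
#' @param out_dir Output directory (created).
#' @param seed Integer seed for the synthetic generator.
#' @param config Analysis configuration ([default_config()] /
#'   [load_config()]).
#' @param write_recordings Also write the generated synthetic
#'   recordings to `out_dir/recordings` as interchange files.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(synthetic = NULL, input_dir = NULL, out_dir,
                         seed = 1, config = default_config(),
                         write_recordings = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  logit("synaptoprobe %s pipeline run, seed=%d",
        as.character(utils::packageVersion("synaptoprobe")), as.integer(seed))
  logit("config: %s", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))

  if (!is.null(synthetic)) {
    cohort <- gen_cohort(synthetic, seed = seed)
    bundles <- cohort$bundles
    logit("generated synthetic cohort: %d neurons in %d groups",
          length(bundles), length(synthetic$groups))
    if (write_recordings) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (b in bundles) for (comp in c("epsc", "cc", "vc", "mtest"))
        if (!is.null(b[[comp]]))
          write_recording(b[[comp]],
                          file.path(rec_dir, paste0(b$cell_id, "__", comp, ".h5")))
    }
    utils::write.csv(cohort$truth[, setdiff(names(cohort$truth), "neuron_seed")],
                     file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  } else {
    if (is.null(input_dir)) stop("either `synthetic` or `input_dir` is required",
                                 call. = FALSE)
    files <- list.files(input_dir, full.names = TRUE)
    if (length(files) == 0L) stop("no recordings found in ", input_dir, call. = FALSE)
    pat <- "^(.*)__(epsc|cc|vc|mtest)\\.h5$"
    cells <- list()
    for (f in files) {
      bn <- basename(f)
      if (!grepl(pat, bn)) { logit("skipping unrecognized file: %s", bn); next }
      cid <- sub(pat, "\\1", bn); comp <- sub(pat, "\\2", bn)
      rec <- tryCatch(read_recording(f), error = function(e) {
        logit("skipping unreadable file %s: %s", bn, conditionMessage(e)); NULL })
      if (is.null(rec)) next
      if (is.null(cells[[cid]]))
        cells[[cid]] <- list(cell_id = cid, group_label = rec$group_label)
      cells[[cid]][[comp]] <- rec
    }
    bundles <- unname(cells)
    if (length(bundles) == 0L) stop("no recordings found in ", input_dir, call. = FALSE)
    logit("read %d neuron bundle(s) from %s", length(bundles), input_dir)
  }

  ext <- extract_cohort_features(bundles, config)
  feats <- ext$features
  for (i in seq_len(nrow(feats)))
    logit("qc %s: %s (holding %.1f pA)", feats$cell_id[i],
          ifelse(feats$qc_passed[i], "pass", "FAIL"), feats$holding_pa[i])

  f_feat <- file.path(out_dir, "features.csv")
  write_features_table(feats, f_feat)
  f_ev <- file.path(out_dir, "events.csv")
  ev <- ext$events
  if (is.null(ev)) ev <- empty_events()
  utils::write.csv(ev, f_ev, row.names = FALSE, na = "")

  groups <- unique(feats$group_label)
  f_grp <- file.path(out_dir, "group_table.csv")
  utils::write.csv(build_group_table(feats, groups), f_grp,
                   row.names = FALSE, na = "")

  stats <- list(groups = groups, n_tests = 0L, comparisons = list())
  if (length(groups) >= 2L) {
    ref <- groups[1]
    cmp_feats <- c("epsc_rate_hz", "epsc_mean_amp_pa", "epsc_mean_tau_ms",
                   "total_evoked_ap", "spike_threshold_mv",
                   "spike_amplitude_mv", "spike_width_ms", "spike_ahp_mv",
                   "capacitance_pf", "input_conductance_ns")
    for (g in groups[-1]) {
      for (fc in cmp_feats) {
        cmp <- tryCatch(compare_feature(feats, fc, ref, g),
                        error = function(e) NULL)
        if (!is.null(cmp)) {
          stats$comparisons[[paste(fc, g, sep = "|")]] <-
            unclass(cmp)[c("feature", "group_a", "group_b", "n_a", "n_b",
                           "mean_a", "mean_b", "sem_a", "sem_b", "test",
                           "statistic", "p_value")]
          stats$n_tests <- stats$n_tests + 1L
        }
      }
      af <- tryCatch(compare_active_fraction(feats, ref, g),
                     error = function(e) NULL)
      if (!is.null(af)) {
        stats$comparisons[[paste("active_fraction", g, sep = "|")]] <-
          unclass(af)[c("feature", "group_a", "group_b", "n_a", "n_b",
                        "mean_a", "mean_b", "test", "p_value")]
        stats$n_tests <- stats$n_tests + 1L
      }
      if (!is.null(ev) && nrow(ev)) {
        ca <- ev$amp_pa[ev$cell_id %in% feats$cell_id[feats$group_label == ref & feats$qc_passed]]
        cb <- ev$amp_pa[ev$cell_id %in% feats$cell_id[feats$group_label == g & feats$qc_passed]]
        if (length(ca) && length(cb)) {
          ks <- amplitude_ecdf_compare(ca, cb)
          stats$comparisons[[paste("amplitude_ecdf", g, sep = "|")]] <-
            unclass(ks)
          stats$n_tests <- stats$n_tests + 1L
        }
      }
    }
    for (comp in c("na", "kfast", "kslow")) {
      an <- tryCatch(iv_family_anova(feats, comp, groups),
                     error = function(e) NULL)
      if (!is.null(an)) {
        stats$comparisons[[paste("iv_anova", comp, sep = "|")]] <-
          unclass(an)[c("feature", "n_a", "n_b", "test", "statistic", "p_value")]
        stats$n_tests <- stats$n_tests + 1L
      }
    }
  }
  logit("ran %d statistical tests (no multiple-testing correction applied)",
        stats$n_tests)
  f_stats <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, f_stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  f_log <- file.path(out_dir, "run.log")
  writeLines(log_lines, f_log)

  outputs <- c(f_feat, f_ev, f_grp, f_stats, f_log)
  if (!is.null(synthetic)) outputs <- c(outputs, file.path(out_dir, "ground_truth.csv"))
  if (!is.null(synthetic) && write_recordings)
    outputs <- c(outputs, list.files(file.path(out_dir, "recordings"),
                                     full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("synaptoprobe")),
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(text_md5_file(config))),
    input = if (is.null(synthetic)) list(kind = "directory", path = input_dir)
            else list(kind = "synthetic",
                      groups = lapply(synthetic$groups, function(g) g$n)),
    qc = stats::setNames(as.list(feats$qc_passed), feats$cell_id),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# hash a config by serializing it to canonical JSON in a temp file
text_md5_file <- function(config) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  f
}
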