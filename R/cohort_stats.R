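#' Compare one per-neuron feature between two groups
#'
#' Two-sample, two-tailed t-test on a per-neuron feature, reported with
#' group means and standard errors of the mean. The default is the
#' Welch (unequal-variance) form; `pooled = TRUE` gives the classical
#' pooled-variance Student's t for sensitivity checks. Missing values
#' are excluded and the contributing n per group reported.
#'
#' @param features A data.frame of per-neuron features (one row per
#'   neuron) with a `group_label` column, e.g. from
#'   [extract_neuron_features()] / [read_features_table()].
#' @param feature Name of the feature column.
#' @param group_a,group_b Group labels to compare.
#' @param pooled Use pooled-variance Student's t instead of Welch.
#' @param qc_only Restrict to rows with `qc_passed == TRUE` (default).
#' @return A list of class `group_comparison`: groups, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`, `test`, `statistic`,
#'   `p_value`.
#' @export
compare_feature <- function(features, feature, group_a, group_b,
                            pooled = FALSE, qc_only = TRUE) {
  xa <- feature_values(features, feature, group_a, qc_only)
  xb <- feature_values(features, feature, group_b, qc_only)
  for (g in list(list(group_a, xa), list(group_b, xb)))
    if (length(g[[2]]) < 2L)
      stop("group '", g[[1]], "' has fewer than 2 non-missing values for '",
           feature, "'", call. = FALSE)
  tt <- stats::t.test(xa, xb, var.equal = pooled)
  structure(list(group_a = group_a, group_b = group_b,
                 feature = feature,
                 n_a = length(xa), n_b = length(xb),
                 mean_a = mean(xa), mean_b = mean(xb),
                 sem_a = stats::sd(xa) / sqrt(length(xa)),
                 sem_b = stats::sd(xb) / sqrt(length(xb)),
                 test = if (pooled) "student_t" else "welch_t",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "group_comparison")
}

feature_values <- function(features, feature, group, qc_only = TRUE) {
  if (!feature %in% names(features))
    stop("no feature column '", feature, "'", call. = FALSE)
  sel <- features$group_label == group
  if (qc_only && "qc_passed" %in% names(features))
    sel <- sel & features$qc_passed %in% TRUE
  x <- features[[feature]][sel]
  x[is.finite(x)]
}

#' Compare the fraction of synaptically active neurons between groups
#'
#' Builds the 2x2 active/inactive contingency table from the per-neuron
#' activity flags (the >20-events-per-60-s classification) and tests it
#' with a two-tailed Fisher exact test (`chisq = TRUE` switches to the
#' chi-squared approximation).
#'
#' @inheritParams compare_feature
#' @param chisq Use the chi-squared test instead of Fisher's exact test.
#' @return A `group_comparison` with `mean_*` holding the active
#'   fractions and an extra `table` element.
#' @export
compare_active_fraction <- function(features, group_a, group_b,
                                    chisq = FALSE, qc_only = TRUE) {
  flags <- function(group) {
    sel <- features$group_label == group
    if (qc_only && "qc_passed" %in% names(features))
      sel <- sel & features$qc_passed %in% TRUE
    f <- features$epsc_active[sel]
    f[!is.na(f)]
  }
  fa <- flags(group_a); fb <- flags(group_b)
  if (length(fa) == 0L || length(fb) == 0L)
    stop("empty group in active-fraction comparison", call. = FALSE)
  tab <- matrix(c(sum(fa), sum(!fa), sum(fb), sum(!fb)), nrow = 2, byrow = TRUE,
                dimnames = list(c(group_a, group_b), c("active", "inactive")))
  ht <- if (chisq) suppressWarnings(stats::chisq.test(tab))
        else stats::fisher.test(tab)
  structure(list(group_a = group_a, group_b = group_b,
                 feature = "active_fraction",
                 n_a = length(fa), n_b = length(fb),
                 mean_a = mean(fa), mean_b = mean(fb),
                 sem_a = NA_real_, sem_b = NA_real_,
                 test = if (chisq) "chisq" else "fisher_exact",
                 statistic = if (chisq) unname(ht$statistic) else NA_real_,
                 p_value = ht$p.value,
                 table = tab),
            class = "group_comparison")
}

#' One-way ANOVA on ionic-current densities across groups
#'
#' Each neuron contributes a single extreme density of the chosen
#' component (sodium: the most negative peak density across steps;
#' potassium: the largest density across steps); a one-way ANOVA then
#' tests for group differences. A per-voltage two-way layout
#' (`per_voltage = TRUE`, groups x step voltage, neuron densities at
#' every step) is available because the summary-statistic layout is a
#' modeling choice, not a given.
#'
#' @param features Per-neuron feature data.frame containing
#'   `<component>_peak_density` columns (and, for `per_voltage`, an
#'   `iv_list` attribute as produced by [extract_neuron_features()]).
#' @param component `"na"`, `"kfast"` or `"kslow"`.
#' @param groups Character vector (>= 2) of group labels.
#' @param per_voltage Use the per-step two-way layout.
#' @param qc_only Restrict to QC-passed neurons.
#' @return A `group_comparison` with `test = "anova"`, `statistic` = F,
#'   and `p_value`.
#' @export
iv_family_anova <- function(features, component = c("na", "kfast", "kslow"),
                            groups, per_voltage = FALSE, qc_only = TRUE) {
  component <- match.arg(component)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  col <- paste0(component, "_peak_density")
  vals <- lapply(groups, function(g) feature_values(features, col, g, qc_only))
  bad <- lengths(vals) < 2L
  if (any(bad))
    stop("group(s) ", paste(groups[bad], collapse = ", "),
         " have fewer than 2 neurons with I-V data", call. = FALSE)
  if (!per_voltage) {
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(groups, lengths(vals)), levels = groups))
    fit <- stats::aov(y ~ g, data = df)
    s <- summary(fit)[[1]]
    fstat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  } else {
    ivs <- attr(features, "iv_list")
    if (is.null(ivs)) stop("per-voltage ANOVA needs the iv_list attribute", call. = FALSE)
    rows <- list()
    for (i in seq_len(nrow(features))) {
      if (!features$group_label[i] %in% groups) next
      if (qc_only && !isTRUE(features$qc_passed[i])) next
      iv <- ivs[[features$cell_id[i]]]
      if (is.null(iv)) next
      dens <- switch(component, na = iv$na_peak_density,
                     kfast = iv$kfast_density, kslow = iv$kslow_density)
      rows[[length(rows) + 1L]] <- data.frame(
        y = dens, v = iv$step_mv, g = features$group_label[i])
    }
    df <- do.call(rbind, rows)
    df$g <- factor(df$g, levels = groups)
    fit <- stats::aov(y ~ g + factor(v), data = df)
    s <- summary(fit)[[1]]
    fstat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  }
  structure(list(group_a = groups[1], group_b = paste(groups[-1], collapse = "+"),
                 feature = col,
                 n_a = lengths(vals)[1], n_b = sum(lengths(vals)[-1]),
                 mean_a = mean(vals[[1]]), mean_b = mean(unlist(vals[-1])),
                 sem_a = NA_real_, sem_b = NA_real_,
                 test = "anova", statistic = fstat, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> %s: %s (n=%d, %.4g +- %.3g) vs %s (n=%d, %.4g +- %.3g), stat=%.4g, p=%.4g\n",
              x$test, x$feature,
              x$group_a, x$n_a, x$mean_a, x$sem_a,
              x$group_b, x$n_b, x$mean_b, x$sem_b,
              ifelse(is.na(x$statistic), NA, x$statistic), x$p_value))
  invisible(x)
}

#' Per-group summary table (n, mean, SEM per feature)
#'
#' One row per group with, for every numeric feature, the contributing
#' n, mean and SEM, plus the active fraction — the table behind the
#' bar-and-error-bar panels of a cohort report. No multiple-testing
#' correction is involved here; comparisons themselves annotate the
#' number of tests run.
#'
#' @param features Per-neuron feature data.frame.
#' @param groups Group labels (default: all present).
#' @param qc_only Restrict to QC-passed neurons.
#' @return A data.frame, one row per group.
#' @export
build_group_table <- function(features, groups = unique(features$group_label),
                              qc_only = TRUE) {
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      c())
  rows <- lapply(groups, function(g) {
    sel <- features$group_label == g
    if (qc_only && "qc_passed" %in% names(features))
      sel <- sel & features$qc_passed %in% TRUE
    row <- list(group = g, n = sum(sel))
    for (cn in num_cols) {
      x <- features[[cn]][sel]
      x <- x[is.finite(x)]
      row[[paste0(cn, "_n")]] <- length(x)
      row[[paste0(cn, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0(cn, "_sem")]] <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    if ("epsc_active" %in% names(features)) {
      f <- features$epsc_active[sel]
      f <- f[!is.na(f)]
      row$active_fraction <- if (length(f)) mean(f) else NA_real_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
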