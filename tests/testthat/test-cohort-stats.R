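make_features <- function(a, b, active_a = NULL, active_b = NULL) {
  data.frame(cell_id = paste0("n", seq_len(length(a) + length(b))),
             group_label = rep(c("A", "B"), c(length(a), length(b))),
             qc_passed = TRUE,
             epsc_rate_hz = c(a, b),
             epsc_active = c(active_a %||% rep(TRUE, length(a)),
                             active_b %||% rep(TRUE, length(b))))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("identical groups give t = 0 and p = 1; swapping groups negates t", {
  x <- c(1.2, 0.8, 1.0, 1.4, 0.6)
  f <- make_features(x, x)
  cmp <- compare_feature(f, "epsc_rate_hz", "A", "B")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$sem_a, sd(x) / sqrt(5))
  f2 <- make_features(x, x * 2)
  ab <- compare_feature(f2, "epsc_rate_hz", "A", "B")
  ba <- compare_feature(f2, "epsc_rate_hz", "B", "A")
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("groups with fewer than two values are refused by name", {
  f <- make_features(c(1, 2, 3), 1)
  expect_error(compare_feature(f, "epsc_rate_hz", "A", "B"), "'B'")
  expect_error(compare_feature(f, "nonexistent", "A", "B"), "nonexistent")
})

test_that("QC-failed neurons are excluded from comparisons", {
  f <- make_features(c(1, 1.2, 0.9), c(1.1, 0.9, 1.0, 100))
  f$qc_passed[7] <- FALSE
  cmp <- compare_feature(f, "epsc_rate_hz", "A", "B")
  expect_equal(cmp$n_b, 3)
  expect_equal(cmp$mean_b, 1)
})

test_that("a 5x rate depression is detected in most replicate cohorts", {
  cfg <- cohort_config(groups = list(
    control = group_spec(n = 15, epsc_rate_mean_hz = 1, epsc_rate_cv = 0.8),
    pd = group_spec(n = 15, epsc_rate_mean_hz = 1, epsc_rate_cv = 0.8,
                    rate_scale = 0.2)))
  hits <- 0; ratio_ok <- 0; n_rep <- 200
  for (s in seq_len(n_rep)) {
    p <- draw_cohort_params(cfg, seed = s)
    a <- p$epsc_rate_hz[p$group_label == "control"]
    b <- p$epsc_rate_hz[p$group_label == "pd"]
    if (t.test(a, b)$p.value < 0.05) hits <- hits + 1
    r <- mean(b) / mean(a)
    if (r >= 0.1 && r <= 0.4) ratio_ok <- ratio_ok + 1
  }
  expect_gte(hits / n_rep, 0.8)
  expect_gte(ratio_ok / n_rep, 0.95)
})

test_that("identical groups are declared non-significant in most replicates", {
  cfg <- cohort_config(groups = list(a = group_spec(n = 15),
                                     b = group_spec(n = 15)))
  fp <- 0; n_rep <- 200
  for (s in seq_len(n_rep)) {
    p <- draw_cohort_params(cfg, seed = 10000 + s)
    if (t.test(p$epsc_rate_hz[p$group_label == "a"],
               p$epsc_rate_hz[p$group_label == "b"])$p.value < 0.05)
      fp <- fp + 1
  }
  expect_gte((n_rep - fp) / n_rep, 0.90)
})

test_that("Fisher exact matches hypergeometric enumeration on canonical tables", {
  f <- make_features(rep(1, 10), rep(1, 10),
                     active_a = rep(TRUE, 10),
                     active_b = c(rep(TRUE, 2), rep(FALSE, 8)))
  cmp <- compare_active_fraction(f, "A", "B")
  expect_equal(cmp$test, "fisher_exact")
  expect_equal(cmp$p_value, fisher_exact_enum(10, 0, 2, 8), tolerance = 1e-10)
  expect_equal(unname(cmp$table[1, ]), c(10, 0))
  # identical active patterns: p = 1
  f2 <- make_features(rep(1, 10), rep(1, 10))
  expect_equal(compare_active_fraction(f2, "A", "B")$p_value, 1)
  # random tables up to n = 30
  set.seed(4)
  for (i in 1:30) {
    tab <- rmultinom(1, sample(8:30, 1), rep(0.25, 4))
    expect_equal(fisher.test(matrix(tab, 2))$p.value,
                 fisher_exact_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-8)
  }
  expect_error(compare_active_fraction(make_features(1, numeric(0)), "A", "B"),
               "empty group")
})

test_that("the chi-squared alternative is available behind its flag", {
  f <- make_features(rep(1, 12), rep(1, 12),
                     active_a = c(rep(TRUE, 10), FALSE, FALSE),
                     active_b = c(rep(TRUE, 3), rep(FALSE, 9)))
  cmp <- compare_active_fraction(f, "A", "B", chisq = TRUE)
  expect_equal(cmp$test, "chisq")
  expect_true(is.finite(cmp$statistic))
})

test_that("one-way ANOVA on extreme densities behaves at the null and under effects", {
  mk_iv_features <- function(na_means, n = 10, seed = 1) {
    withr::with_seed(seed, {
      g <- rep(names(na_means), each = n)
      data.frame(cell_id = paste0(g, seq_along(g)), group_label = g,
                 qc_passed = TRUE,
                 na_peak_density = unlist(lapply(na_means, function(m)
                   rnorm(n, m, 2))))
    })
  }
  # two identical copies of one group: F ~ 0
  f <- mk_iv_features(c(a = -20, b = -20), seed = 2)
  f$na_peak_density[f$group_label == "b"] <- f$na_peak_density[f$group_label == "a"]
  an <- iv_family_anova(f, "na", c("a", "b"))
  expect_lt(an$statistic, 1e-20)
  # a strong group effect is detected
  f2 <- mk_iv_features(c(a = -20, b = -5), seed = 3)
  expect_lt(iv_family_anova(f2, "na", c("a", "b"))$p_value, 0.01)
  expect_error(iv_family_anova(mk_iv_features(c(a = -20, b = -5)), "na",
                               c("a", "missing")),
               "missing")
})

test_that("group tables report n, mean, SEM and handle all-missing features", {
  f <- make_features(rnorm(15, 1), rnorm(15, 0.2))
  f$capacitance_pf <- NA_real_
  tab <- build_group_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n, c(15, 15))
  expect_equal(tab$capacitance_pf_n, c(0, 0))
  expect_true(all(is.na(tab$capacitance_pf_mean)))
  expect_equal(tab$epsc_rate_hz_mean[1], mean(f$epsc_rate_hz[1:15]))
  expect_equal(tab$active_fraction, c(1, 1))
})

test_that("cohort table means track the generator means", {
  cfg <- cohort_config(groups = list(a = group_spec(n = 15),
                                     b = group_spec(n = 15, rate_scale = 0.2)))
  p <- draw_cohort_params(cfg, seed = 77)
  f <- data.frame(cell_id = p$cell_id, group_label = p$group_label,
                  qc_passed = TRUE, epsc_rate_hz = p$epsc_rate_hz,
                  epsc_active = p$epsc_rate_hz * 60 > 20)
  tab <- build_group_table(f)
  for (i in 1:2) {
    target <- c(a = 1, b = 0.2)[tab$group[i]]
    expect_lt(abs(tab$epsc_rate_hz_mean[i] - target),
              2 * tab$epsc_rate_hz_sem[i] + 0.15)
  }
})
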