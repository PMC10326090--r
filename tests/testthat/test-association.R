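test_that("clinical_grouping partitions 0..4 into none/low/high", {
  g <- clinical_grouping(0:4)
  expect_equal(as.character(g), c("none", "low", "low", "high", "high"))
  expect_equal(levels(g), c("none", "low", "high"))
  expect_true(is.na(clinical_grouping(NA)))
  expect_error(clinical_grouping(5), "0\\.\\.4")
})

test_that("compare_groups reports medians, ranges and reference tests", {
  set.seed(88)
  x <- c(rnorm(30), rnorm(30))
  g <- rep(c("a", "b"), each = 30)
  res <- compare_groups(x, g, reference = "a")
  expect_equal(res$groups$group, c("a", "b"))
  expect_true(is.na(res$groups$p_value[1]))
  expect_false(is.na(res$groups$p_value[2]))
  # medians lie within the reported min-max
  expect_true(all(res$groups$median >= res$groups$min &
                    res$groups$median <= res$groups$max))
  # identical groups: large-sample two-sided MW p = 1
  res2 <- compare_groups(c(1:30, 1:30), g, reference = "a")
  expect_equal(res2$groups$p_value[2], 1)
  # empty group excluded with warning
  gf <- factor(g, levels = c("a", "b", "c"))
  expect_warning(compare_groups(x, gf, reference = "a"), "empty")
  expect_error(compare_groups(x, g, reference = "z"), "reference")
})

test_that("kruskal-wallis on 2 tie-free groups equals z^2 of the MW approx", {
  set.seed(89)
  x <- sample(seq(0.001, 1, length.out = 40))  # no ties
  g <- rep(c("a", "b"), each = 20)
  res <- compare_groups(x, g, reference = "a")
  kw_stat <- res$kruskal$statistic
  z <- stats::qnorm(res$groups$p_value[2] / 2)
  expect_equal(kw_stat, z^2, tolerance = 1e-8)
  expect_equal(res$kruskal$p_value, res$groups$p_value[2], tolerance = 1e-8)
})

test_that("exact Mann-Whitney is used for small tie-free samples", {
  x <- c(1.1, 2.3, 3.7)
  y <- c(4.2, 5.9, 6.4)
  res <- compare_groups(c(x, y), rep(c("a", "b"), each = 3), "a")
  # exact two-sided p for complete separation with n = m = 3: 2/choose(6,3)
  expect_equal(res$groups$p_value[2], 2 / choose(6, 3))
})

test_that("chi2_beasley matches closed forms and the residual oracle", {
  res <- chi2_beasley(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_equal(abs(as.vector(res$residuals)), rep(sqrt(20), 4))

  # perfectly proportional table: zero residuals, zero chi-square
  prop <- outer(c(10, 20), c(3, 7)) / 10
  res <- chi2_beasley(prop)
  expect_equal(res$statistic, 0)
  expect_equal(max(abs(res$residuals)), 0)
  expect_equal(unname(res$p_cells), matrix(1, 2, 2))

  set.seed(99)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 8) + 1, 3, 3)
    res <- chi2_beasley(tab)
    expect_equal(unname(res$residuals), beasley_oracle(tab),
                 tolerance = 1e-10)
    # chi-square equals sum (O-E)^2 / E, and (O-E) rows sum to zero
    expect_equal(res$statistic,
                 sum((tab - res$expected)^2 / res$expected),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(tab - res$expected)), rep(0, 3),
                 tolerance = 1e-10)
    expect_true(all(res$p_cells_bonferroni >= res$p_cells - 1e-12))
  }

  expect_warning(chi2_beasley(matrix(c(5, 2, 0, 0, 3, 2), 2)), "empty")
  expect_error(chi2_beasley(matrix(-1, 2, 2)), "non-negative")
})

test_that("correlate_measures gives a unit-diagonal symmetric matrix", {
  set.seed(111)
  base <- rnorm(40)
  df <- data.frame(biopsy_id = paste0("b", 1:40),
                   s1 = base + rnorm(40, sd = 0.2),
                   s2 = base + rnorm(40, sd = 0.2),
                   flat = rep(1, 40))
  rho <- correlate_measures(df)
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(rho, t(rho))
  expect_gt(rho["s1", "s2"], 0.8)
  expect_true(is.na(rho["s1", "flat"]))
  # s2 = s1 + constant within a subset -> rank correlation 1
  df2 <- data.frame(s1 = 1:10, s2 = 1:10 + 3)
  expect_equal(correlate_measures(df2)["s1", "s2"], 1)
})

test_that("grading systems correlate more with each other than with clinic", {
  # strong mutual association of the grading systems, moderate association
  # with the clinical grades, averaged over replicate cohorts
  mats <- lapply(1:25, function(i) {
    co <- simulate_cohort(sim_config(n_biopsies = 120, seed = 5000 + i))
    p <- panel_means(co$ratings)
    g <- panel_grades(grade_assessments(co$ratings))
    m <- merge(merge(g, sum_scores(p), by = "biopsy_id"),
               co$clinical[, c("biopsy_id", "glucksberg_overall",
                               "gi_stage")],
               by = "biopsy_id")
    correlate_measures(m)
  })
  rho <- Reduce(`+`, mats) / length(mats)
  systems <- c("lerner", "sale", "melson", "nih")
  internal <- rho[systems, systems]
  external <- rho[c(systems, "s1", "s2", "s3"),
                  c("glucksberg_overall", "gi_stage")]
  expect_gt(min(internal), max(external))
  expect_true(all(external > 0.2))  # moderate, positive external link
})

test_that("association_report emits a row per measure, axis and group", {
  co <- simulate_cohort(sim_config(n_biopsies = 100, seed = 13))
  p <- panel_means(co$ratings)
  measures <- merge(p[, c("biopsy_id", "mean_cab")],
                    sum_scores(p), by = "biopsy_id")
  rep <- association_report(measures, co$clinical)
  expect_setequal(unique(rep$measure), c("mean_cab", "s1", "s2", "s3"))
  expect_setequal(unique(rep$axis),
                  c("glucksberg", "gi_stage", "steroid_response", "survival"))
  expect_true(all(rep$median >= rep$min & rep$median <= rep$max))
  expect_true(all(rep$n >= 1))
  # intolerant cases are not summarised on the steroid axis
  expect_false("intolerant" %in% rep$group)
  # stars agree with raw p at the usual thresholds
  expect_equal(rep$stars, p_stars(rep$p_value))
})

test_that("cab_cutoff_sweep builds monotone splits and flags degenerates", {
  co <- simulate_cohort(sim_config(n_biopsies = 100, seed = 14))
  data <- merge(panel_means(co$ratings)[, c("biopsy_id", "mean_cab")],
                co$clinical, by = "biopsy_id")
  cutoffs <- c(0.5, 1, 2, 3, 5, 6, 7)
  sw <- cab_cutoff_sweep(data, cutoffs)
  expect_equal(nrow(sw), length(cutoffs) * 5)
  # biopsies below the cut-off grow with the cut-off, for every outcome
  for (oc in unique(sw$outcome)) {
    nb <- sw$n_below[sw$outcome == oc]
    expect_true(all(diff(nb) >= 0))
  }
  expect_true(all(is.na(sw$p_value[sw$skipped])))
  expect_true(all(!is.na(sw$p_value[!sw$skipped])))
  tabs <- attr(sw, "tables")
  expect_true(all(vapply(tabs, sum, numeric(1)) <= nrow(data)))
  # a cut-off below every observed count leaves one side empty -> skipped
  sw2 <- cab_cutoff_sweep(data[data$mean_cab >= 1, ], 0.25)
  expect_true(all(sw2$skipped))
  expect_error(cab_cutoff_sweep(data, c(-1, 2)), "positive")
  expect_error(cab_cutoff_sweep(data, c(2, 1)), "sorted")
})
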