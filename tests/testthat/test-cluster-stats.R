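# Prevalence estimators, cluster-summary t-test, group comparisons and risk
# cross-tabulations.

# Closed-form two-sample statistics, written directly from the textbook
# formulas, as the independent oracle.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("fixture HIV prevalence among the self-reported active is 5.7%", {
  p <- prevalence(build_inpaper_fixture(), hiv_result == "positive",
                  subset = self_report_active == "yes")
  expect_identical(c(p$numerator, p$denominator), c(61L, 1066L))
  expect_equal(round(p$unadjusted_percent, 1), 5.7)
})

test_that("adjusted equals unadjusted when all clusters share size and prevalence", {
  cohort <- tibble::as_tibble(random_cohort(n = 40, seed = 3, n_clusters = 1))
  # two identical clusters: same records, relabelled
  c2 <- cohort
  c2$cluster_id <- "school_02"
  c2$student_id <- paste0(c2$student_id, "b")
  both <- as_cohort(dplyr::bind_rows(cohort, c2))
  p <- prevalence(both, hiv_result == "positive")
  expect_equal(p$adjusted_percent, p$unadjusted_percent, tolerance = 1e-12)
})

test_that("adjusted prevalence is the unweighted cluster mean regardless of cluster size", {
  cohort <- tibble::tibble(
    student_id = sprintf("S%04d", 1:1010),
    cluster_id = rep(c("small", "big"), c(10, 1000)),
    positive = c(rep(c(TRUE, FALSE), c(2, 8)), rep(c(TRUE, FALSE), c(400, 600)))
  )
  p <- prevalence(cohort, positive)
  expect_equal(p$adjusted_percent, 30)
  expect_equal(p$unadjusted_percent, 100 * 402 / 1010)
})

test_that("an empty complete-case denominator raises an estimation error naming the variable", {
  cohort <- as_cohort(one_record(hiv_result = NA_character_))
  expect_error(prevalence(cohort, hiv_result == "positive"),
               "hiv_result", class = "msap_estimation_error")
})

test_that("prevalences are invariant to record permutation and cluster renaming", {
  cohort <- tibble::as_tibble(random_cohort(n = 200, seed = 12, n_clusters = 6))
  p0 <- prevalence(cohort, hsv2_result == "positive")
  set.seed(1)
  p1 <- prevalence(cohort[sample(nrow(cohort)), ], hsv2_result == "positive")
  expect_equal(p1$unadjusted_percent, p0$unadjusted_percent)
  expect_equal(p1$adjusted_percent, p0$adjusted_percent)
  renamed <- cohort
  renamed$cluster_id <- chartr("0123456789", "9876543210", renamed$cluster_id)
  p2 <- prevalence(renamed, hsv2_result == "positive")
  expect_equal(sort(p2$clusters$percent), sort(p0$clusters$percent))
  expect_equal(p2$adjusted_percent, p0$adjusted_percent)
})

test_that("identical cluster summaries give t = 0, p = 1", {
  v <- c(10, 25, 40, 55)
  cmp <- cluster_summary_ttest(v, v)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("t-test matches the closed form to 1e-12 in both variance modes", {
  cmp <- cluster_summary_ttest(c(10, 20, 30), c(40, 50, 60))
  oracle <- student_t_oracle(c(10, 20, 30), c(40, 50, 60))
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-12)
  expect_identical(cmp$degrees_of_freedom, oracle$df)

  set.seed(42)
  for (i in 1:20) {
    a <- runif(sample(2:8, 1), 0, 100)
    b <- runif(sample(2:8, 1), 0, 100)
    pooled <- cluster_summary_ttest(a, b, mode = "pooled")
    op <- student_t_oracle(a, b)
    expect_equal(pooled$t_statistic, op$t, tolerance = 1e-12)
    expect_equal(pooled$p_value, op$p, tolerance = 1e-12)
    welch <- cluster_summary_ttest(a, b, mode = "welch")
    ow <- welch_t_oracle(a, b)
    expect_equal(welch$t_statistic, ow$t, tolerance = 1e-12)
    expect_equal(welch$degrees_of_freedom, ow$df, tolerance = 1e-12)
    expect_equal(welch$p_value, ow$p, tolerance = 1e-12)
  }
})

test_that("swapping groups negates t and preserves p", {
  set.seed(7)
  a <- runif(5, 0, 100); b <- runif(6, 0, 100)
  fwd <- cluster_summary_ttest(a, b)
  rev <- cluster_summary_ttest(b, a)
  expect_equal(rev$t_statistic, -fwd$t_statistic)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("fewer than two clusters per group is an inference error", {
  expect_error(cluster_summary_ttest(5, c(1, 2, 3)), class = "msap_inference_error")
  expect_error(cluster_summary_ttest(c(1, 2), numeric(0)), class = "msap_inference_error")
})

test_that("the paired variant requires matched clusters and preserves symmetry", {
  set.seed(8)
  a <- runif(6, 0, 100); b <- runif(6, 0, 100)
  fwd <- cluster_summary_ttest(a, b, paired = TRUE)
  rev <- cluster_summary_ttest(b, a, paired = TRUE)
  expect_equal(rev$t_statistic, -fwd$t_statistic)
  expect_equal(rev$p_value, fwd$p_value)
  expect_error(cluster_summary_ttest(a, b[1:4], paired = TRUE),
               class = "msap_inference_error")
})

test_that("fixture group comparison reproduces the published female percentages", {
  fx <- build_inpaper_fixture()
  res <- classify_cohort(fx)
  cmp <- compare_groups(fx, res, sex == "female",
                        status == "newly_identified",
                        status == "self_reported_active")
  expect_equal(round(cmp$unadjusted_percent_a, 1), 66.4)
  expect_equal(round(cmp$unadjusted_percent_b, 1), 41.9)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("risk cross-tabulation reproduces the published high-risk cell and collapses consistently", {
  fx <- build_inpaper_fixture()
  res <- classify_cohort(fx)
  groups <- rlang::quos(active = status == "self_reported_active",
                        not_active_report = !is.na(self_report_active) &
                          self_report_active == "no")
  tab4 <- risk_crosstab(fx, res, groups)
  high <- tab4[tab4$group == "active" & tab4$category == "high", ]
  expect_identical(c(high$n, high$N), c(417L, 899L))
  expect_equal(round(high$percent, 1), 46.4)

  tab2 <- risk_crosstab(fx, res, groups, collapse = TRUE)
  for (g in unique(tab4$group)) {
    at_risk_4 <- sum(tab4$n[tab4$group == g & tab4$category != "no_risk"])
    expect_identical(tab2$n[tab2$group == g & tab2$category == "at_risk"], at_risk_4)
    expect_identical(tab2$n[tab2$group == g & tab2$category == "no_risk"],
                     tab4$n[tab4$group == g & tab4$category == "no_risk"])
  }
})

test_that("an all-no-risk group collapses to 100% / 0%", {
  cohort <- random_cohort(n = 30, seed = 21)
  cohort$risk_perception <- "no_risk"
  tab <- risk_crosstab(as_cohort(cohort), classify_cohort(as_cohort(cohort)),
                       rlang::quos(all = TRUE), collapse = TRUE)
  expect_equal(tab$percent[tab$category == "no_risk"], 100)
  expect_equal(tab$percent[tab$category == "at_risk"], 0)
})
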