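# Synthetic generator: determinism, degenerate configurations, analytic
# calibration, and fidelity of the reconstructed fixture.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(tibble::as_tibble(a$cohort), tibble::as_tibble(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cfg, seed = 34)
  expect_false(identical(tibble::as_tibble(a$cohort), tibble::as_tibble(c$cohort)))
})

test_that("generation restores the caller's RNG state", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  state <- .Random.seed
  invisible(generate_cohort(small_config(seed = 5)))
  expect_identical(.Random.seed, state)
  expect_identical(runif(1), before)
})

test_that("a never-active cohort with clean indicators is entirely not_active", {
  cfg <- small_config(p_active = const_rates(0),
                      indicator_rates = flat_indicator_rates(active = 0.5, inactive = 0),
                      p_selfreport_missing = 0, seed = 2)
  res <- classify_cohort(generate_cohort(cfg)$cohort)
  expect_true(all(res$status == "not_active"))
})

test_that("invalid configurations are rejected with the key named", {
  expect_error(small_config(sex_ratio_female = 1.2), "sex_ratio_female",
               class = "msap_config_error")
  expect_error(small_config(p_disclose = const_rates(-0.1)), "p_disclose",
               class = "msap_config_error")
  expect_error(small_config(n_clusters = 0), "n_clusters",
               class = "msap_config_error")
  bad_age <- c("15_or_under" = 0.5, "16_17" = 0.4, "18_19" = 0.2, "20_plus" = 0.1)
  expect_error(small_config(age_distribution = bad_age), "age_distribution",
               class = "msap_config_error")
  bad_preg <- flat_indicator_rates()
  bad_preg$PREG_TEST$active[["male"]] <- 0.1
  expect_error(small_config(indicator_rates = bad_preg), "PREG_TEST",
               class = "msap_config_error")
})

test_that("male records never carry a positive pregnancy test", {
  sim <- generate_cohort(small_config(seed = 17))
  males <- sim$cohort[sim$cohort$sex == "male", ]
  expect_true(all(is.na(males$pregnancy_test)))
})

test_that("empirical stratum prevalences converge to the analytic mixtures", {
  # school effects off: with them on, between-school variance does not shrink
  # as schools grow, so the law-of-large-numbers check targets the pure mixture
  cfg <- simulation_config(n_clusters = 10, cluster_size_mean = 10000,
                           cluster_size_dispersion = 0, cluster_effect_sd = 0,
                           seed = 101)
  sim <- generate_cohort(cfg)
  cohort <- sim$cohort
  checks <- list(list(ind = "HIV", col = "hiv_result", pos = "positive", sex = "female"),
                 list(ind = "HSV2", col = "hsv2_result", pos = "positive", sex = "male"),
                 list(ind = "EVER_PREG", col = "ever_pregnant_or_made_pregnant",
                      pos = "yes", sex = "female"))
  for (ck in checks) {
    sub <- cohort[cohort$sex == ck$sex, ]
    p_hat <- mean(sub[[ck$col]] == ck$pos, na.rm = TRUE)
    p_exp <- expected_indicator_prevalence(cfg, ck$ind, ck$sex)
    se <- sqrt(p_exp * (1 - p_exp) / nrow(sub))
    expect_lt(abs(p_hat - p_exp), 3 * se + 1e-12)
  }
})

test_that("the closed-form gap reduces to the stratum mixture formula without school effects", {
  cfg <- small_config(cluster_effect_sd = 0, p_selfreport_missing = 0)
  w_sex <- c(female = cfg$sex_ratio_female, male = 1 - cfg$sex_ratio_female)
  manual <- 0
  for (s in c("female", "male")) {
    s_pos <- 1 - prod(vapply(cfg$indicator_rates, function(r) 1 - r$active[[s]], numeric(1)))
    f_pos <- 1 - prod(vapply(cfg$indicator_rates, function(r) 1 - r$inactive[[s]], numeric(1)))
    for (b in names(cfg$age_distribution)) {
      w <- w_sex[[s]] * cfg$age_distribution[[b]]
      pa <- cfg$p_active[s, b]
      manual <- manual + w * (pa * (1 - cfg$p_disclose[s, b]) * s_pos + (1 - pa) * f_pos)
    }
  }
  expect_equal(expected_identified_gap(cfg), 100 * manual, tolerance = 1e-12)
})

test_that("closed-form helpers refuse dependent-indicator configurations", {
  cfg <- small_config(indicator_dependence_sd = 0.5)
  expect_error(expected_identified_gap(cfg), class = "msap_config_error")
  expect_error(expected_indicator_prevalence(cfg, "HIV", "female"),
               class = "msap_config_error")
})

test_that("perfect indicators give recovery sensitivity exactly 1; null indicators give gap 0", {
  cfg_perfect <- small_config(indicator_rates = flat_indicator_rates(active = 1, inactive = 0),
                              p_selfreport_missing = 0, seed = 3)
  rec <- recovery_experiment(cfg_perfect, n_reps = 5)
  expect_true(all(rec$replicates$sensitivity_hidden == 1))
  expect_true(all(rec$replicates$false_id_rate == 0))

  cfg_null <- small_config(indicator_rates = flat_indicator_rates(active = 0, inactive = 0),
                           p_selfreport_missing = 0, seed = 4)
  rec0 <- recovery_experiment(cfg_null, n_reps = 5)
  expect_true(all(rec0$replicates$gap_percent == 0))
  expect_equal(rec0$expected_gap, 0)
})

test_that("the YAML configuration round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_clusters: 5",
    "cluster_size_mean: 30",
    "cluster_size_dispersion: 0",
    "seed: 7",
    "p_active:",
    "  female: {15_or_under: 0.1, 16_17: 0.2, 18_19: 0.3, 20_plus: 0.4}",
    "  male:   {15_or_under: 0.2, 16_17: 0.3, 18_19: 0.4, 20_plus: 0.5}",
    "indicator_rates:",
    "  HIV: {active: {female: 0.2, male: 0.05}}"
  ), path)
  cfg <- read_simulation_config(path)
  expect_identical(cfg$n_clusters, 5L)
  expect_equal(cfg$p_active["female", "16_17"], 0.2)
  expect_equal(cfg$indicator_rates$HIV$active[["female"]], 0.2)
  # untouched keys keep defaults
  expect_equal(cfg$indicator_rates$HSV2$active[["female"]], 0.21)
})

test_that("every transcribed margin is recoverable by recounting the fixture", {
  fx <- build_inpaper_fixture()
  recount <- fixture_margins(fx)
  constants <- msap:::fixture_margin_constants()
  joined <- dplyr::inner_join(recount, constants,
                              by = c("group", "sex", "variable"),
                              suffix = c("_recount", "_published"))
  expect_identical(nrow(joined), nrow(constants))
  expect_identical(joined$numerator_recount, as.integer(joined$numerator_published))
  expect_identical(joined$denominator_recount, as.integer(joined$denominator_published))
})

test_that("fixture composition matches the published cohort structure", {
  fx <- build_inpaper_fixture()
  expect_identical(nrow(fx), 2675L)
  expect_identical(sum(fx$sex == "female"), 1423L)
  expect_identical(sum(fx$sex == "male"), 1252L)
  expect_identical(sum(is.na(fx$self_report_active)), 30L)
  res <- classify_cohort(fx)
  newly <- res[res$status == "newly_identified", ]
  expect_identical(nrow(newly), 223L)
  expect_identical(sum(newly$sex == "female"), 148L)
  expect_identical(sum(newly$n_positive >= 2), 25L)
})
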