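# Run orchestration: simulate/classify/compare entry points and report
# integrity (every reported count re-derivable from the persisted results).

test_that("cmd_simulate writes reproducible cohort and truth files", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- small_config(seed = 5)
  suppressMessages(cmd_simulate(out1, config = cfg))
  suppressMessages(cmd_simulate(out2, config = cfg))
  expect_true(file.exists(file.path(out1, "cohort.csv")))
  expect_true(file.exists(file.path(out1, "cohort_truth.csv")))
  expect_identical(readLines(file.path(out1, "cohort.csv")),
                   readLines(file.path(out2, "cohort.csv")))
  log <- jsonlite::fromJSON(file.path(out1, "simulate_log.json"))
  expect_identical(log$seed, 5L)
})

test_that("cmd_simulate surfaces configuration errors with the key named", {
  out <- withr::local_tempdir()
  expect_error(cmd_simulate(out, config = small_config(p_overreport = 1.2)),
               "p_overreport", class = "msap_config_error")
})

test_that("simulated cohort size tracks clusters x mean size", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(n_clusters = 14, cluster_size_mean = 200,
                           cluster_size_dispersion = 0, seed = 6)
  suppressMessages(cmd_simulate(out, config = cfg))
  cohort <- read_cohort(file.path(out, "cohort.csv"))
  expect_identical(nrow(cohort), 2800L)
  expect_identical(length(unique(cohort$cluster_id)), 14L)
})

test_that("cmd_classify reports the published fixture percentages and recountable results", {
  dir <- withr::local_tempdir()
  cohort_path <- file.path(dir, "fixture.csv")
  write_cohort(build_inpaper_fixture(), cohort_path)
  suppressMessages(cmd_classify(cohort_path, dir))
  report <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(round(report$classification$self_report_percent, 1), 40.3)
  expect_equal(round(report$classification$msap_percent, 1), 48.7)
  expect_identical(report$input$n_records, 2675L)

  # every count re-derivable from the persisted per-student results
  results <- readr::read_csv(file.path(dir, "results.csv"), show_col_types = FALSE)
  recount <- table(results$status)
  expect_identical(unname(recount[["newly_identified"]]),
                   report$classification$status_counts$newly_identified)
  expect_identical(unname(recount[["self_reported_active"]]),
                   report$classification$status_counts$self_reported_active)
  att <- report$attribution
  expect_identical(sum(att$n), unname(recount[["newly_identified"]]))
  # synthetic round-robin clusters are flagged
  expect_true(any(grepl("synthetic", report$warnings)))
})

test_that("an all-yes cohort reports MSAP% equal to self-report% of 100", {
  dir <- withr::local_tempdir()
  cohort <- random_cohort(n = 30, seed = 10)
  cohort$self_report_active <- "yes"
  path <- file.path(dir, "cohort.csv")
  write_cohort(as_cohort(cohort), path)
  suppressMessages(cmd_classify(path, dir))
  report <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(report$classification$self_report_percent, 100)
  expect_equal(report$classification$msap_percent, 100)
})

test_that("cmd_compare emits one row per contrast and propagates inference errors", {
  dir <- withr::local_tempdir()
  suppressMessages(cmd_simulate(dir, config = small_config(seed = 8)))
  cohort_path <- file.path(dir, "cohort.csv")
  suppressMessages(cmd_classify(cohort_path, dir))
  contrasts <- list(
    list(variable = 'sex == "female"',
         group_a = 'status == "newly_identified"',
         group_b = 'status == "self_reported_active"',
         label_a = "newly", label_b = "self-report"),
    list(variable = 'risk_perception == "high"',
         group_a = 'status == "newly_identified"',
         group_b = 'status == "self_reported_active"')
  )
  out <- suppressMessages(
    cmd_compare(cohort_path, file.path(dir, "results.csv"), contrasts, dir)
  )
  expect_identical(nrow(out), 2L)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_true(file.exists(file.path(dir, "comparisons.csv")))

  # single-cluster cohort: the cluster-summary test is undefined
  one <- random_cohort(n = 40, seed = 11, n_clusters = 1)
  one_path <- file.path(dir, "one.csv")
  write_cohort(one, one_path)
  suppressMessages(cmd_classify(one_path, file.path(dir, "one_out")))
  expect_error(
    suppressMessages(cmd_compare(one_path, file.path(dir, "one_out", "results.csv"),
                                 contrasts[1], dir)),
    class = "msap_inference_error"
  )
})
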