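test_that("run counts scale with the cohort", {
  rs <- suppressWarnings(run_experiment(run_config(n = 1, seed = 2)))
  expect_equal(rs$n_patients, 1)
  expect_equal(rs$n_models, 3)
  expect_equal(rs$n_simulations_attempted, 12)
  expect_equal(nrow(rs$results), 12 * 6)
})

test_that("runs are reproducible from the persisted configuration", {
  cfg <- run_config(n = 3, seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  a <- suppressWarnings(run_experiment(cfg))
  b <- suppressWarnings(run_experiment(cfg2))
  expect_equal(a$results$compression_N, b$results$compression_N, tolerance = 1e-6)
  expect_identical(a$cohort, b$cohort)
})

test_that("load summaries reproduce order statistics", {
  rs <- smoke_run()
  tab <- summarize_loads(rs$results)
  expect_setequal(names(tab), c("load_case", "config", "level", "response",
                                "count", "mean", "std", "min", "p25", "p50",
                                "p75", "max"))
  # independent check for one group by direct sorting
  sub <- rs$results[rs$results$config == "Indiv" & rs$results$level == "L4/L5" &
                      rs$results$load_case == "neutral" & rs$results$feasible, ]
  row <- tab[tab$config == "Indiv" & tab$level == "L4/L5" &
               tab$load_case == "neutral" & tab$response == "compression", ]
  v <- sort(sub$compression_N)
  expect_equal(row$count, length(v))
  expect_equal(row$mean, mean(v), tolerance = 1e-12)
  expect_equal(row$min, v[1]); expect_equal(row$max, v[length(v)])
  expect_equal(row$p50, median(v), tolerance = 1e-12)
  expect_equal(row$p25, unname(quantile(v, 0.25)), tolerance = 1e-12)

  const <- data.frame(patient_id = "p", config = "Indiv", load_case = "neutral",
                      level = "L4/L5", compression_N = 7, shear_AP_N = -1,
                      feasible = TRUE)[rep(1, 5), ]
  tc <- summarize_loads(const)
  expect_true(all(tc$std == 0))
  expect_true(all(tc[tc$response == "compression",
                     c("mean", "min", "p25", "p50", "p75", "max")] == 7))
})

test_that("configuration comparison pairs patients and subtracts values", {
  rs <- smoke_run()
  cmp <- compare_configurations(rs$results)
  expect_equal(cmp$compression_d_uniSpine,
               cmp$compression_uniSpine - cmp$compression_Indiv, tolerance = 1e-12)
  expect_equal(cmp$shear_AP_d_uniTorso,
               cmp$shear_AP_uniTorso - cmp$shear_AP_Indiv, tolerance = 1e-12)
  feas <- rs$results[rs$results$feasible, ]
  min_feas <- min(table(feas$config)) / length(spineload:::JOINT_LEVELS)
  expect_lte(nrow(cmp) / length(spineload:::JOINT_LEVELS), min_feas)

  # a patient matching the uniform spine yields near-identical uniSpine loads
  uni_rec <- data.frame(patient_id = "U", TK = 29, LL = 44, TH = 0.45,
                        TW = 23.3, CoM_AP = 0.03, CoM_SI = 0.21)
  class(uni_rec) <- c("spine_cohort", "data.frame")
  ru <- suppressWarnings(run_experiment(run_config(n = 1, seed = 3), cohort = uni_rec))
  cu <- compare_configurations(ru$results)
  expect_lt(max(abs(cu$compression_d_uniSpine)), 1e-6)
})

test_that("run outputs are written as CSV tables", {
  rs <- smoke_run()
  dir <- withr::local_tempdir()
  write_run_outputs(rs, dir)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "results.csv",
                                               "descriptives.csv",
                                               "regressions.csv", "run_log.csv",
                                               "embedding.csv", "config.yaml")))))
  logtab <- read.csv(file.path(dir, "run_log.csv"))
  expect_equal(nrow(logtab), rs$n_simulations_attempted)
  expect_true(all(logtab$status %in% c("optimal", "infeasible")))
  back <- read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(back), nrow(rs$results))
})
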