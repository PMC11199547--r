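test_that("cohort sampling is deterministic, validated, and handles n = 0", {
  expect_equal(nrow(sample_cohort(0)), 0L)
  a <- sample_cohort(25, seed = 11)
  b <- sample_cohort(25, seed = 11)
  expect_identical(a, b)
  c <- sample_cohort(25, seed = 12)
  expect_false(identical(a, c))
  expect_true(all(spineload:::valid_morphology(a)))
  expect_error(cohort_stats(sd_TW = -1), "non-negative")
  expect_error(cohort_stats(corr_LL_TK = 1), "corr")
  expect_error(sample_cohort(-1), "non-negative")
})

test_that("large-sample moments match the target statistics", {
  st <- cohort_stats()
  co <- sample_cohort(10000, seed = 5, stats = st)
  for (nm in names(st$means)) {
    se <- st$sds[[nm]] / sqrt(10000)
    expect_lt(abs(mean(co[[nm]]) - st$means[[nm]]), 3 * se + 1e-12)
  }
  expect_lt(abs(cor(co$LL, co$TK) - 0.4), 0.05)
  # uncorrelated pairs stay near zero
  expect_lt(abs(cor(co$TW, co$LL)), 0.05)
})

test_that("study-size cohort recovers the mean torso weight", {
  co <- sample_cohort(93, seed = 1)
  se <- 5.9 / sqrt(93)
  expect_lt(abs(mean(co$TW) - 25.1), 2 * se)
})

test_that("alignment regression recovers the configured LL-TK association", {
  co <- sample_cohort(10000, seed = 3)
  fit <- cohort_alignment_regression(co)
  expect_lt(abs(fit$slope_std - 0.4), 0.05)
  expect_lt(abs(fit$r_squared - 0.16), 0.04)
  expect_equal(fit$r_squared, fit$slope_std^2, tolerance = 1e-12)

  ident <- data.frame(TK = co$LL[1:50], LL = co$LL[1:50])
  fit2 <- cohort_alignment_regression(ident)
  expect_equal(fit2$slope_std, 1, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  co0 <- sample_cohort(5000, seed = 4, stats = cohort_stats(corr_LL_TK = 0))
  expect_lt(abs(cohort_alignment_regression(co0)$slope_std), 0.05)

  degen <- data.frame(TK = rnorm(10), LL = rep(1, 10))
  expect_true(cohort_alignment_regression(degen)$degenerate)
  expect_error(cohort_alignment_regression(co[1:2, ]), "at least 3")
})

test_that("segment mass profiles conserve mass and aggregate centre of mass", {
  co <- sample_cohort(12, seed = 9)
  for (i in seq_len(nrow(co))) {
    rec <- co[i, ]
    geom <- build_sagittal_curve(rec$TK, rec$LL, rec$TH)
    prof <- derive_segment_masses(rec, geometry = geom)
    expect_lt(abs(sum(prof$mass_kg) - rec$TW), 1e-9)
    # independent mass-weighted summation in the L5 frame
    lv <- geom$levels
    l5 <- lv[lv$level == "L5", ]
    ap <- sum(prof$mass_kg * (lv$cx - l5$cx + prof$off_ap)) / rec$TW
    si <- sum(prof$mass_kg * (lv$cy - l5$cy + prof$off_si)) / rec$TW
    expect_lt(abs(ap - rec$CoM_AP), 1e-6)
    expect_lt(abs(si - rec$CoM_SI), 1e-6)
    expect_true(attr(prof, "feasible"))
  }
})

test_that("degenerate and infeasible profiles are handled explicitly", {
  rec <- ref_record()
  rec$TW <- 0
  geom <- build_sagittal_curve(rec$TK, rec$LL, rec$TH)
  prof <- derive_segment_masses(rec, geometry = geom)
  expect_true(all(prof$mass_kg == 0))

  far <- ref_record()
  far$CoM_AP <- 0.5  # far outside any anatomical band
  expect_warning(p2 <- derive_segment_masses(far), "anatomical band")
  expect_false(attr(p2, "feasible"))

  bad <- default_mass_template()
  bad$w[1] <- bad$w[1] + 0.1
  expect_error(derive_segment_masses(ref_record(), template = bad), "sum to 1")
})

test_that("cohort CSV round-trips through the documented header", {
  co <- sample_cohort(6, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(hdr, c("patient_id", "TK_deg", "LL_deg", "TH_m", "TW_kg",
                          "CoM_AP_m", "CoM_SI_m"))
  back <- read_cohort_csv(path)
  expect_equal(back$TW, co$TW, tolerance = 1e-12)
  expect_identical(back$patient_id, co$patient_id)
})
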