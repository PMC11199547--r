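test_that("a perfectly explained response gives beta 1, R2 1", {
  set.seed(18)
  x <- rnorm(40)
  fit <- standardized_regression(data.frame(x1 = x), (x - mean(x)) / sd(x))
  expect_equal(fit$coefficients$beta, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$coefficients$p, 1e-12)
  expect_equal(fit$coefficients$stars, "***")
})

test_that("standardized OLS equals the normal-equations closed form", {
  set.seed(23)
  for (trial in 1:5) {
    X <- as.data.frame(matrix(rnorm(20 * 3), 20, 3))
    y <- rnorm(20)
    fit <- standardized_regression(X, y)
    Z <- cbind(1, scale(as.matrix(X)))
    zy <- as.numeric(scale(y))
    beta_cf <- solve(t(Z) %*% Z, t(Z) %*% zy)
    expect_equal(fit$coefficients$beta, as.numeric(beta_cf[-1]), tolerance = 1e-10)
    pred <- Z %*% beta_cf
    expect_equal(fit$r_squared, 1 - sum((zy - pred)^2) / sum(zy^2), tolerance = 1e-10)
    # residual-based standard errors from the closed form
    s2 <- sum((zy - pred)^2) / (20 - 3 - 1)
    se_cf <- sqrt(diag(solve(t(Z) %*% Z)) * s2)[-1]
    expect_equal(fit$coefficients$se, as.numeric(se_cf), tolerance = 1e-10)
  }
})

test_that("an unrelated response yields small effects and near-zero R2", {
  set.seed(29)
  X <- as.data.frame(matrix(rnorm(2000 * 3), 2000, 3))
  y <- rnorm(2000)
  fit <- standardized_regression(X, y)
  expect_true(all(abs(fit$coefficients$beta) < 0.08))
  expect_lt(fit$r_squared, 0.01)
})

test_that("rank-deficient designs are flagged, not silently fitted", {
  X <- data.frame(a = 1:20, b = (1:20) * 2)
  fit <- standardized_regression(X, rnorm(20))
  expect_true(fit$rank_deficient)
  expect_true(all(is.na(fit$coefficients$beta)))
  expect_true(standardized_regression(data.frame(a = rep(1, 20)),
                                      rnorm(20))$rank_deficient)
  expect_error(standardized_regression(data.frame(a = 1:4, b = rnorm(4), c = rnorm(4)),
               rnorm(4)), "n >")
})

test_that("the regression battery covers every cell with its predictor set", {
  rs <- smoke_run()
  reg <- run_regressions(rs$results, rs$cohort)
  cells <- unique(reg[, c("response", "level", "load_case", "config")])
  expect_equal(nrow(cells), 2 * 6 * 4 * 3)
  ut <- reg[reg$config == "uniTorso", ]
  expect_setequal(unique(ut$predictor), c("TK", "LL", "TH"))
  us <- reg[reg$config == "uniSpine", ]
  expect_setequal(unique(us$predictor), c("TW", "CoM_AP", "CoM_SI"))
  iv <- reg[reg$config == "Indiv", ]
  expect_setequal(unique(iv$predictor),
                  c("TK", "LL", "TH", "TW", "CoM_AP", "CoM_SI"))
  expect_true(all(reg$r2 >= 0 & reg$r2 <= 1, na.rm = TRUE))
  expect_true(all(reg$n_used <= 10))
})

test_that("torso weight drives uniSpine compression at every load case", {
  rs <- full_run()
  reg <- run_regressions(rs$results, rs$cohort)
  tw <- reg[reg$config == "uniSpine" & reg$level == "L4/L5" &
              reg$response == "compression" & reg$predictor == "TW", ]
  expect_equal(nrow(tw), 4)
  expect_true(all(tw$beta > 0))
  expect_true(all(tw$p < 0.001))
})
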