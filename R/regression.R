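# Standardized multiple regression of lumbar loads on morphology.

# Predictor subsets per model configuration: only the individualized
# parameters enter the regression for a given configuration.
CONFIG_PREDICTORS <- list(
  Indiv    = c("TK", "LL", "TH", "TW", "CoM_AP", "CoM_SI"),
  uniTorso = c("TK", "LL", "TH"),
  uniSpine = c("TW", "CoM_AP", "CoM_SI")
)

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Standardized ordinary least squares
#'
#' Centers and z-scores the predictors and the response, fits OLS, and
#' reports standardized coefficients (effect strengths), standard errors,
#' two-sided p-values from the t distribution with n - k - 1 degrees of
#' freedom, significance stars at 0.05/0.01/0.001, and R^2.
#'
#' @param X data frame or matrix of predictors.
#' @param y numeric response.
#' @return List: \code{coefficients} data frame (\code{predictor, beta,
#'   se, p, stars}), \code{r_squared}, \code{n}, \code{rank_deficient}.
#' @export
standardized_regression <- function(X, y) {
  X <- as.data.frame(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("need n > number of predictors + 1")
  sds <- vapply(X, stats::sd, numeric(1))
  if (stats::sd(y) == 0 || any(sds == 0)) {
    return(list(coefficients = data.frame(predictor = names(X), beta = NA_real_,
                                          se = NA_real_, p = NA_real_, stars = NA_character_),
                r_squared = NA_real_, n = n, rank_deficient = TRUE))
  }
  Z <- as.data.frame(lapply(X, function(v) (v - mean(v)) / stats::sd(v)))
  zy <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm(zy ~ ., data = cbind(zy = zy, Z))
  if (any(is.na(stats::coef(fit)))) {
    return(list(coefficients = data.frame(predictor = names(X), beta = NA_real_,
                                          se = NA_real_, p = NA_real_, stars = NA_character_),
                r_squared = NA_real_, n = n, rank_deficient = TRUE))
  }
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  list(coefficients = data.frame(predictor = names(X),
                                 beta = unname(co[, 1]),
                                 se = unname(co[, 2]),
                                 p = unname(co[, 4]),
                                 stars = p_stars(unname(co[, 4])),
                                 stringsAsFactors = FALSE),
       r_squared = sm$r.squared, n = n, rank_deficient = FALSE)
}

#' Run the full regression battery
#'
#' One standardized multiple regression per (response x level x load case
#' x configuration) cell: 2 responses x 6 levels x 4 load cases x 3
#' configurations = 144 cells. Predictor sets follow the configuration
#' (all six morphology parameters for Indiv, TK/LL/TH for uniTorso,
#' TW/CoM_AP/CoM_SI for uniSpine). Infeasible simulations are dropped per
#' cell and counted in \code{n_used}.
#'
#' @param results simulation results table with columns \code{patient_id,
#'   config, load_case, level, compression_N, shear_AP_N, feasible}.
#' @param cohort the morphology cohort the simulations were run on.
#' @return Data frame with one row per (cell x predictor): \code{response,
#'   level, load_case, config, predictor, beta, se, p, stars, r2, n_used}.
#' @export
run_regressions <- function(results, cohort) {
  out <- list()
  cases <- unique(results$load_case)
  for (config in names(CONFIG_PREDICTORS)) {
    preds <- CONFIG_PREDICTORS[[config]]
    for (lvl in JOINT_LEVELS) {
      for (cs in cases) {
        sub <- results[results$config == config & results$level == lvl &
                         results$load_case == cs & results$feasible, ]
        sub <- merge(sub, cohort, by = "patient_id")
        for (resp in c("compression", "shear_AP")) {
          ycol <- paste0(resp, "_N")
          cell <- data.frame(response = resp, level = lvl, load_case = cs,
                             config = config, predictor = preds,
                             beta = NA_real_, se = NA_real_, p = NA_real_,
                             stars = NA_character_, r2 = NA_real_,
                             n_used = nrow(sub), stringsAsFactors = FALSE)
          if (nrow(sub) > length(preds) + 1) {
            fit <- standardized_regression(sub[, preds, drop = FALSE], sub[[ycol]])
            if (!fit$rank_deficient) {
              cell$beta <- fit$coefficients$beta
              cell$se <- fit$coefficients$se
              cell$p <- fit$coefficients$p
              cell$stars <- fit$coefficients$stars
              cell$r2 <- fit$r_squared
            }
          }
          out[[length(out) + 1]] <- cell
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
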