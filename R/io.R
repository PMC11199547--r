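# File interfaces: cohort CSV, result tables, YAML/JSON configuration.

COHORT_CSV_HEADER <- c("patient_id", "TK_deg", "LL_deg", "TH_m", "TW_kg",
                       "CoM_AP_m", "CoM_SI_m")

#' Write a cohort to CSV
#' @param cohort a \code{spine_cohort} data frame.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(patient_id = cohort$patient_id, TK_deg = cohort$TK,
                    LL_deg = cohort$LL, TH_m = cohort$TH, TW_kg = cohort$TW,
                    CoM_AP_m = cohort$CoM_AP, CoM_SI_m = cohort$CoM_SI)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a user-supplied cohort from CSV
#'
#' Accepts the same format \code{\link{write_cohort_csv}} produces:
#' header \code{patient_id,TK_deg,LL_deg,TH_m,TW_kg,CoM_AP_m,CoM_SI_m}.
#' Records are validated against the morphology ranges.
#'
#' @param path CSV file.
#' @return A \code{spine_cohort} data frame.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(COHORT_CSV_HEADER %in% names(raw))) {
    stop("cohort CSV must have header: ", paste(COHORT_CSV_HEADER, collapse = ","))
  }
  out <- data.frame(patient_id = as.character(raw$patient_id),
                    TK = raw$TK_deg, LL = raw$LL_deg, TH = raw$TH_m,
                    TW = raw$TW_kg, CoM_AP = raw$CoM_AP_m, CoM_SI = raw$CoM_SI_m,
                    stringsAsFactors = FALSE)
  if (!all(valid_morphology(out))) stop("cohort CSV contains invalid morphology records")
  class(out) <- c("spine_cohort", "data.frame")
  out
}

#' Write all run outputs as CSV
#'
#' Cohort, per-simulation load results, descriptive statistics, regression
#' table, per-simulation solver log, 2-D embedding coordinates and the
#' resolved configuration (YAML) into one directory.
#'
#' @param summary a \code{run_summary}.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run_outputs <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(summary$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(summary$results, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(summarize_loads(summary$results),
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  utils::write.csv(run_regressions(summary$results, summary$cohort),
                   file.path(dir, "regressions.csv"), row.names = FALSE)
  utils::write.csv(summary$log, file.path(dir, "run_log.csv"), row.names = FALSE)
  lmat <- build_load_matrix(summary$results)
  perp <- min(30, floor((nrow(lmat) - 1) / 3))
  emb <- embed_2d(minmax_scale_signed(lmat), perplexity = perp,
                  seed = summary$config$seed, n_iter = 300)
  emb$row_id <- seq_len(nrow(emb))
  utils::write.csv(emb[, c("row_id", "dim1", "dim2", "load_case", "config")],
                   file.path(dir, "embedding.csv"), row.names = FALSE)
  write_run_config(summary$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Persist a run configuration as YAML
#' @param config a \code{\link{run_config}}.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    n = config$n, seed = config$seed,
    stats = list(means = as.list(config$stats$means),
                 sds = as.list(config$stats$sds),
                 corr_LL_TK = config$stats$corr_LL_TK),
    defaults = config$defaults[setdiff(names(config$defaults), "mass_template")],
    mass_template = as.list(config$defaults$mass_template),
    solver = unclass(config$solver),
    load_cases = vapply(config$load_cases, function(c) c$name, character(1)),
    configs = config$configs
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by \code{\link{write_run_config}} (or
#'   hand-edited with the same fields; missing fields fall back to
#'   defaults).
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- if (is.null(y$stats)) cohort_stats() else {
    m <- y$stats$means; s <- y$stats$sds
    cohort_stats(m$TK, s$TK, m$LL, s$LL, m$TH, s$TH, m$TW, s$TW,
                 m$CoM_AP, s$CoM_AP, m$CoM_SI, s$CoM_SI, y$stats$corr_LL_TK)
  }
  defaults <- model_defaults()
  for (nm in intersect(names(y$defaults), names(defaults))) defaults[[nm]] <- y$defaults[[nm]]
  if (!is.null(y$mass_template)) defaults$mass_template <- as.data.frame(y$mass_template)
  solver <- solver_settings()
  if (!is.null(y$solver)) {
    ys <- y$solver
    solver <- solver_settings(
      sigma_max_pa = ys$sigma_max_pa %||% 1e6,
      gravity_ms2 = ys$gravity_ms2 %||% 9.81,
      k1 = ys$k1 %||% 0.3, k3 = ys$k3 %||% 0.001,
      tol = ys$tol %||% 1e-6, feas_tol = ys$feas_tol %||% 1e-3,
      constraint_mode = ys$constraint_mode %||% "equality",
      balance_band_m = ys$balance_band_m %||% 0.005)
  }
  cases <- if (is.null(y$load_cases)) default_load_cases() else {
    stats::setNames(lapply(y$load_cases, load_case), y$load_cases)
  }
  run_config(n = y$n %||% 93, seed = y$seed %||% 1, stats = st,
             defaults = defaults, solver = solver, load_cases = cases,
             configs = y$configs %||% c("Indiv", "uniSpine", "uniTorso"))
}
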