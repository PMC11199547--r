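# Experiment orchestration: cohort -> 3 x n models -> 4 load cases ->
# load tables -> statistics.

#' Experiment configuration
#'
#' @param n cohort size (default: the study scale of 93 patients).
#' @param seed master seed; all randomness (cohort sampling, embedding
#'   initialization) flows from it.
#' @param stats \code{\link{cohort_stats}}.
#' @param defaults \code{\link{model_defaults}}.
#' @param solver \code{\link{solver_settings}}.
#' @param load_cases list of \code{\link{load_case}} objects.
#' @param configs configurations to run.
#' @param muscle_table muscle parameter table.
#' @param out_dir optional output directory for CSV tables.
#' @param smoke when TRUE, run a reduced 8-patient cohort.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(n = 93, seed = 1, stats = cohort_stats(),
                       defaults = model_defaults(),
                       solver = solver_settings(),
                       load_cases = default_load_cases(),
                       configs = c("Indiv", "uniSpine", "uniTorso"),
                       muscle_table = NULL, out_dir = NULL, smoke = FALSE) {
  if (smoke) n <- 8
  structure(list(n = n, seed = seed, stats = stats, defaults = defaults,
                 solver = solver, load_cases = load_cases, configs = configs,
                 muscle_table = muscle_table, out_dir = out_dir),
            class = "run_config")
}

#' Run the full experiment
#'
#' Samples the synthetic cohort, builds the three model configurations per
#' patient, simulates every load case on every model, and returns the
#' result tables and a run summary. A single infeasible static
#' optimization is counted and excluded but never aborts the run.
#'
#' @param config a \code{\link{run_config}}.
#' @param cohort optional pre-built cohort (e.g. read from CSV); when NULL
#'   a cohort of size \code{config$n} is sampled.
#' @param progress print per-patient progress.
#' @return Object of class \code{run_summary}: counts (patients, models,
#'   attempted and succeeded simulations per configuration and load case)
#'   and the tables \code{cohort} and \code{results}.
#' @export
run_experiment <- function(config = run_config(), cohort = NULL, progress = FALSE) {
  if (is.null(cohort)) cohort <- sample_cohort(config$n, config$seed, config$stats)
  muscle_table <- config$muscle_table %||% default_muscle_table()
  rows <- vector("list", nrow(cohort) * length(config$configs) * length(config$load_cases))
  logs <- vector("list", length(rows))
  ri <- 0
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    profile <- derive_segment_masses(rec, template = config$defaults$mass_template)
    for (mode in config$configs) {
      model <- assemble_model(rec, profile = profile, config = model_config(mode),
                              muscle_table = muscle_table, defaults = config$defaults)
      tilt <- neutral_balance(model, band_m = config$solver$balance_band_m)$tilt_deg
      for (cs in config$load_cases) {
        sim <- simulate_case(model, cs, settings = config$solver, base_tilt_deg = tilt)
        r <- sim$results
        r$patient_id <- rec$patient_id
        r$config <- mode
        r$load_case <- cs$name
        ri <- ri + 1
        rows[[ri]] <- r[, c("patient_id", "config", "load_case", "level",
                            "compression_N", "shear_AP_N", "feasible")]
        logs[[ri]] <- data.frame(
          patient_id = rec$patient_id, config = mode, load_case = cs$name,
          status = sim$solution$status,
          residual_Nm = sim$solution$residual,
          balance_tilt_deg = tilt,
          reason = if (sim$solution$status == "optimal") "" else
            "demand exceeds muscle capacity at the stress bound",
          stringsAsFactors = FALSE)
      }
    }
    if (progress) message(sprintf("patient %d/%d done", i, nrow(cohort)))
  }
  results <- do.call(rbind, rows[seq_len(ri)])
  rownames(results) <- NULL
  per_case <- stats::aggregate(feasible ~ config + load_case, data = results,
                               FUN = function(f) sum(f) / length(JOINT_LEVELS))
  names(per_case)[3] <- "succeeded"
  per_case$attempted <- nrow(cohort)
  summary <- structure(list(
    n_patients = nrow(cohort),
    n_models = length(config$configs) * nrow(cohort),
    n_simulations_attempted = length(config$configs) * length(config$load_cases) * nrow(cohort),
    n_simulations_succeeded = sum(per_case$succeeded),
    per_case = per_case,
    cohort = cohort,
    results = results,
    log = do.call(rbind, logs[seq_len(ri)]),
    config = config
  ), class = "run_summary")
  if (!is.null(config$out_dir)) write_run_outputs(summary, config$out_dir)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Run: %d patients, %d models, %d simulations attempted, %d feasible\n",
              x$n_patients, x$n_models, x$n_simulations_attempted,
              x$n_simulations_succeeded))
  print(x$per_case)
  invisible(x)
}

#' Descriptive statistics of simulated loads
#'
#' Per (load case, configuration, level, response): count of feasible
#' solves, mean, SD, min, quartiles and max, mirroring the layout of the
#' study's descriptive table.
#'
#' @param results simulation results table.
#' @param levels levels to include (default all six).
#' @return Long data frame with one row per group and response.
#' @export
summarize_loads <- function(results, levels = JOINT_LEVELS) {
  r <- results[results$feasible & results$level %in% levels, ]
  out <- list()
  for (resp in c("compression", "shear_AP")) {
    v <- r[[paste0(resp, "_N")]]
    key <- list(load_case = r$load_case, config = r$config, level = r$level)
    agg <- stats::aggregate(v, by = key, FUN = function(z) {
      c(count = length(z), mean = mean(z), std = stats::sd(z), min = min(z),
        p25 = unname(stats::quantile(z, 0.25)), p50 = unname(stats::median(z)),
        p75 = unname(stats::quantile(z, 0.75)), max = max(z))
    })
    stats_df <- as.data.frame(agg$x)
    agg$x <- NULL
    agg$response <- resp
    out[[resp]] <- cbind(agg, stats_df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair simulated loads across configurations
#'
#' Per (patient, load case, level) the values from all three
#' configurations plus differences to the fully individualized model;
#' rows with an infeasible member are dropped and counted.
#'
#' @param results simulation results table covering all configurations.
#' @return Wide data frame with value and difference columns for both
#'   responses; the number of dropped rows is in attribute
#'   \code{n_dropped}.
#' @export
compare_configurations <- function(results) {
  r <- results
  ids <- unique(r[, c("patient_id", "load_case", "level")])
  take <- function(cfg, col) {
    sub <- r[r$config == cfg, ]
    i <- match(paste(ids$patient_id, ids$load_case, ids$level),
               paste(sub$patient_id, sub$load_case, sub$level))
    ifelse(sub$feasible[i], sub[[col]][i], NA_real_)
  }
  out <- ids
  for (col in c("compression_N", "shear_AP_N")) {
    short <- sub("_N$", "", col)
    out[[paste0(short, "_Indiv")]] <- take("Indiv", col)
    out[[paste0(short, "_uniSpine")]] <- take("uniSpine", col)
    out[[paste0(short, "_uniTorso")]] <- take("uniTorso", col)
    out[[paste0(short, "_d_uniSpine")]] <-
      out[[paste0(short, "_uniSpine")]] - out[[paste0(short, "_Indiv")]]
    out[[paste0(short, "_d_uniTorso")]] <-
      out[[paste0(short, "_uniTorso")]] - out[[paste0(short, "_Indiv")]]
  }
  complete <- stats::complete.cases(out)
  res <- out[complete, ]
  rownames(res) <- NULL
  structure(res, n_dropped = sum(!complete))
}
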