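# Trunk model assembly under three individualization configurations.

UNIFORM_SPINE <- list(TK = 29, LL = 44, TH = 0.45)
UNIFORM_TORSO <- list(TW = 23.3, CoM_AP = 0.03, CoM_SI = 0.21)

#' Model configuration
#'
#' @param mode \code{"Indiv"} (individualized spine and torso),
#'   \code{"uniSpine"} (uniform spine TK 29 deg, LL 44 deg, TH 0.45 m —
#'   the average healthy spine — with the individual torso), or
#'   \code{"uniTorso"} (individual spine with a uniform 23.3 kg torso with
#'   fixed per-level distribution and segment centre-of-mass offsets).
#' @param uniform_spine,uniform_torso overrides for the uniform parameter
#'   sets; the defaults are the study's reference values.
#' @return Object of class \code{model_config}.
#' @export
model_config <- function(mode = c("Indiv", "uniSpine", "uniTorso"),
                         uniform_spine = UNIFORM_SPINE,
                         uniform_torso = UNIFORM_TORSO) {
  mode <- match.arg(mode)
  structure(list(mode = mode, uniform_spine = uniform_spine,
                 uniform_torso = uniform_torso),
            class = "model_config")
}

#' Generic model defaults
#'
#' Appendage masses and positions not individualized from imaging:
#' head-neck (5.0 kg, centred above T1) and two arm cylinders (3.5 kg
#' each) attached at T3, hanging slightly anterior in unloaded postures.
#' During lifting tasks the arm centre of mass is repositioned to the hand
#' lever. Offsets are metres in the local (unposed) frame of the thoracic
#' block.
#'
#' @param head_mass_kg,head_ap_m,head_si_m head-neck point mass and offset
#'   from the T1 centre.
#' @param arm_mass_kg mass of one arm.
#' @param arm_ap_m,arm_si_m arm centre-of-mass offset from T3 when hanging.
#' @param mass_template per-level torso allocation template.
#' @return List of defaults consumed by \code{\link{assemble_model}}.
#' @export
model_defaults <- function(head_mass_kg = 5.0, head_ap_m = 0.04, head_si_m = 0.22,
                           arm_mass_kg = 3.5, arm_ap_m = 0.08, arm_si_m = -0.10,
                           mass_template = default_mass_template()) {
  list(head_mass_kg = head_mass_kg, head_ap_m = head_ap_m, head_si_m = head_si_m,
       arm_mass_kg = arm_mass_kg, arm_ap_m = arm_ap_m, arm_si_m = arm_si_m,
       mass_template = mass_template)
}

uniform_record <- function(config) {
  c(list(patient_id = "uniform"), config$uniform_spine, config$uniform_torso)
}

#' Assemble a posed-neutral trunk model for one patient
#'
#' Combines spine geometry, segment mass profile, generic appendages and
#' the generic muscle set according to the configuration: \code{Indiv}
#' uses the record's spine and torso, \code{uniSpine} substitutes the
#' uniform spine geometry (shared across the cohort), and \code{uniTorso}
#' substitutes the uniform segment mass profile (masses and segment
#' centre-of-mass offsets derived once from the uniform torso parameters).
#'
#' @param record one cohort row.
#' @param profile the record's \code{segment_mass_profile}; if NULL it is
#'   derived from the record. Ignored under \code{uniTorso}.
#' @param config a \code{\link{model_config}}.
#' @param muscle_table muscle parameter table.
#' @param defaults generic parameters from \code{\link{model_defaults}}.
#' @return Object of class \code{trunk_model}.
#' @export
assemble_model <- function(record, profile = NULL,
                           config = model_config("Indiv"),
                           muscle_table = default_muscle_table(),
                           defaults = model_defaults()) {
  if (!inherits(config, "model_config")) stop("config must be a model_config")
  record <- as.list(record)
  if (config$mode %in% c("Indiv", "uniTorso")) {
    geometry <- build_sagittal_curve(record$TK, record$LL, record$TH)
  } else {
    us <- config$uniform_spine
    geometry <- build_sagittal_curve(us$TK, us$LL, us$TH)
  }
  if (config$mode == "uniTorso") {
    ur <- uniform_record(config)
    ugeom <- build_sagittal_curve(ur$TK, ur$LL, ur$TH)
    profile <- derive_segment_masses(ur, template = defaults$mass_template,
                                     geometry = ugeom)
  } else if (is.null(profile)) {
    pg <- if (config$mode == "Indiv") geometry else
      build_sagittal_curve(record$TK, record$LL, record$TH)
    profile <- derive_segment_masses(record, template = defaults$mass_template,
                                     geometry = pg)
  }
  fascicles <- attach_muscles(geometry, muscle_table)
  structure(list(patient_id = record$patient_id %||% NA_character_,
                 config = config$mode,
                 record = record,
                 geometry = geometry,
                 profile = profile,
                 fascicles = fascicles,
                 defaults = defaults),
            class = "trunk_model")
}

#' @export
print.trunk_model <- function(x, ...) {
  cat(sprintf("Trunk model [%s] patient %s: TW(profile) %.1f kg, %d fascicles\n",
              x$config, x$patient_id, sum(x$profile$mass_kg), nrow(x$fascicles)))
  invisible(x)
}

#' Total suspended weight of a model
#'
#' Torso segment masses plus head-neck and both arms (kilograms), before
#' any external load is applied.
#' @param model a \code{trunk_model}.
#' @return Mass in kilograms.
#' @export
model_total_mass <- function(model) {
  sum(model$profile$mass_kg) + model$defaults$head_mass_kg +
    2 * model$defaults$arm_mass_kg
}

#' Serialize a trunk model to JSON (debugging aid)
#' @param model a \code{trunk_model}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- unclass(model)
  x$geometry <- unclass(x$geometry)
  x$profile <- as.data.frame(x$profile)
  js <- jsonlite::toJSON(x, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
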