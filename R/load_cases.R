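# Static load cases and the flexion partition.

# Fraction of total trunk flexion taken by the sacral base and by the
# lumbar joints, and the per-joint split of the lumbar share.
SACRAL_FRACTION <- 0.4
LUMBAR_FRACTION <- 0.6
LUMBAR_PARTITION <- c("L1/L2" = 0.255, "L2/L3" = 0.231, "L3/L4" = 0.204,
                      "L4/L5" = 0.185, "L5/S1" = 0.125)

#' Define a static load case
#'
#' The four study tasks: upright neutral standing; 30 degrees of trunk
#' flexion (40\% sacral rotation, 60\% lumbar flexion split 25.5/23.1/
#' 20.4/18.5/12.5\% over L1/L2..L5/S1); lifting 10 kg in front of the
#' chest at 0.25 m from T3; and lifting 10 kg with stretched arms at
#' 0.55 m from T3. In lifting tasks the arm centre of mass is moved to
#' the hand lever.
#'
#' @param name one of \code{"neutral"}, \code{"flexion30"},
#'   \code{"lift10_25"}, \code{"lift10_55"}.
#' @return Object of class \code{load_case} with fields
#'   \code{external_mass_kg}, \code{hand_lever_m}, \code{flexion_deg}.
#' @export
load_case <- function(name = c("neutral", "flexion30", "lift10_25", "lift10_55")) {
  name <- match.arg(name)
  spec <- switch(name,
    neutral   = list(external_mass_kg = 0,  hand_lever_m = NA_real_, flexion_deg = 0),
    flexion30 = list(external_mass_kg = 0,  hand_lever_m = NA_real_, flexion_deg = 30),
    lift10_25 = list(external_mass_kg = 10, hand_lever_m = 0.25,     flexion_deg = 0),
    lift10_55 = list(external_mass_kg = 10, hand_lever_m = 0.55,     flexion_deg = 0)
  )
  stopifnot(abs(sum(LUMBAR_PARTITION) - 1) < 1e-12)
  structure(c(list(name = name), spec,
              list(sacral_fraction = SACRAL_FRACTION,
                   lumbar_fraction = LUMBAR_FRACTION,
                   lumbar_partition = LUMBAR_PARTITION)),
            class = "load_case")
}

#' The four default study load cases
#' @return Named list of \code{\link{load_case}} objects.
#' @export
default_load_cases <- function() {
  nms <- c("neutral", "flexion30", "lift10_25", "lift10_55")
  stats::setNames(lapply(nms, load_case), nms)
}
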