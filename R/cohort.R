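# Synthetic cohort generation: morphology records whose marginal and joint
# statistics emulate a population-based elderly cohort.

#' Cohort summary statistics
#'
#' Container for the per-parameter means and standard deviations of the
#' morphology distribution plus the lumbar-lordosis / thoracic-kyphosis
#' correlation. Defaults reproduce the study cohort: TK 42.2 +/- 11.5 deg,
#' LL 37.4 +/- 12.0 deg, TH 0.43 +/- 0.03 m, TW 25.1 +/- 5.9 kg,
#' torso centre of mass 0.03 +/- 0.01 m anterior and 0.21 +/- 0.01 m
#' superior of the L5 vertebral frame, corr(LL, TK) = 0.4.
#'
#' @param mean_TK,sd_TK thoracic kyphosis mean / SD, degrees.
#' @param mean_LL,sd_LL lumbar lordosis mean / SD, degrees.
#' @param mean_TH,sd_TH torso height (T1 upper endplate to L5 lower
#'   endplate) mean / SD, metres.
#' @param mean_TW,sd_TW torso soft-tissue weight mean / SD, kilograms.
#' @param mean_CoM_AP,sd_CoM_AP anterior offset of the torso centre of mass,
#'   metres, relative to the L5 vertebral frame.
#' @param mean_CoM_SI,sd_CoM_SI superior offset of the torso centre of mass,
#'   metres, relative to the L5 vertebral frame.
#' @param corr_LL_TK correlation between LL and TK (|corr| < 1); all other
#'   pairs are independent.
#' @return An object of class \code{cohort_stats}.
#' @export
cohort_stats <- function(mean_TK = 42.2, sd_TK = 11.5,
                         mean_LL = 37.4, sd_LL = 12.0,
                         mean_TH = 0.43, sd_TH = 0.03,
                         mean_TW = 25.1, sd_TW = 5.9,
                         mean_CoM_AP = 0.03, sd_CoM_AP = 0.01,
                         mean_CoM_SI = 0.21, sd_CoM_SI = 0.01,
                         corr_LL_TK = 0.4) {
  means <- c(TK = mean_TK, LL = mean_LL, TH = mean_TH, TW = mean_TW,
             CoM_AP = mean_CoM_AP, CoM_SI = mean_CoM_SI)
  sds <- c(TK = sd_TK, LL = sd_LL, TH = sd_TH, TW = sd_TW,
           CoM_AP = sd_CoM_AP, CoM_SI = sd_CoM_SI)
  if (any(!is.finite(means)) || any(!is.finite(sds))) {
    stop("cohort statistics must be finite")
  }
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (!is.finite(corr_LL_TK) || abs(corr_LL_TK) >= 1) {
    stop("|corr_LL_TK| must be < 1")
  }
  structure(list(means = means, sds = sds, corr_LL_TK = corr_LL_TK),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort statistics (mean +/- SD):\n")
  for (nm in names(x$means)) {
    cat(sprintf("  %-7s %8.3f +/- %.3f\n", nm, x$means[[nm]], x$sds[[nm]]))
  }
  cat(sprintf("  corr(LL, TK) = %.2f\n", x$corr_LL_TK))
  invisible(x)
}

valid_morphology <- function(df) {
  is.finite(df$TK) & is.finite(df$LL) & is.finite(df$TH) & is.finite(df$TW) &
    is.finite(df$CoM_AP) & is.finite(df$CoM_SI) &
    df$TH > 0 & df$TW > 0 &
    df$TK >= 0 & df$TK <= 90 & df$LL >= 0 & df$LL <= 90
}

#' Sample a synthetic morphology cohort
#'
#' Draws morphology records from a multivariate normal distribution in which
#' only LL and TK are correlated (at \code{stats$corr_LL_TK}); all other
#' pairs are independent. Draws violating the anatomical validity ranges
#' (TH > 0, TW > 0, 0 <= TK <= 90 deg, 0 <= LL <= 90 deg) are resampled,
#' not clipped, so marginal shapes are truncated-normal.
#'
#' @param n number of patients (>= 0).
#' @param seed integer seed; a fixed seed yields a bit-identical cohort. The
#'   caller's RNG state is preserved.
#' @param stats a \code{\link{cohort_stats}} object.
#' @return A data frame of class \code{spine_cohort} with columns
#'   \code{patient_id, TK, LL, TH, TW, CoM_AP, CoM_SI} (units: degrees,
#'   metres, kilograms as in \code{\link{cohort_stats}}).
#' @export
sample_cohort <- function(n, seed = 1, stats = cohort_stats()) {
  if (!inherits(stats, "cohort_stats")) stop("stats must be a cohort_stats object")
  if (length(n) != 1 || !is.finite(n) || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer")
  }
  cols <- names(stats$means)
  empty <- stats::setNames(
    data.frame(patient_id = character(0),
               matrix(numeric(0), 0, length(cols))),
    c("patient_id", cols)
  )
  if (n == 0) {
    class(empty) <- c("spine_cohort", "data.frame")
    return(empty)
  }
  sigma <- diag(stats$sds^2)
  dimnames(sigma) <- list(cols, cols)
  sigma["LL", "TK"] <- sigma["TK", "LL"] <-
    stats$corr_LL_TK * stats$sds[["LL"]] * stats$sds[["TK"]]
  draw <- function(k) {
    m <- MASS::mvrnorm(k, mu = stats$means, Sigma = sigma)
    if (k == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, cols))
    as.data.frame(m)
  }
  out <- with_seed(seed, {
    acc <- draw(n)
    ok <- valid_morphology(acc)
    guard <- 0
    while (!all(ok)) {
      guard <- guard + 1
      if (guard > 1000) stop("resampling failed to produce valid morphologies")
      acc[!ok, ] <- draw(sum(!ok))
      ok <- valid_morphology(acc)
    }
    acc
  })
  out <- cbind(patient_id = sprintf("P%03d", seq_len(n)), out)
  rownames(out) <- NULL
  class(out) <- c("spine_cohort", "data.frame")
  out
}

#' Alignment association within a cohort
#'
#' Standardized simple regression of thoracic kyphosis on lumbar lordosis:
#' both variables are z-scored, so the slope equals the Pearson correlation
#' and the coefficient of determination is its square.
#'
#' @param cohort a cohort data frame with columns \code{TK} and \code{LL}.
#' @return A list with \code{slope_std}, \code{r_squared}, \code{n}, and
#'   \code{degenerate} (TRUE when LL has zero variance).
#' @export
cohort_alignment_regression <- function(cohort) {
  if (nrow(cohort) < 3) stop("need at least 3 records")
  if (stats::sd(cohort$LL) == 0) {
    return(list(slope_std = NA_real_, r_squared = NA_real_,
                n = nrow(cohort), degenerate = TRUE))
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  fit <- stats::lm(zTK ~ zLL, data = data.frame(zTK = z(cohort$TK), zLL = z(cohort$LL)))
  slope <- unname(stats::coef(fit)[["zLL"]])
  list(slope_std = slope, r_squared = summary(fit)$r.squared,
       n = nrow(cohort), degenerate = FALSE)
}

#' Default per-level torso mass allocation template
#'
#' Fraction of torso weight assigned to each vertebral level T1..L5, rising
#' monotonically in the caudal direction (abdominal levels carry more soft
#' tissue than the lung-dominated upper thorax), normalized to sum to one.
#' Default unadjusted segment centre-of-mass offsets place each segment's
#' mass 4 cm anterior of its vertebral frame.
#'
#' @return Data frame with columns \code{level}, \code{w} (mass fraction),
#'   \code{off_ap}, \code{off_si} (metres, relative to the level frame).
#' @export
default_mass_template <- function() {
  n <- length(ALL_LEVELS)
  w <- seq(0.7, 1.8, length.out = n)
  data.frame(level = ALL_LEVELS, w = w / sum(w),
             off_ap = rep(0.04, n), off_si = rep(0, n),
             stringsAsFactors = FALSE)
}

#' Derive a per-level segment mass profile from a morphology record
#'
#' Distributes torso weight over vertebral levels T1..L5 using a fixed
#' allocation template and then applies the minimal-norm (mass-weighted)
#' correction to the per-segment centre-of-mass offsets so that the
#' mass-weighted aggregate centre of mass, expressed in the L5 vertebral
#' frame, equals the record's (CoM_AP, CoM_SI). The minimal-norm correction
#' under the aggregate constraint is a uniform shift of all offsets.
#'
#' @param record one cohort row (data frame row or list with fields
#'   \code{TW, CoM_AP, CoM_SI} and, if \code{geometry} is NULL, also
#'   \code{TK, LL, TH}).
#' @param template allocation template as from
#'   \code{\link{default_mass_template}}; mass fractions must be
#'   non-negative and sum to 1.
#' @param geometry optional \code{spine_geometry}; defaults to the curve
#'   built from the record's own TK/LL/TH. Level positions are needed
#'   because the aggregate constraint lives in the L5 frame.
#' @param com_band_m half-width of the anatomically plausible band for the
#'   corrected anterior offsets, metres; a required offset outside the band
#'   flags the profile infeasible rather than clipping it.
#' @return Data frame of class \code{segment_mass_profile} with columns
#'   \code{level, mass_kg, off_ap, off_si} and attributes \code{feasible}
#'   and \code{patient_id}.
#' @export
derive_segment_masses <- function(record, template = default_mass_template(),
                                  geometry = NULL, com_band_m = 0.15) {
  record <- as.list(record)
  if (any(template$w < 0)) stop("template mass fractions must be non-negative")
  if (abs(sum(template$w) - 1) > 1e-9) stop("template mass fractions must sum to 1")
  if (!identical(template$level, ALL_LEVELS)) stop("template must cover levels T1..L5 in order")
  if (is.null(geometry)) {
    geometry <- build_sagittal_curve(record$TK, record$LL, record$TH)
  }
  mass <- record$TW * template$w
  prof <- data.frame(level = template$level, mass_kg = mass,
                     off_ap = template$off_ap, off_si = template$off_si,
                     stringsAsFactors = FALSE)
  feasible <- TRUE
  if (record$TW > 0) {
    lv <- geometry$levels
    l5 <- lv[lv$level == "L5", ]
    cx <- lv$cx - l5$cx
    cy <- lv$cy - l5$cy
    cur_ap <- sum(mass * (cx + prof$off_ap)) / record$TW
    cur_si <- sum(mass * (cy + prof$off_si)) / record$TW
    prof$off_ap <- prof$off_ap + (record$CoM_AP - cur_ap)
    prof$off_si <- prof$off_si + (record$CoM_SI - cur_si)
    if (any(abs(prof$off_ap) > com_band_m)) {
      feasible <- FALSE
      warning("required segment CoM correction leaves the anatomical band; profile flagged")
    }
  }
  structure(prof, class = c("segment_mass_profile", "data.frame"),
            feasible = feasible, patient_id = record$patient_id %||% NA_character_)
}

#' Aggregate centre of mass of a segment profile
#'
#' Direct mass-weighted summation of segment centres of mass in the L5
#' vertebral frame; used to verify the conservation invariants of
#' \code{\link{derive_segment_masses}}.
#'
#' @param profile a \code{segment_mass_profile}.
#' @param geometry the \code{spine_geometry} the profile refers to.
#' @return Named numeric vector \code{c(ap, si)} in metres, or \code{c(NA,
#'   NA)} for a massless profile.
#' @export
profile_aggregate_com <- function(profile, geometry) {
  tw <- sum(profile$mass_kg)
  if (tw == 0) return(c(ap = NA_real_, si = NA_real_))
  lv <- geometry$levels
  l5 <- lv[lv$level == "L5", ]
  c(ap = sum(profile$mass_kg * (lv$cx - l5$cx + profile$off_ap)) / tw,
    si = sum(profile$mass_kg * (lv$cy - l5$cy + profile$off_si)) / tw)
}
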