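# Sagittal spine geometry: two tangent circular arcs (kyphotic thoracic,
# lordotic lumbar) realized as a chain of straight per-level segments.
#
# Coordinates: x = anterior (AP), y = superior (SI), sagittal plane only.
# The tangent angle psi is measured from the vertical (+y), positive when
# the spine axis leans anteriorly. An endplate perpendicular to the axis
# then makes the angle psi with the horizontal, positive anterior-down.

# Relative per-level heights: lumbar vertebra+disc units are taller than
# thoracic ones.
LEVEL_LEN_UNITS <- c(rep(1, 12), rep(1.25, 5))

#' Build a sagittal spine curve from clinical alignment angles
#'
#' Realizes thoracic kyphosis and lumbar lordosis as two tangent circular
#' arcs: going cranially the tangent rotates posteriorly by LL across the
#' five lumbar levels and anteriorly by TK across the twelve thoracic
#' levels, with even angular increments per level inside each region. The
#' free global orientation is closed by making the T1-to-L5 chord vertical,
#' and the chain is scaled so the distance from the T1 upper endplate to
#' the L5 lower endplate equals the torso height TH. The L5 lower endplate
#' sits at the origin, which is also the lumbosacral joint centre.
#'
#' @param TK thoracic kyphosis, degrees, in [0, 90].
#' @param LL lumbar lordosis, degrees, in [0, 90].
#' @param TH torso height, metres (> 0).
#' @return An object of class \code{spine_geometry}: list with a
#'   \code{levels} data frame (per level T1..L5: centre \code{cx, cy},
#'   segment axis angle \code{angle_deg}, boundary endplate positions and
#'   tilts \code{lower_x, lower_y, lower_tilt, upper_x, upper_y,
#'   upper_tilt}), the input angles, and the chord closure angle
#'   \code{psi0_deg}.
#' @export
build_sagittal_curve <- function(TK, LL, TH) {
  if (!all(is.finite(c(TK, LL, TH)))) stop("TK, LL, TH must be finite")
  if (TK < 0 || TK > 90 || LL < 0 || LL > 90) stop("TK and LL must lie in [0, 90] degrees")
  if (TH <= 0) stop("TH must be positive")

  lens <- LEVEL_LEN_UNITS
  n <- length(lens)
  s_bound <- c(0, cumsum(rev(lens)))       # arc position of boundaries, bottom-up
  s_lumbar <- sum(lens[13:17])             # lumbar arc span (units)
  s_total <- sum(lens)

  # Tangent angle (deg, relative to the free closure angle psi0) at arc
  # position s measured upward from the L5 lower endplate.
  psi_rel <- function(s) {
    ifelse(s <= s_lumbar,
           -LL * s / s_lumbar,
           -LL + TK * (s - s_lumbar) / (s_total - s_lumbar))
  }
  s_mid <- (s_bound[-1] + s_bound[-(n + 1)]) / 2
  psi_mid_rel <- psi_rel(s_mid)

  # Close the curve: choose psi0 so the T1-top to L5-bottom chord is
  # vertical. The AP offset is monotone in psi0 while all tangents stay
  # within +/-90 deg.
  ap_offset <- function(psi0) sum(rev(lens) * sin(deg2rad(psi0 + psi_mid_rel)))
  lo <- -89 - min(psi_mid_rel); hi <- 89 - max(psi_mid_rel)
  if (lo >= hi) stop("alignment angles leave no admissible spine orientation")
  psi0 <- stats::uniroot(ap_offset, c(lo, hi), tol = 1e-12)$root
  psi_mid <- psi0 + psi_mid_rel                       # bottom-up per segment
  if (any(abs(psi_mid) >= 90)) stop("arc construction failed: segment axis beyond horizontal")

  # Accumulate unit-scale boundary positions bottom-up, then rescale.
  dx <- rev(lens) * sin(deg2rad(psi_mid))
  dy <- rev(lens) * cos(deg2rad(psi_mid))
  bx <- c(0, cumsum(dx))
  by <- c(0, cumsum(dy))
  chord <- sqrt(bx[n + 1]^2 + by[n + 1]^2)
  scale <- TH / chord
  bx <- bx * scale; by <- by * scale

  psi_bound <- psi0 + psi_rel(s_bound)                # endplate tilts, bottom-up
  idx_low <- rev(seq_len(n))                          # map cranial order -> bottom-up
  levels <- data.frame(
    level = ALL_LEVELS,
    cx = (bx[idx_low] + bx[idx_low + 1]) / 2,
    cy = (by[idx_low] + by[idx_low + 1]) / 2,
    angle_deg = rev(psi_mid),
    lower_x = bx[idx_low], lower_y = by[idx_low],
    lower_tilt = psi_bound[idx_low],
    upper_x = bx[idx_low + 1], upper_y = by[idx_low + 1],
    upper_tilt = psi_bound[idx_low + 1],
    stringsAsFactors = FALSE
  )
  if (any(diff(levels$cy) >= 0)) stop("vertebral frames are not strictly ordered superior to inferior")
  structure(list(levels = levels, TK = TK, LL = LL, TH = TH, psi0_deg = psi0),
            class = "spine_geometry")
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat(sprintf("Sagittal spine geometry: TK %.1f deg, LL %.1f deg, TH %.3f m (17 levels)\n",
              x$TK, x$LL, x$TH))
  invisible(x)
}

#' Re-measure sagittal alignment angles from spine frames
#'
#' Independent Cobb-type measurement on the generated frames: the angle
#' between the T1 upper and T12 lower endplate direction vectors (TK) and
#' between the L1 upper and L5 lower endplate direction vectors (LL),
#' computed from the frame coordinates via \code{atan2} of the endplate
#' direction vectors, plus the Euclidean T1-upper to L5-lower distance.
#'
#' @param geometry a \code{spine_geometry}.
#' @return Named vector \code{c(TK, LL, TH)} (degrees, degrees, metres).
#' @export
measure_sagittal_angles <- function(geometry) {
  lv <- geometry$levels
  plate_angle <- function(tilt_deg) {
    # endplate direction vector (anterior-pointing), angle via atan2
    v <- c(cos(deg2rad(tilt_deg)), -sin(deg2rad(tilt_deg)))
    rad2deg(atan2(v[2], v[1]))
  }
  a_t1 <- plate_angle(lv$upper_tilt[lv$level == "T1"])
  a_t12 <- plate_angle(lv$lower_tilt[lv$level == "T12"])
  a_l1 <- plate_angle(lv$upper_tilt[lv$level == "L1"])
  a_l5 <- plate_angle(lv$lower_tilt[lv$level == "L5"])
  th <- sqrt((lv$upper_x[lv$level == "T1"] - lv$lower_x[lv$level == "L5"])^2 +
             (lv$upper_y[lv$level == "T1"] - lv$lower_y[lv$level == "L5"])^2)
  c(TK = abs(a_t1 - a_t12), LL = abs(a_l1 - a_l5), TH = th)
}

# Joint centre table in build (unposed) coordinates. Each evaluated FSU is
# located at the boundary between its vertebrae; the FSU frame carries the
# endplate tilt of the upper endplate of the lower element (for L5/S1 the
# sacral plate, which coincides with the L5 lower boundary plane).
joint_table <- function(geometry) {
  lv <- geometry$levels
  row_of <- function(level) lv[lv$level == level, ]
  lower_elem <- c("L1", "L2", "L3", "L4", "L5", "sacrum")
  out <- data.frame(joint = JOINT_LEVELS,
                    upper_body = c("thorax", "L1", "L2", "L3", "L4", "L5"),
                    lower_body = c("L1", "L2", "L3", "L4", "L5", "pelvis"),
                    stringsAsFactors = FALSE)
  pos <- t(vapply(seq_len(6), function(i) {
    if (lower_elem[i] == "sacrum") {
      r <- row_of("L5")
      c(r$lower_x, r$lower_y, r$lower_tilt)
    } else {
      r <- row_of(lower_elem[i])
      c(r$upper_x, r$upper_y, r$upper_tilt)
    }
  }, numeric(3)))
  out$x <- pos[, 1]; out$y <- pos[, 2]; out$plate_tilt <- pos[, 3]
  # FSU plate body: rotates with the lower element; the sacral plate follows
  # only the sacral rotation (handled in posing via the pseudo-body tag).
  out$plate_body <- c("L1", "L2", "L3", "L4", "L5", "sacrum_plate")
  out
}
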