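# Posing: forward kinematics of the sagittal chain under the flexion
# partition, plus the neutral-standing balance adjustment.
#
# Flexion is positive when the superior body tips anteriorly; a flexion
# rotation by angle a maps a body point p to c + R(-a)(p - c) about the
# joint centre c, where R is the counter-clockwise rotation matrix in
# (x = anterior, y = superior) coordinates.

rot_flex <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # R(-a)
}

# Bodies that move: everything except the pelvis, plus the pseudo-body
# carrying the sacral endplate (follows only the sacral rotation).
POSE_BODIES <- c("sacrum_plate", BODY_ORDER)

#' Pose a trunk model for a load case
#'
#' Applies the sacral rotation (40\% of case flexion plus any baseline
#' standing tilt) about the lumbosacral joint and the per-joint lumbar
#' rotations (60\% of case flexion split by the fixed partition), composing
#' rotations bottom-up about the already-posed joint centres.
#'
#' @param model a \code{trunk_model}.
#' @param case a \code{\link{load_case}}.
#' @param base_tilt_deg baseline sacral tilt from
#'   \code{\link{neutral_balance}}, degrees (flexion-positive).
#' @return Object of class \code{posture_state}: per-joint rotations,
#'   per-body rigid transforms, posed joint table (centres and functional
#'   spinal unit plate tilts), and the total case flexion.
#' @export
pose_model <- function(model, case, base_tilt_deg = 0) {
  stopifnot(inherits(case, "load_case"))
  jt <- joint_table(model$geometry)
  sacral <- base_tilt_deg + case$sacral_fraction * case$flexion_deg
  defl <- stats::setNames(rep(0, length(JOINT_LEVELS)), JOINT_LEVELS)
  lum <- case$lumbar_fraction * case$flexion_deg * case$lumbar_partition
  defl[names(lum)] <- lum

  tf <- lapply(POSE_BODIES, function(b) list(M = diag(2), t = c(0, 0), ang = 0))
  names(tf) <- POSE_BODIES
  apply_rot <- function(bodies, center, deg) {
    R <- rot_flex(deg)
    for (b in bodies) {
      tf[[b]]$M <<- R %*% tf[[b]]$M
      tf[[b]]$t <<- center + R %*% (tf[[b]]$t - center)
      tf[[b]]$ang <<- tf[[b]]$ang + deg
    }
  }
  # 1) sacral rotation about the lumbosacral joint carries the sacral plate
  #    and the whole spine; 2) lumbar joints bottom-up.
  apply_rot(setdiff(POSE_BODIES, "pelvis"), c(0, 0), sacral)
  for (j in rev(JOINT_LEVELS)) {              # caudal to cranial
    d <- defl[[j]]
    row <- jt[jt$joint == j, ]
    above <- BODY_ORDER[body_index(row$upper_body):length(BODY_ORDER)]
    if (d != 0) {
      lb <- if (row$lower_body == "pelvis") "sacrum_plate" else row$lower_body
      center <- as.numeric(tf[[lb]]$M %*% c(row$x, row$y) + tf[[lb]]$t)
      # the lumbosacral centre is the sacral pivot itself
      if (j == "L5/S1") center <- c(0, 0)
      apply_rot(above, center, d)
    }
  }
  posed <- jt
  for (i in seq_len(nrow(jt))) {
    lb <- if (jt$lower_body[i] == "pelvis") "sacrum_plate" else jt$lower_body[i]
    p <- as.numeric(tf[[lb]]$M %*% c(jt$x[i], jt$y[i]) + tf[[lb]]$t)
    posed$x[i] <- p[1]; posed$y[i] <- p[2]
    pb <- jt$plate_body[i]
    posed$plate_tilt[i] <- jt$plate_tilt[i] + tf[[pb]]$ang
  }
  structure(list(sacral_deg = sacral, deflections_deg = defl,
                 transforms = tf, joints = posed,
                 flexion_deg = case$flexion_deg, case = case$name),
            class = "posture_state")
}

# Transform points (n x 2 matrix or length-2 vector) of a given body.
pose_points <- function(posture, body, xy) {
  tf <- posture$transforms[[body]]
  if (is.null(tf)) stop("unknown body: ", body)
  xy <- matrix(xy, ncol = 2)
  t(tf$M %*% t(xy)) + matrix(tf$t, nrow(xy), 2, byrow = TRUE)
}

# All point masses of a posed model under a load case: torso segments,
# head-neck, arms (repositioned to the hand lever while lifting), and the
# external mass.
mass_points <- function(model, posture, case) {
  lv <- model$geometry$levels
  prof <- model$profile
  body <- body_of_level(lv$level)
  pts <- cbind(lv$cx + prof$off_ap, lv$cy + prof$off_si)
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    p <- pose_points(posture, body[i], pts[i, ])
    data.frame(label = lv$level[i], body = body[i],
               mass = prof$mass_kg[i], x = p[1], y = p[2])
  })
  d <- model$defaults
  t1 <- lv[lv$level == "T1", ]; t3 <- lv[lv$level == "T3", ]
  head_p <- pose_points(posture, "thorax", c(t1$cx + d$head_ap_m, t1$cy + d$head_si_m))
  rows <- c(rows, list(data.frame(label = "head", body = "thorax",
                                  mass = d$head_mass_kg, x = head_p[1], y = head_p[2])))
  lifting <- case$external_mass_kg > 0
  arm_off <- if (lifting) c(case$hand_lever_m, 0) else c(d$arm_ap_m, d$arm_si_m)
  arm_p <- pose_points(posture, "thorax", c(t3$cx + arm_off[1], t3$cy + arm_off[2]))
  rows <- c(rows, list(data.frame(label = "arms", body = "thorax",
                                  mass = 2 * d$arm_mass_kg, x = arm_p[1], y = arm_p[2])))
  if (lifting) {
    ext_p <- pose_points(posture, "thorax", c(t3$cx + case$hand_lever_m, t3$cy))
    rows <- c(rows, list(data.frame(label = "external", body = "thorax",
                                    mass = case$external_mass_kg, x = ext_p[1], y = ext_p[2])))
  }
  out <- do.call(rbind, rows)
  out$body_idx <- body_index(out$body)
  out
}

#' Neutral standing balance adjustment
#'
#' Finds the single sacral-tilt adjustment that places the whole-body
#' centre of mass (torso segments, head-neck and arms; no external load)
#' vertically over the lumbosacral joint, bounded to +/- 10 degrees. This
#' stands in for the posture optimization that corrects the supine CT
#' alignment to an upright standing position.
#'
#' @param model a \code{trunk_model}.
#' @param band_m AP tolerance band, metres: the model is flagged
#'   unbalanceable when the achieved offset exceeds the band.
#' @param max_tilt_deg adjustment bound, degrees.
#' @return List with \code{tilt_deg}, \code{offset_before_m},
#'   \code{offset_after_m} and \code{balanced}.
#' @export
neutral_balance <- function(model, band_m = 0.005, max_tilt_deg = 10) {
  case <- load_case("neutral")
  p0 <- pose_model(model, case, base_tilt_deg = 0)
  mp <- mass_points(model, p0, case)
  M <- sum(mp$mass)
  if (M <= 0) return(list(tilt_deg = 0, offset_before_m = 0, offset_after_m = 0,
                          balanced = TRUE))
  xb <- sum(mp$mass * mp$x) / M
  yb <- sum(mp$mass * mp$y) / M
  # rotating by flexion a maps the CoM AP to xb*cos(a) + yb*sin(a)
  tilt <- rad2deg(atan2(-xb, yb))
  clipped <- max(-max_tilt_deg, min(max_tilt_deg, tilt))
  p1 <- pose_model(model, case, base_tilt_deg = clipped)
  mp1 <- mass_points(model, p1, case)
  after <- sum(mp1$mass * mp1$x) / M
  balanced <- abs(after) <= band_m
  if (!balanced) {
    warning(sprintf("model %s not balanceable within +/-%g deg (residual %.3f m); simulated with clipped tilt",
                    model$patient_id, max_tilt_deg, after))
  }
  list(tilt_deg = clipped, offset_before_m = xb, offset_after_m = after,
       balanced = balanced)
}

#' Posed fascicle geometry and moment arms
#'
#' Transforms every fascicle's attachment points into the posed frame and
#' computes, for each evaluated joint, whether the fascicle crosses it and
#' its flexion-positive moment arm per unit force,
#' \code{a = cross2(p_sup - c, u)} with \code{u} the unit vector from the
#' inferior toward the superior attachment. This equals minus the
#' derivative of fascicle length with respect to the joint's flexion
#' angle.
#'
#' @param model a \code{trunk_model}.
#' @param posture a \code{posture_state}.
#' @return List with posed \code{origin}/\code{insertion} matrices,
#'   \code{length}, the \code{arms} matrix (fascicles x joints, metres)
#'   and the logical \code{crosses} matrix.
#' @export
fascicle_mechanics <- function(model, posture) {
  fs <- model$fascicles
  o <- t(vapply(seq_len(nrow(fs)), function(i)
    as.numeric(pose_points(posture, fs$o_body[i], c(fs$o_x[i], fs$o_y[i]))), numeric(2)))
  ins <- t(vapply(seq_len(nrow(fs)), function(i)
    as.numeric(pose_points(posture, fs$i_body[i], c(fs$i_x[i], fs$i_y[i]))), numeric(2)))
  len <- sqrt(rowSums((o - ins)^2))
  oi <- body_index(fs$o_body); ii <- body_index(fs$i_body)
  jt <- posture$joints
  n <- nrow(fs); m <- nrow(jt)
  arms <- matrix(0, n, m, dimnames = list(fs$name, jt$joint))
  crosses <- matrix(FALSE, n, m, dimnames = list(fs$name, jt$joint))
  for (k in seq_len(m)) {
    ub <- body_index(jt$upper_body[k])
    sup_is_o <- oi >= ub & ii < ub
    sup_is_i <- ii >= ub & oi < ub
    cr <- sup_is_o | sup_is_i
    crosses[, k] <- cr
    if (!any(cr)) next
    cx <- jt$x[k]; cy <- jt$y[k]
    p_sup <- ifelse(matrix(sup_is_o, n, 2), o, ins)
    p_inf <- ifelse(matrix(sup_is_o, n, 2), ins, o)
    ux <- (p_sup[, 1] - p_inf[, 1]) / len
    uy <- (p_sup[, 2] - p_inf[, 2]) / len
    a <- cross2(p_sup[, 1] - cx, p_sup[, 2] - cy, ux, uy)
    arms[cr, k] <- a[cr]
  }
  list(fascicles = fs, origin = o, insertion = ins, length = len,
       arms = arms, crosses = crosses)
}
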