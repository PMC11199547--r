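# Inverse statics and static optimization of muscle forces.
#
# Moments are sagittal and flexion-positive (anterior gravity levers give
# positive moments; extensor fascicles have negative flexion moment arms).

#' Solver and passive-element settings
#'
#' @param sigma_max_pa maximum muscle stress bound, pascals (1 MPa).
#' @param exponent objective exponent; the cost is the sum of cubed muscle
#'   stresses and the exponent is fixed at 3.
#' @param gravity_ms2 gravitational acceleration, m/s^2.
#' @param k1,k3 passive disc/ligament stiffness coefficients of the odd
#'   restoring polynomial k1*theta + k3*theta^3 (N m per deg and per
#'   deg^3), sized so passive structures carry well under 20\% of the
#'   demand at the largest posed deflections.
#' @param tol equilibrium residual target, N m.
#' @param feas_tol residual above which a solve is declared infeasible, N m.
#' @param constraint_mode \code{"equality"}: muscle moments balance the net
#'   demand exactly at every articulated joint (default);
#'   \code{"one_sided"}: muscles must at least match the demand in its own
#'   direction.
#' @param balance_band_m AP tolerance band for the standing balance.
#' @return List of class \code{solver_settings}.
#' @export
solver_settings <- function(sigma_max_pa = 1e6, exponent = 3, gravity_ms2 = 9.81,
                            k1 = 0.3, k3 = 0.001, tol = 1e-6, feas_tol = 1e-3,
                            constraint_mode = c("equality", "one_sided"),
                            balance_band_m = 0.005) {
  if (sigma_max_pa <= 0) stop("sigma_max must be positive")
  if (exponent != 3) stop("objective exponent is fixed at 3")
  structure(list(sigma_max_pa = sigma_max_pa, exponent = 3,
                 gravity_ms2 = gravity_ms2, k1 = k1, k3 = k3,
                 tol = tol, feas_tol = feas_tol,
                 constraint_mode = match.arg(constraint_mode),
                 balance_band_m = balance_band_m),
            class = "solver_settings")
}

#' Passive restoring moment of a functional spinal unit
#'
#' Non-linear elastic disc/ligament element: an odd polynomial
#' \code{-(k1*theta + k3*theta^3)} that opposes the deflection, is zero at
#' zero deflection, and grows strictly with |theta|.
#'
#' @param deflection_deg joint deflection, degrees (flexion-positive).
#' @param k1,k3 stiffness coefficients (N m/deg, N m/deg^3).
#' @return Moment in N m (flexion-positive sign convention).
#' @export
passive_moment <- function(deflection_deg, k1 = 0.3, k3 = 0.001) {
  -(k1 * deflection_deg + k3 * deflection_deg^3)
}

#' Net intersegmental moments and forces
#'
#' For every evaluated joint, sums the gravity (and external-load) moments
#' of all point masses superior to the joint about the posed joint centre,
#' subtracts the passive elastic moment at the joint's deflection, and
#' reports the net demand the muscles must balance.
#'
#' @param model a \code{trunk_model}.
#' @param posture a \code{posture_state} from \code{\link{pose_model}}.
#' @param case the \code{\link{load_case}} used to pose the model.
#' @param settings \code{\link{solver_settings}} (gravity and passive
#'   stiffness; set \code{gravity_ms2 = 0} for test mode).
#' @return Data frame per joint: gravity moment, passive moment, muscle
#'   demand (N m, flexion-positive), and the resultant suspended force
#'   components \code{fx, fy} (N).
#' @export
inverse_statics <- function(model, posture, case, settings = solver_settings()) {
  mp <- mass_points(model, posture, case)
  jt <- posture$joints
  g <- settings$gravity_ms2
  out <- jt[, c("joint", "upper_body")]
  out$m_gravity <- NA_real_; out$m_passive <- NA_real_
  out$fx <- 0; out$fy <- NA_real_
  for (k in seq_len(nrow(jt))) {
    ub <- body_index(jt$upper_body[k])
    sel <- mp$body_idx >= ub
    w <- mp$mass[sel] * g
    out$m_gravity[k] <- sum(w * (mp$x[sel] - jt$x[k]))
    out$fy[k] <- -sum(w)
    defl <- posture$deflections_deg[[jt$joint[k]]]
    out$m_passive[k] <- passive_moment(defl, settings$k1, settings$k3)
  }
  out$demand <- -(out$m_gravity + out$m_passive)
  out
}

# Clipped stationary point of x^3 - s*x on [0, 1].
.dual_x <- function(s) pmin(1, sqrt(pmax(s, 0) / 3))

#' Solve the muscle redundancy problem by static optimization
#'
#' Minimizes the sum of cubed muscle stresses subject to sagittal
#' joint-moment balance at every evaluated joint and the bound
#' \code{0 <= F_i <= sigma_max * PCSA_i}. In activation variables
#' \code{x_i = F_i / (sigma_max PCSA_i)} the program is \code{min sum
#' x_i^3} under linear constraints, a smooth convex program; it is solved
#' on the dual: the Lagrangian minimizer is separable and closed-form, the
#' concave dual is maximized by BFGS and polished by Newton steps on the
#' primal residual. Demands that exceed the moment-generating capacity at
#' the stress bound leave a residual and are flagged infeasible.
#'
#' @param demand named vector of muscle moment demands per joint (N m,
#'   flexion-positive), as from \code{\link{inverse_statics}}.
#' @param pcsa_m2 fascicle PCSAs, m^2.
#' @param arms moment-arm matrix (fascicles x joints, metres,
#'   flexion-positive).
#' @param settings \code{\link{solver_settings}}.
#' @return List: \code{force} (N), \code{activation}, \code{status}
#'   (\code{"optimal"} or \code{"infeasible"}), \code{residual} (max
#'   absolute moment imbalance, N m), \code{objective} (sum of cubed
#'   stresses, Pa^3), \code{lambda}.
#' @export
solve_muscle_forces <- function(demand, pcsa_m2, arms, settings = solver_settings()) {
  smax <- settings$sigma_max_pa
  G <- t(arms * pcsa_m2 * smax)                      # joints x fascicles
  m <- nrow(G); n <- ncol(G)
  d <- as.numeric(demand)
  one_sided <- settings$constraint_mode == "one_sided"
  sgn <- if (one_sided) ifelse(d >= 0, 1, -1) else rep(1, m)

  dual_neg <- function(lam) {
    s <- as.numeric(crossprod(G, lam))
    x <- .dual_x(s)
    -(sum(x^3 - s * x) + sum(lam * d))
  }
  dual_neg_gr <- function(lam) {
    x <- .dual_x(as.numeric(crossprod(G, lam)))
    -(d - as.numeric(G %*% x))
  }
  if (one_sided) {
    # sign-constrained multipliers: optimize over mu >= 0 with lam = sgn*mu
    fn <- function(mu) dual_neg(sgn * mu)
    gr <- function(mu) sgn * dual_neg_gr(sgn * mu)
    opt <- stats::optim(rep(0, m), fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 1000, factr = 10))
    lam <- sgn * opt$par
  } else {
    opt <- stats::optim(rep(0, m), dual_neg, dual_neg_gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
    lam <- opt$par
  }
  x <- .dual_x(as.numeric(crossprod(G, lam)))
  res <- d - as.numeric(G %*% x)
  if (one_sided) res <- pmax(res * sgn, 0) * sgn     # only deficit counts
  # Newton polish on the active-set system R D R^T dlam = res
  for (it in 1:100) {
    if (max(abs(res)) <= settings$tol) break
    s <- as.numeric(crossprod(G, lam))
    dx <- ifelse(s > 0 & s < 3, 1 / (2 * sqrt(3 * pmax(s, 1e-300))), 0)
    J <- G %*% (dx * t(G))
    step <- tryCatch(solve(J + diag(1e-10, m), res), error = function(e) NULL)
    if (is.null(step)) break
    lam_new <- lam + step
    if (one_sided) lam_new <- sgn * pmax(sgn * lam_new, 0)
    x_new <- .dual_x(as.numeric(crossprod(G, lam_new)))
    res_new <- d - as.numeric(G %*% x_new)
    if (one_sided) res_new <- pmax(res_new * sgn, 0) * sgn
    if (max(abs(res_new)) >= max(abs(res))) break
    lam <- lam_new; x <- x_new; res <- res_new
  }
  feasible <- max(abs(res)) <= settings$feas_tol
  force <- x * smax * pcsa_m2
  list(force = if (feasible) force else rep(NA_real_, n),
       activation = if (feasible) x else rep(NA_real_, n),
       status = if (feasible) "optimal" else "infeasible",
       residual = max(abs(res)),
       objective = if (feasible) sum((force / pcsa_m2)^3) else NA_real_,
       lambda = lam)
}

#' Joint reactions in the functional spinal unit frame
#'
#' The force transmitted across each evaluated joint is the resultant of
#' gravity and external loads on the superior sub-chain plus the tensions
#' of all crossing fascicles pulling the superior part toward their
#' inferior attachments. It is decomposed in the posed FSU frame:
#' compression normal to the upper endplate of the lower vertebra
#' (positive pressing into the plate) and anterior-posterior shear in the
#' plane, positive pointing posteriorly.
#'
#' @param model a \code{trunk_model}.
#' @param posture a \code{posture_state}.
#' @param case the posed \code{\link{load_case}}.
#' @param solution result of \code{\link{solve_muscle_forces}}.
#' @param mech fascicle mechanics (posed endpoints, crossings); recomputed
#'   when NULL.
#' @param settings \code{\link{solver_settings}}.
#' @return Data frame per level: \code{compression_N}, \code{shear_AP_N},
#'   \code{feasible}. Infeasible solves carry no force values.
#' @export
joint_reaction <- function(model, posture, case, solution,
                           mech = NULL, settings = solver_settings()) {
  jt <- posture$joints
  if (solution$status != "optimal") {
    return(data.frame(level = jt$joint, compression_N = NA_real_,
                      shear_AP_N = NA_real_, feasible = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (is.null(mech)) mech <- fascicle_mechanics(model, posture)
  mp <- mass_points(model, posture, case)
  g <- settings$gravity_ms2
  oi <- body_index(mech$fascicles$o_body); ii <- body_index(mech$fascicles$i_body)
  out <- data.frame(level = jt$joint, compression_N = NA_real_,
                    shear_AP_N = NA_real_, feasible = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(jt))) {
    ub <- body_index(jt$upper_body[k])
    sel <- mp$body_idx >= ub
    Fx <- 0; Fy <- -sum(mp$mass[sel]) * g
    cr <- mech$crosses[, k]
    if (any(cr)) {
      sup_is_o <- oi >= ub
      p_sup <- ifelse(matrix(sup_is_o, length(oi), 2), mech$origin, mech$insertion)
      p_inf <- ifelse(matrix(sup_is_o, length(oi), 2), mech$insertion, mech$origin)
      ux <- (p_inf[, 1] - p_sup[, 1]) / mech$length
      uy <- (p_inf[, 2] - p_sup[, 2]) / mech$length
      Fx <- Fx + sum(solution$force[cr] * ux[cr])
      Fy <- Fy + sum(solution$force[cr] * uy[cr])
    }
    th <- deg2rad(jt$plate_tilt[k])
    nvec <- c(sin(th), cos(th))                      # endplate normal, superior
    tvec <- c(-cos(th), sin(th))                     # in-plane, posterior-positive
    out$compression_N[k] <- -(Fx * nvec[1] + Fy * nvec[2])
    out$shear_AP_N[k] <- Fx * tvec[1] + Fy * tvec[2]
  }
  out
}

#' Simulate one load case on one model
#'
#' Poses the model, computes net intersegmental demands, solves the static
#' optimization, and decomposes the joint reactions. The baseline standing
#' tilt from \code{\link{neutral_balance}} is applied to every case of the
#' same model.
#'
#' @param model a \code{trunk_model}.
#' @param case a \code{\link{load_case}} or case name.
#' @param settings \code{\link{solver_settings}}.
#' @param base_tilt_deg baseline sacral tilt, degrees; when NULL it is
#'   computed by \code{\link{neutral_balance}}.
#' @return List: \code{results} (per-level loads), \code{posture},
#'   \code{demands}, \code{solution}, \code{equilibrium_residual}.
#' @export
simulate_case <- function(model, case, settings = solver_settings(),
                          base_tilt_deg = NULL) {
  if (is.character(case)) case <- load_case(case)
  if (is.null(base_tilt_deg)) {
    base_tilt_deg <- neutral_balance(model, band_m = settings$balance_band_m)$tilt_deg
  }
  # Flexed tasks prescribe the trunk inclination absolutely (from vertical);
  # the standing-balance tilt corrects upright postures only.
  if (case$flexion_deg != 0) base_tilt_deg <- 0
  posture <- pose_model(model, case, base_tilt_deg = base_tilt_deg)
  demands <- inverse_statics(model, posture, case, settings)
  mech <- fascicle_mechanics(model, posture)
  sol <- solve_muscle_forces(stats::setNames(demands$demand, demands$joint),
                             mech$fascicles$pcsa_m2, mech$arms, settings)
  res <- joint_reaction(model, posture, case, sol, mech = mech, settings = settings)
  list(results = res, posture = posture, demands = demands, solution = sol,
       equilibrium_residual = sol$residual)
}
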