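test_that("passive moments restore toward neutral and follow the polynomial", {
  expect_equal(passive_moment(0), 0)
  th <- c(-8, -2, -0.5, 0.5, 2, 8)
  expect_true(all(sign(passive_moment(th)) == -sign(th)))
  expect_equal(passive_moment(4.59, k1 = 0.5, k3 = 0.002),
               -(0.5 * 4.59 + 0.002 * 4.59^3), tolerance = 1e-12)
  # strictly increasing magnitude in |theta|
  mag <- abs(passive_moment(seq(0, 10, by = 0.5)))
  expect_true(all(diff(mag) > 0))
})

test_that("without gravity all intersegmental demands vanish", {
  m <- ref_model()
  cs <- load_case("neutral")
  p <- pose_model(m, cs)
  d <- inverse_statics(m, p, cs, solver_settings(gravity_ms2 = 0))
  expect_true(all(abs(d$m_gravity) < 1e-12))
  expect_true(all(abs(d$demand) < 1e-12))
  expect_true(all(abs(d$fy) < 1e-12))
})

test_that("a single point mass produces the hand-computed moment and force", {
  m <- ref_model()
  # strip the model to one torso segment and no appendages
  m$profile$mass_kg[] <- 0
  m$profile$mass_kg[m$profile$level == "T5"] <- 4
  m$defaults$head_mass_kg <- 0
  m$defaults$arm_mass_kg <- 0
  cs <- load_case("neutral")
  p <- pose_model(m, cs)
  d <- inverse_statics(m, p, cs)
  lv <- m$geometry$levels
  px <- lv$cx[lv$level == "T5"] + m$profile$off_ap[m$profile$level == "T5"]
  for (k in seq_len(nrow(d))) {
    jx <- p$joints$x[p$joints$joint == d$joint[k]]
    expect_equal(d$m_gravity[k], 4 * 9.81 * (px - jx), tolerance = 1e-9)
    expect_equal(d$fy[k], -4 * 9.81, tolerance = 1e-12)
  }
})

test_that("an external load adds exactly its static contribution", {
  m <- ref_model()
  neutral <- load_case("neutral"); lift <- load_case("lift10_25")
  p <- pose_model(m, neutral)  # identical posture for both cases
  d0 <- inverse_statics(m, p, neutral)
  d1 <- inverse_statics(m, p, lift)
  lv <- m$geometry$levels
  t3 <- lv[lv$level == "T3", ]
  hand_x <- t3$cx + 0.25
  arm_x0 <- t3$cx + m$defaults$arm_ap_m
  g <- 9.81
  for (k in seq_len(nrow(d0))) {
    jx <- p$joints$x[k]
    delta_expected <- 10 * g * (hand_x - jx) +
      2 * m$defaults$arm_mass_kg * g * ((hand_x - jx) - (arm_x0 - jx))
    expect_equal(d1$m_gravity[k] - d0$m_gravity[k], delta_expected, tolerance = 1e-9)
    expect_equal(d1$fy[k] - d0$fy[k], -10 * g, tolerance = 1e-9)
  }
})

test_that("joint reactions decompose by the endplate rotation identity", {
  m <- ref_model()
  cs <- load_case("neutral")
  p <- pose_model(m, cs)
  sol <- list(force = rep(0, nrow(m$fascicles)), status = "optimal")
  rj <- joint_reaction(m, p, cs, sol)
  mp <- spineload:::mass_points(m, p, cs)
  for (k in seq_len(nrow(p$joints))) {
    ub <- spineload:::body_index(p$joints$upper_body[k])
    W <- sum(mp$mass[mp$body_idx >= ub]) * 9.81
    th <- p$joints$plate_tilt[k] * pi / 180
    expect_equal(rj$compression_N[k], W * cos(th), tolerance = 1e-9)
    expect_equal(rj$shear_AP_N[k], -W * sin(th), tolerance = 1e-9)
  }
})

test_that("muscle force pairs symmetric about the plate normal add pure compression", {
  m <- ref_model()
  cs <- load_case("neutral")
  p <- pose_model(m, cs)
  mech <- fascicle_mechanics(m, p)
  k <- which(p$joints$joint == "L4/L5")
  th <- p$joints$plate_tilt[k] * pi / 180
  nvec <- c(sin(th), cos(th))
  sol0 <- list(force = rep(0, nrow(m$fascicles)), status = "optimal")
  base <- joint_reaction(m, p, cs, sol0, mech = mech)
  # project a pair of crossing fascicle forces onto the normal: shear response
  # must equal the tangential components, compression the normal components
  cross_idx <- which(mech$crosses[, k])[1:2]
  f <- rep(0, nrow(m$fascicles)); f[cross_idx] <- 100
  sol1 <- list(force = f, status = "optimal")
  with_f <- joint_reaction(m, p, cs, sol1, mech = mech)
  oi <- spineload:::body_index(mech$fascicles$o_body)
  ub <- spineload:::body_index(p$joints$upper_body[k])
  dC <- 0; dS <- 0
  for (i in cross_idx) {
    sup_is_o <- oi[i] >= ub
    p_sup <- if (sup_is_o) mech$origin[i, ] else mech$insertion[i, ]
    p_inf <- if (sup_is_o) mech$insertion[i, ] else mech$origin[i, ]
    u <- (p_inf - p_sup) / sqrt(sum((p_inf - p_sup)^2))
    dC <- dC - 100 * sum(u * nvec)
    dS <- dS + 100 * sum(u * c(-cos(th), sin(th)))
  }
  expect_equal(with_f$compression_N[k] - base$compression_N[k], dC, tolerance = 1e-9)
  expect_equal(with_f$shear_AP_N[k] - base$shear_AP_N[k], dS, tolerance = 1e-9)
})

test_that("every feasible simulation satisfies equilibrium and the stress bound", {
  m <- ref_model()
  st <- solver_settings()
  for (nm in names(default_load_cases())) {
    sim <- simulate_case(m, nm, settings = st)
    expect_equal(sim$solution$status, "optimal")
    expect_lte(sim$equilibrium_residual, st$feas_tol)
    stress <- sim$solution$force / m$fascicles$pcsa_m2
    expect_lte(max(stress), st$sigma_max_pa * (1 + 1e-9))
    expect_true(all(sim$solution$force >= -1e-9))
    # direct re-check: muscle moments balance gravity plus passive moments
    mech <- fascicle_mechanics(m, sim$posture)
    resid <- t(mech$arms) %*% sim$solution$force +
      sim$demands$m_gravity + sim$demands$m_passive
    expect_lt(max(abs(resid)), st$feas_tol)
  }
})
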