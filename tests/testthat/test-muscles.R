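test_that("the bundled muscle table is complete and symmetric", {
  tab <- default_muscle_table()
  expect_setequal(unique(tab$group), c("RA", "IO", "EO", "PM", "QL", "MF",
                                       "LTL", "IL", "IS"))
  expect_true(all(tab$pcsa_m2 > 0))
  left <- tab[tab$side == "L", ]
  right <- tab[tab$side == "R", ]
  # left/right pairs mirror through the sagittal plane: identical sagittal
  # coordinates and PCSAs
  num <- c("origin_ap", "origin_si", "insertion_ap", "insertion_si", "pcsa_m2")
  expect_equal(left[, num], right[, num], ignore_attr = TRUE)
})

test_that("attachment is affine in the geometry and rejects missing levels", {
  g <- build_sagittal_curve(29, 44, 0.45)
  fs <- attach_muscles(g)
  expect_equal(nrow(fs), nrow(default_muscle_table()))
  # straight-spine symmetry: left and right fascicles coincide sagittally
  fl <- fs[fs$side == "L", ]; fr <- fs[fs$side == "R", ]
  expect_equal(fl$o_x, fr$o_x); expect_equal(fl$i_y, fr$i_y)

  bad <- default_muscle_table()
  bad$insertion_level[1] <- "L6"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_muscle_table(path), "not part of the modeled chain")
})

test_that("extensor moment arms at L4/L5 stay in the anatomical band", {
  m <- assemble_model(list(patient_id = "uni", TK = 29, LL = 44, TH = 0.45,
                           TW = 23.3, CoM_AP = 0.03, CoM_SI = 0.21))
  p <- pose_model(m, load_case("neutral"))
  mech <- fascicle_mechanics(m, p)
  ext <- mech$fascicles$group %in% c("MF", "LTL", "IL") & mech$crosses[, "L4/L5"]
  arms <- -mech$arms[ext, "L4/L5"]  # extension arms are flexion-negative
  expect_true(all(arms >= 0.04 & arms <= 0.07))
})

test_that("moment arms equal minus the length derivative at every joint", {
  m <- ref_model()
  h <- 1e-4  # degrees
  base <- fascicle_mechanics(m, pose_model(m, load_case("neutral")))
  for (joint in c("T12/L1", "L1/L2", "L3/L4", "L5/S1")) {
    up <- fascicle_mechanics(m, pose_model(m, single_joint_case(joint, h)))
    dn <- fascicle_mechanics(m, pose_model(m, single_joint_case(joint, -h)))
    fd <- -(up$length - dn$length) / (2 * spineload:::deg2rad(h))
    expect_lt(max(abs(fd - base$arms[, joint])), 1e-6)
  }
})

test_that("taller geometries scale attachments and increase moment arms", {
  rec <- ref_record()
  arms_at <- function(th) {
    r <- rec; r$TH <- th
    m <- assemble_model(r)
    mech <- fascicle_mechanics(m, pose_model(m, load_case("neutral")))
    ext <- mech$fascicles$group %in% c("MF", "LTL", "IL") & mech$crosses[, "L4/L5"]
    mean(-mech$arms[ext, "L4/L5"])
  }
  a <- vapply(c(0.40, 0.44, 0.484), arms_at, numeric(1))
  expect_true(all(diff(a) > 0))
  expect_equal(a[3] / a[1], 0.484 / 0.40, tolerance = 1e-6)

  g1 <- build_sagittal_curve(rec$TK, rec$LL, 0.44)
  g2 <- build_sagittal_curve(rec$TK, rec$LL, 0.44 * 1.1)
  f1 <- attach_muscles(g1); f2 <- attach_muscles(g2)
  expect_equal(f2$o_x, f1$o_x * 1.1, tolerance = 1e-12)
  expect_equal(f2$i_y, f1$i_y * 1.1, tolerance = 1e-12)
})
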