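# The synthetic articulated-limb generator: templates, population
# sampling, pose application, mock sets.

test_that("templates are deterministic and scale with femur length", {
  cfg <- generator_config(n_subjects = 2)
  t1 <- make_template(cfg)
  t2 <- make_template(cfg)
  expect_identical(shape_coords(t1$limb), shape_coords(t2$limb))
  expect_setequal(unique(t1$limb$part), c("pelvis", "femur", "tibia", "foot"))
  expect_equal(unname(table(t1$limb$part)[c("pelvis", "femur", "tibia", "foot")]),
               unname(c(cfg$landmarks)), ignore_attr = TRUE)

  big <- make_template(generator_config(n_subjects = 2, femur_length = 900))
  fem1 <- shape_coords(shape_part(t1$limb, "femur"))
  fem2 <- shape_coords(shape_part(big$limb, "femur"))
  d1 <- as.vector(dist(fem1[1:20, ])); d2 <- as.vector(dist(fem2[1:20, ]))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(make_template(generator_config(n_subjects = 2,
                                              landmarks = c(pelvis = 3, femur = 10,
                                                            tibia = 10, foot = 10))),
               "at least 4")
})

test_that("joint centers lie inside the hull of their articular landmarks", {
  tpl <- make_template(generator_config(n_subjects = 2))
  set.seed(1)
  dirs <- matrix(rnorm(3 * 500), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (jn in names(tpl$joints)) {
    j <- tpl$joints[[jn]]
    ctr <- joint_center(tpl$limb, j)
    pts <- shape_coords(tpl$limb)[match(j$center_ids, tpl$limb$point_id), ]
    # directional-support oracle: an interior point projects inside the
    # support interval of the articular points along every direction
    proj_c <- dirs %*% ctr
    lo <- apply(dirs %*% t(pts), 1, min); hi <- apply(dirs %*% t(pts), 1, max)
    expect_true(all(proj_c >= lo - 1e-9 & proj_c <= hi + 1e-9))
  }
})

test_that("populations regenerate bit-identically and honour their moments", {
  cfg <- generator_config(n_subjects = 150, n_rescan_subjects = 5, seed = 99,
                          sides = "right", joints = "hip")
  p1 <- sample_population(cfg)
  p2 <- sample_population(cfg)
  expect_identical(lapply(p1$scans$limb, shape_coords),
                   lapply(p2$scans$limb, shape_coords))
  expect_identical(p1$subjects$latents, p2$subjects$latents)

  # size-latent variance matches the configured (truncated-normal) value
  z1 <- vapply(p1$subjects$latents, `[[`, 1, 1L)
  expect_lt(abs(var(z1) / p1$template$calibration$var_z1 - 1), 0.2)
  # sex ratio near 2:1
  expect_gt(mean(p1$subjects$sex == 1), 0.5)
  # pose angles independent of the size latent
  pose_flex <- vapply(seq_len(nrow(p1$scans)), function(i)
    as.numeric(p1$scans$pose[[i]]$hip)[1], 1)
  z1_scan <- z1[match(p1$scans$subject_id, p1$subjects$subject_id)]
  expect_lt(abs(cor(pose_flex, z1_scan)), 0.15)
})

test_that("neutral-alignment map is recovered by regressing angles on latents", {
  pop <- small_population()
  z1 <- vapply(pop$subjects$latents, `[[`, 1, 1L)
  for (jn in c("hip", "knee", "ankle")) {
    ang <- t(vapply(seq_len(nrow(pop$subjects)), function(i) {
      k <- which(pop$anatomy$subject_id == pop$subjects$subject_id[i] &
                   pop$anatomy$side == "right")
      as.numeric(pop$anatomy$neutral_angles[[k]][[jn]])
    }, numeric(3)))
    for (ax in 1:3) {
      fit <- lm(ang[, ax] ~ z1)
      expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)
      expect_equal(unname(coef(fit)[2]),
                   pop$config$alignment_coefficients[[jn]][ax],
                   tolerance = 1e-6)
    }
  }
})

test_that("rescan pairs share anatomy but not pose; zero-variance config collapses", {
  pop <- small_population()
  second <- pop$scans[pop$scans$scan_no == 2, ]
  expect_gt(nrow(second), 0)
  for (i in seq_len(min(4, nrow(second)))) {
    first <- pop$scans[pop$scans$subject_id == second$subject_id[i] &
                         pop$scans$side == second$side[i] & pop$scans$scan_no == 1, ]
    f1 <- shape_part(first$limb[[1]], "femur")
    f2 <- shape_part(second$limb[[i]], "femur")
    expect_lt(procrustes_align(f2, f1)$rmse, 1e-9)   # same bone geometry
    expect_false(isTRUE(all.equal(shape_coords(first$limb[[1]]),
                                  shape_coords(second$limb[[i]]))))  # pose differs
  }

  flat <- sample_population(generator_config(
    n_subjects = 3, size_sd = 0, minor_strength = 0, sex_effect_fraction = 0,
    asymmetry_sd = 0, latent_asymmetry_sd = 0, pose_limit_deg = 0,
    alignment_coefficients = list(hip = c(0, 0, 0), knee = c(0, 0, 0),
                                  ankle = c(0, 0, 0)),
    global_pose_sd = 0, global_shift_sd = 0, sides = "right",
    n_rescan_subjects = 0, seed = 1))
  ref <- shape_coords(flat$scans$limb[[1]])
  for (i in 2:3) expect_equal(shape_coords(flat$scans$limb[[i]]), ref,
                              tolerance = 1e-12)
})

test_that("apply_pose is exact, invertible and matches the measurement", {
  pop <- small_population()
  j <- pop$template$joints$knee
  con <- scan_construct(pop$anatomy$limb[[1]], j)
  expect_equal(shape_coords(apply_pose(con, j, pose_angles(0, 0, 0))),
               shape_coords(con))
  ang <- pose_angles(5, -7, 12)
  posed <- apply_pose(con, j, ang)
  # proximal untouched, distal moved
  expect_equal(shape_coords(shape_part(posed, "femur")),
               shape_coords(shape_part(con, "femur")))
  expect_gt(max(abs(shape_coords(shape_part(posed, "tibia")) -
                      shape_coords(shape_part(con, "tibia")))), 1)
  # inverse via the composed rotation
  Rinv <- t(rotation_from_euler(ang))
  back <- apply_pose(posed, j, euler_from_rotation(Rinv))
  expect_lt(max(abs(shape_coords(back) - shape_coords(con))), 1e-6)
  # measured deviation equals the applied angles (shared convention)
  m <- measure_joint_deviation(posed, con, j)
  expect_equal(as.numeric(m$angles), c(5, -7, 12), tolerance = 1e-6)
  expect_error(apply_pose(shape_part(con, "femur"), j, ang), "missing parts")
})

test_that("mock sets honour the uniform-rotation moments and limits", {
  pl <- small_pipeline()
  jf <- pl$joints$hip
  mock <- make_mock_set(jf$recoupled, jf$joint, K = 1000, limit_deg = 15,
                        seed = 31)
  A <- abs(cbind(mock$flexion, mock$abduction, mock$endorotation))
  se <- (15 / sqrt(12)) / sqrt(1000)   # SE of mean |angle|, uniform(-15,15)
  for (ax in 1:3) {
    expect_lt(abs(mean(A[, ax]) - 7.5), 3 * se)
    expect_lt(abs(sd(A[, ax]) - 15 / sqrt(12)), 0.45)
  }
  expect_true(all(A <= 15))
  # zero limit: mock equals its controls
  m0 <- make_mock_set(jf$recoupled, jf$joint, K = 5, limit_deg = 0, seed = 3)
  for (i in 1:5) expect_equal(m0$posed[[i]], m0$control[[i]], tolerance = 1e-12)
  expect_error(make_mock_set(jf$recoupled, jf$joint, K = 0), "at least 1")
})
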