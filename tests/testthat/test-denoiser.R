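# The denoising pipeline: decoupled/articulated models, regressed and
# recoupled constructs, instant prediction, joint chaining.

test_that("decoupled scores are pose invariant; first mode tracks size", {
  pop <- small_population()
  pl <- small_pipeline()
  # rescan pairs: identical bones in different poses -> identical scores
  second <- pop$scans[pop$scans$scan_no == 2, ][1:3, ]
  for (i in 1:3) {
    first <- pop$scans[pop$scans$subject_id == second$subject_id[i] &
                         pop$scans$side == second$side[i] &
                         pop$scans$scan_no == 1, ]
    for (b in c("femur", "tibia")) {
      s1 <- ssm_project(pl$bones[[b]]$model,
                        shape_coords(shape_part(first$limb[[1]], b)), align = TRUE)
      s2 <- ssm_project(pl$bones[[b]]$model,
                        shape_coords(shape_part(second$limb[[i]], b)), align = TRUE)
      expect_equal(s1, s2, tolerance = 1e-6)
    }
  }
  # femur decoupled mode 1 correlates with the generator's size latent
  popb <- default_population()
  plb <- default_pipeline()
  z1 <- vapply(popb$subjects$latents, `[[`, 1, 1L)
  z1l <- vapply(popb$subjects$latents_left, `[[`, 1, 1L)
  z_scan <- ifelse(plb$scan_index$side == "right",
                   z1[match(plb$scan_index$subject_id, popb$subjects$subject_id)],
                   z1l[match(plb$scan_index$subject_id, popb$subjects$subject_id)])
  expect_gt(abs(cor(plb$bones$femur$scores[, 1], z_scan)), 0.99)
  expect_gt(abs(cor(plb$bones$tibia$scores[, 1], z_scan)), 0.99)
})

test_that("pose noise inflates articulated variance and first-mode share drops", {
  base <- generator_config(n_subjects = 25, n_rescan_subjects = 0, seed = 13,
                           sides = "right", joints = "hip",
                           global_pose_sd = 0, global_shift_sd = 0)
  nopose <- base; nopose$pose_limit_deg <- 0
  p_pose <- sample_population(base)
  p_flat <- sample_population(nopose)
  fit_art <- function(pop) {
    shapes <- lapply(pop$scans$limb, scan_construct,
                     joint = pop$template$joints$hip)
    fit_ssm(generalized_procrustes(shapes)$aligned, variance_kept = 0.999)
  }
  m_pose <- fit_art(p_pose); m_flat <- fit_art(p_flat)
  expect_gt(sum(m_pose$eigenvalues_full), sum(m_flat$eigenvalues_full))
  expect_lt(glance(m_pose)$first_mode_variance,
            glance(m_flat)$first_mode_variance)
})

test_that("regressed constructs are pose invariant and centred", {
  pop <- small_population()
  pl <- small_pipeline()
  j <- pop$template$joints$hip
  # same anatomy under two arbitrary poses -> identical offline output
  limb <- pop$anatomy$limb[[1]]
  c1 <- apply_pose(scan_construct(limb, j), j, pose_angles(12, -8, 10))
  c2 <- apply_pose(scan_construct(limb, j), j, pose_angles(-11, 3, -14))
  d1 <- denoise(pl, c1, "hip"); d2 <- denoise(pl, c2, "hip")
  expect_lt(max(abs(shape_coords(d1) - shape_coords(d2))), 1e-6)
  # rescan pair -> identical regressed construct
  second <- pop$scans[pop$scans$scan_no == 2, ][1, ]
  first <- pop$scans[pop$scans$subject_id == second$subject_id &
                       pop$scans$side == second$side & pop$scans$scan_no == 1, ]
  r1 <- predict_neutral(pl, scan_construct(canonical_limb(pop, which(
    pop$scans$scan_id == first$scan_id)), j), "hip")
  r2 <- predict_neutral(pl, scan_construct(canonical_limb(pop, which(
    pop$scans$scan_id == second$scan_id)), j), "hip")
  expect_lt(max(abs(shape_coords(r1) - shape_coords(r2))), 1e-6)
  # a subject at the decoupled mean predicts near the articulated mean
  jf <- pl$joints$hip
  yh <- predict(jf$regressed_pls, jf$regressed_pls$x_mean, k = jf$k_star)
  expect_equal(as.vector(yh), jf$regressed_pls$y_mean, tolerance = 1e-10)
})

test_that("recoupling preserves bone geometry exactly and placement closely", {
  pop <- small_population()
  pl <- small_pipeline()
  j <- pop$template$joints$knee
  con <- scan_construct(canonical_limb(pop, 1), j)
  reg <- predict_neutral(pl, con, "knee")
  rec <- recouple(reg, con)
  # per-bone geometry identical up to a rigid transform (zero Procrustes distance)
  for (b in c("femur", "tibia")) {
    expect_lt(procrustes_align(shape_part(rec, b), shape_part(con, b))$rmse, 1e-9)
  }
  # recoupled joint angles equal regressed joint angles
  m <- measure_joint_deviation(rec, reg, j)
  expect_lt(max(abs(as.numeric(m$angles))), 0.1)
  # identity case: recoupling a construct with its own parts
  rec2 <- recouple(reg, reg)
  expect_equal(shape_coords(rec2), shape_coords(reg), tolerance = 1e-9)
  expect_error(recouple(reg, shape_part(con, "femur")), "No landmarks|Missing")
})

test_that("instant prediction approaches the offline recoupled construct", {
  pop <- small_population()
  pl <- small_pipeline()
  jf <- pl$joints$hip
  # training residual is non-increasing in the component count
  err_at <- function(k) {
    Yh <- predict(jf$instant_pls, jf$articulated_scores, k = k)
    sqrt(mean((Yh - jf$recoupled_scores)^2))
  }
  ks <- unique(pmin(c(1, 2, 5, jf$k_instant), jf$k_instant))
  errs <- vapply(ks, err_at, 1)
  expect_true(all(diff(errs) <= 1e-9))
  # instant output close to offline output (mean point error below 5% of
  # the mean bone radius ~ tens of mm)
  con <- scan_construct(canonical_limb(pop, 2), pop$template$joints$hip)
  d_off <- denoise(pl, con, "hip", method = "offline")
  d_ins <- denoise(pl, con, "hip", method = "instant")
  rmse <- sqrt(mean(rowSums((shape_coords(d_off) - shape_coords(d_ins))^2)))
  expect_lt(rmse, 2)
  expect_error(denoise(pl, con, "shoulder"), "no joint")
})

test_that("joint chaining rebuilds a neutral limb, insensitive to order", {
  pop <- default_population()
  pl <- default_pipeline()
  row <- 3
  limb <- canonical_limb(pop, row)
  ch <- chain_joints(pl, limb)
  expect_setequal(unique(ch$limb$part), c("pelvis", "femur", "tibia", "foot"))
  expect_identical(ch$limb$point_id, limb$point_id)
  # shared bones are bit-identical across joints -> near-zero residual
  expect_lt(max(ch$residuals), 1e-6)
  ch2 <- chain_joints(pl, limb, order = c("hip", "knee", "ankle"))
  f <- procrustes_align(ch2$limb, ch$limb)
  expect_lt(f$rmse, 0.1)
  # ground-truth neutral angles recovered within 1 degree at each joint
  sid <- pop$scans$subject_id[row]; side <- pop$scans$side[row]
  for (jn in c("hip", "knee", "ankle")) {
    ctl <- neutral_control(pop, sid, side, jn)
    m <- measure_joint_deviation(
      scan_construct(ch$limb, pop$template$joints[[jn]]), ctl,
      pop$template$joints[[jn]])
    expect_lt(max(abs(as.numeric(m$angles))), 1)
  }
})
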