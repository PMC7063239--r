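# Error metrics and the validation experiments.

test_that("left/right dissimilarity measures relative pose, not frame", {
  pop <- small_population()
  j <- pop$template$joints$knee
  con <- scan_construct(pop$anatomy$limb[[1]], j)   # right-side construct
  left_twin <- mirror_shape(con)                    # perfectly symmetric subject
  expect_lt(lr_dissimilarity(con, left_twin), 1e-9)

  # extra 10 degrees of left knee flexion -> residual matches the
  # brute-force whole-construct alignment oracle
  flexed <- mirror_shape(apply_pose(con, j, pose_angles(10, 0, 0)))
  d <- lr_dissimilarity(con, flexed)
  expect_gt(d, 0.5)
  oracle <- grid_procrustes_rmse(
    shape_coords(mirror_shape(flexed)), shape_coords(con))
  expect_equal(d, oracle, tolerance = 1e-3)

  # invariant to global rigid motion of either side
  expect_equal(lr_dissimilarity(rigid_move(con, 20, -30, 40, c(9, -9, 9)), flexed),
               d, tolerance = 1e-8)
  expect_equal(lr_dissimilarity(con, rigid_move(flexed, -15, 25, -35, c(4, 4, 4))),
               d, tolerance = 1e-8)
})

test_that("joint deviation measurement inverts pose application", {
  pop <- small_population()
  j <- pop$template$joints$hip
  con <- scan_construct(pop$anatomy$limb[[2]], j)
  m0 <- measure_joint_deviation(con, con, j)
  expect_equal(as.numeric(m0$angles), c(0, 0, 0), tolerance = 1e-9)
  expect_lt(m0$rmse, 1e-9)
  for (ang in list(c(5, 0, 0), c(5, -7, 12), c(-14, 9, -3))) {
    posed <- apply_pose(con, j, pose_angles(ang[1], ang[2], ang[3]))
    m <- measure_joint_deviation(posed, con, j)
    expect_equal(as.numeric(m$angles), ang, tolerance = 1e-6)
    # global rigid motion of both inputs conjugates the decomposition
    # (axes follow the control's frame) but preserves the rotation
    # magnitude and the RMSE
    m2 <- measure_joint_deviation(rigid_move(posed, 11, -7, 23, c(5, 5, 5)),
                                  rigid_move(con, 11, -7, 23, c(5, 5, 5)), j)
    rot_angle <- function(a) {
      acos(pmin(1, (sum(diag(rotation_from_euler(a))) - 1) / 2)) * 180 / pi
    }
    expect_equal(rot_angle(as.numeric(m2$angles)), rot_angle(ang),
                 tolerance = 1e-6)
    expect_equal(m2$rmse, m$rmse, tolerance = 1e-8)
  }
})

test_that("mock validation reports uniform moments before and improvement after", {
  pl <- small_pipeline()
  jf <- pl$joints$hip
  mock <- make_mock_set(jf$recoupled, jf$joint, K = 120, limit_deg = 15,
                        seed = 77)
  rep <- validate_mock(pl, mock, n_perm = 2000, seed = 2)
  ang <- rep[rep$metric != "rmse", ]
  expect_equal(ang$before_mean, rep(7.5, 3), tolerance = 1.3)
  expect_equal(ang$before_sd, rep(4.33, 3), tolerance = 1.3)
  expect_true(all(ang$after_mean < 1))
  expect_true(all(ang$after_mean < ang$before_mean))
  expect_true(all(rep$p_value < 0.001))
  # report internal consistency: means match the per-case values
  cases <- validation_cases(rep)
  expect_equal(rep$before_mean[rep$metric == "flexion"],
               mean(abs(cases$before_flexion)))
  expect_equal(rep$after_sd[rep$metric == "rmse"], sd(abs(cases$after_rmse)))
  # p-values reproduce bit-exactly for a fixed seed
  rep2 <- validate_mock(pl, mock, n_perm = 2000, seed = 2)
  expect_identical(rep$p_value, rep2$p_value)
})

test_that("rescan validation reduces within-pair deviation by >= 95 percent", {
  pop <- small_population()
  pl <- small_pipeline()
  rep <- validate_rescan(pl, pop, n_perm = 2000, seed = 4)
  expect_identical(attr(rep, "experiment"), "rescan")
  ang <- rep[rep$metric != "rmse", ]
  expect_true(all(ang$before_mean > 0))
  expect_true(all(1 - ang$after_mean / ang$before_mean >= 0.95))
  expect_true(all(rep$p_value < 0.001))
})

test_that("error-evolution curves expose pose reintroduction, not the instant path", {
  pl <- small_pipeline()
  curves <- error_evolution(pl, instant_k = c(1, 3, 5))
  reg <- curves[curves$mapping == "regressed" & curves$joint == "hip", ]
  expect_equal(reg$k, pl$joints$hip$error_curve$k)
  # regressed curve rises again beyond the selected component count
  k_star <- pl$joints$hip$k_star
  expect_gt(max(reg$lr_dissimilarity[reg$k > k_star]),
            reg$lr_dissimilarity[reg$k == k_star])
  ins <- curves[curves$mapping == "instant" & curves$joint == "hip", ]
  expect_equal(nrow(ins), 3L)
  # the instant path does not reintroduce pose: its dissimilarity stays at
  # the anatomical-asymmetry scale, far below the posed-construct scale
  pop <- small_population()
  idx <- pl$scan_index
  rsub <- which(idx$scan_no == 1 & idx$side == "right")[1:10]
  posed_dis <- vapply(rsub, function(i) {
    sid <- idx$subject_id[i]
    li <- which(pop$scans$subject_id == sid & pop$scans$side == "left" &
                  pop$scans$scan_no == 1)
    jspec <- pl$joints$hip$joint
    lr_dissimilarity(scan_construct(pop$scans$limb[[i]], jspec),
                     scan_construct(pop$scans$limb[[li]], jspec))
  }, 1)
  expect_lt(max(ins$lr_dissimilarity), 0.25 * mean(posed_dis))
})

test_that("zero-pose data give flat, near-zero validation and curves", {
  cfg <- generator_config(n_subjects = 20, n_rescan_subjects = 2, seed = 5,
                          pose_limit_deg = 0, global_pose_sd = 0,
                          global_shift_sd = 0, asymmetry_sd = 0,
                          latent_asymmetry_sd = 0, joints = "knee")
  pop <- sample_population(cfg)
  pl <- build_pipeline(pop, joints = "knee")
  rep <- validate_rescan(pl, pop, n_perm = 500, seed = 1)
  expect_true(all(rep$before_mean < 1e-6))
  expect_true(all(rep$after_mean < 1e-6))
  curve <- pl$joints$knee$error_curve$lr_dissimilarity
  expect_true(all(curve < 0.05))
})
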