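# Rigid and generalized Procrustes superimposition, mirroring and
# Euler-angle conversions.

test_that("pairwise Procrustes recovers planted transforms exactly", {
  s <- toy_shape(8, seed = 1)
  id <- procrustes_align(s, s)
  expect_lt(id$rmse, 1e-10)
  expect_equal(id$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$transform$translation, c(0, 0, 0), tolerance = 1e-10)

  tgt <- rigid_move(s, endo = 10, shift = c(5, 0, 0))
  fit <- procrustes_align(s, tgt)
  expect_lt(fit$rmse, 1e-9)
  expect_equal(fit$transform$rotation,
               rotation_from_euler(pose_angles(0, 0, 10)), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(5, 0, 0), tolerance = 1e-8)
  expect_identical(fit$transform$scale, 1)       # scaling disabled -> exactly 1
  expect_false(fit$transform$reflection_used)
})

test_that("Procrustes RMSE matches a rotation-grid brute-force oracle", {
  s <- toy_shape(8, seed = 2)
  set.seed(7)
  noisy <- shape_replace_coords(s, shape_coords(s) + matrix(rnorm(24), 8, 3))
  tgt <- rigid_move(noisy, flex = 23, abd = -11, endo = 40, shift = c(3, -8, 2))
  fit <- procrustes_align(s, tgt)
  oracle <- grid_procrustes_rmse(shape_coords(s), shape_coords(tgt))
  expect_equal(fit$rmse, oracle, tolerance = 1e-3)
  expect_lte(fit$rmse, oracle + 1e-6)  # SVD solution is the global optimum
})

test_that("Procrustes residual is invariant under rigid pre-transforms", {
  s <- toy_shape(10, seed = 3)
  set.seed(8)
  t0 <- shape_replace_coords(s, shape_coords(s) + matrix(rnorm(30), 10, 3))
  base <- procrustes_align(s, t0)$rmse
  for (i in 1:5) {
    ang <- runif(3, -90, 90); sh <- rnorm(3, sd = 50)
    expect_equal(procrustes_align(rigid_move(s, ang[1], ang[2], ang[3], sh), t0)$rmse,
                 base, tolerance = 1e-8)
    expect_equal(procrustes_align(s, rigid_move(t0, ang[1], ang[2], ang[3], sh))$rmse,
                 base, tolerance = 1e-8)
  }
})

test_that("degenerate configurations are refused", {
  line <- landmark_shape(cbind(1:6, 2 * (1:6), 3 * (1:6)))
  expect_error(procrustes_align(line, line), "collinear|coincident")
  a <- toy_shape(6, seed = 1)
  b <- toy_shape(7, seed = 1)
  expect_error(procrustes_align(a, b), "mismatched point sets")
})

test_that("similarity mode recovers a planted scale; vegan cross-check", {
  s <- toy_shape(9, seed = 4)
  tgt <- shape_replace_coords(s, 1.7 * shape_coords(rigid_move(s, flex = 15)))
  fit <- procrustes_align(s, tgt, allow_scale = TRUE)
  expect_equal(fit$transform$scale, 1.7, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  skip_if_not_installed("vegan")
  set.seed(9)
  t2 <- shape_replace_coords(s, 1.3 * shape_coords(s) + matrix(rnorm(27), 9, 3))
  fit2 <- procrustes_align(s, t2, allow_scale = TRUE)
  vg <- vegan::procrustes(shape_coords(t2), shape_coords(s),
                          scale = TRUE, symmetric = FALSE)
  expect_equal(sqrt(vg$ss / 9), fit2$rmse, tolerance = 1e-6)
})

test_that("generalized Procrustes aligns, converges and is idempotent", {
  s <- toy_shape(8, seed = 5)
  g <- generalized_procrustes(list(rigid_move(s, 30, -10, 5, c(10, 0, 0)),
                                   rigid_move(s, -20, 15, -40, c(0, 5, -5))))
  expect_lt(tail(g$residual_history, 1), 1e-8)
  expect_lt(max(abs(shape_coords(g$aligned[[1]]) - shape_coords(g$aligned[[2]]))),
            1e-6)
  expect_identical(shape_frame(g$aligned[[1]]), "gpa-aligned")

  # perturbed copies: consensus matches the template up to alignment, and
  # re-running on aligned output converges immediately with no change
  set.seed(10)
  shapes <- lapply(1:10, function(i) {
    p <- shape_replace_coords(s, shape_coords(s) + matrix(rnorm(24, sd = 0.05), 8, 3))
    rigid_move(p, runif(1, -40, 40), runif(1, -30, 30), runif(1, -40, 40),
               rnorm(3, sd = 20))
  })
  g2 <- generalized_procrustes(shapes)
  expect_true(all(diff(g2$residual_history) <= 1e-12))  # monotone
  f <- procrustes_align(g2$consensus, s)
  expect_lt(f$rmse, 0.05)  # consensus ~ template at noise scale / sqrt(n)
  g3 <- generalized_procrustes(g2$aligned)
  expect_lte(g3$n_iter, 2L)
  expect_equal(shape_coords(g3$consensus), shape_coords(g2$consensus),
               tolerance = 1e-6)

  # fixed-point oracle: independent align-to-mean iteration reaches the
  # same consensus
  mats <- lapply(shapes, shape_coords)
  cons <- mats[[1]]
  for (it in 1:60) {
    al <- lapply(mats, function(m) procrustes_align(
      landmark_shape(m), landmark_shape(cons))$aligned)
    cons <- Reduce(`+`, lapply(al, shape_coords)) / length(al)
  }
  f2 <- procrustes_align(landmark_shape(cons, point_id = s$point_id),
                         g2$consensus)
  expect_lt(f2$rmse, 1e-5)
})

test_that("mirroring is an involution and maps symmetric shapes to themselves", {
  s <- toy_shape(8, seed = 6)
  expect_equal(shape_coords(mirror_shape(mirror_shape(s))), shape_coords(s))
  expect_identical(shape_side(mirror_shape(s)), "left")

  # a shape symmetric under the pairing map
  co <- rbind(c(1, 2, 3), c(-1, 2, 3), c(4, -1, 0), c(-4, -1, 0),
              c(2, 5, 1), c(-2, 5, 1))
  sym <- landmark_shape(co, point_id = c("a1", "a2", "b1", "b2", "c1", "c2"))
  map <- c(a1 = "a2", a2 = "a1", b1 = "b2", b2 = "b1", c1 = "c2", c2 = "c1")
  expect_equal(shape_coords(mirror_shape(sym, map)), shape_coords(sym),
               tolerance = 1e-12)
  bad <- c(a1 = "a2", a2 = "a2", b1 = "b2", b2 = "b1", c1 = "c2", c2 = "c1")
  expect_error(mirror_shape(sym, bad), "bijection")
})

test_that("Euler round trips match the quaternion oracle and flag gimbal lock", {
  expect_equal(rotation_from_euler(pose_angles(0, 0, 0)), diag(3),
               tolerance = 1e-15)
  expect_equal(as.numeric(euler_from_rotation(rotation_from_euler(
    pose_angles(10, 0, 0)))), c(10, 0, 0), tolerance = 1e-9)

  cases <- rbind(c(5, -7, 12), c(-55, 40, 60), c(0.01, -0.02, 0.03),
                 c(30, -60, -45))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, ]
    R <- rotation_from_euler(a)
    expect_equal(R, quat_rotation_yxz(a[1], a[2], a[3]), tolerance = 1e-12)
    expect_equal(as.numeric(euler_from_rotation(R)), a, tolerance = 1e-9)
  }
  # round-trip error < 1e-9 deg over the working range
  set.seed(11)
  for (i in 1:25) {
    a <- runif(3, -60, 60)
    expect_equal(as.numeric(euler_from_rotation(rotation_from_euler(a))), a,
                 tolerance = 1e-9)
  }
  g <- euler_from_rotation(rotation_from_euler(pose_angles(25, 90, 10)))
  expect_true(attr(g, "gimbal_lock"))
  expect_equal(as.numeric(g)[3], 0)  # documented tie-break
  expect_error(euler_from_rotation(matrix(2 * diag(3), 3)), "orthonormal")
})
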