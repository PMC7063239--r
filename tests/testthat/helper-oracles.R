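# Independent oracles and shared fixtures for the test suite.

# --- brute-force rotation-grid Procrustes oracle ---------------------------
# SVD-free minimisation of the rigid-superimposition RMSE over a
# coarse-to-fine grid of Euler rotations (translation handled by centering).
grid_procrustes_rmse <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  best <- c(0, 0, 0); bestv <- Inf
  eval_rmse <- function(a) {
    R <- rotation_from_euler(a)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  steps <- c(12, 2, 0.4, 0.08, 0.016, 0.0032)
  span <- c(180, 24, 4, 0.8, 0.16, 0.032)
  for (lvl in seq_along(steps)) {
    grid <- seq(-span[lvl], span[lvl], by = steps[lvl])
    for (a1 in best[1] + grid) for (a2 in best[2] + grid) for (a3 in best[3] + grid) {
      v <- eval_rmse(c(a1, a2, a3))
      if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
    }
    span[lvl + 1] <- steps[lvl] * 2
  }
  bestv
}

# --- quaternion oracle for Euler composition --------------------------------
quat_from_axis <- function(axis, angle_deg) {
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}
quat_mult <- function(q, r) {
  c(q[1] * r[1] - sum(q[2:4] * r[2:4]),
    q[1] * r[2:4] + r[1] * q[2:4] + c(
      q[3] * r[4] - q[4] * r[3],
      q[4] * r[2] - q[2] * r[4],
      q[2] * r[3] - q[3] * r[2]))
}
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
quat_rotation_yxz <- function(flex, abd, endo) {
  q <- quat_mult(quat_mult(quat_from_axis(c(0, 1, 0), flex),
                           quat_from_axis(c(1, 0, 0), abd)),
                 quat_from_axis(c(0, 0, 1), endo))
  quat_to_matrix(q)
}

# --- small shape fixtures ---------------------------------------------------
toy_shape <- function(n = 8, seed = 1, part = "bone") {
  set.seed(seed)
  landmark_shape(matrix(rnorm(n * 3, sd = 10), n, 3),
                 point_id = sprintf("p%02d", seq_len(n)), part = part)
}

rigid_move <- function(shape, flex = 0, abd = 0, endo = 0, shift = c(0, 0, 0)) {
  tr <- limb_transform(rotation = rotation_from_euler(c(flex, abd, endo)),
                       translation = shift)
  apply_transform(tr, shape)
}

# --- shared fixtures (built once per test run) ------------------------------
.fixtures <- new.env(parent = emptyenv())

small_population <- function() {
  if (is.null(.fixtures$small_pop)) {
    .fixtures$small_pop <- sample_population(
      generator_config(n_subjects = 40, n_rescan_subjects = 10, seed = 42))
  }
  .fixtures$small_pop
}

small_pipeline <- function() {
  if (is.null(.fixtures$small_pl)) {
    .fixtures$small_pl <- build_pipeline(small_population())
  }
  .fixtures$small_pl
}

default_population <- function() {
  if (is.null(.fixtures$big_pop)) {
    .fixtures$big_pop <- sample_population(generator_config(seed = 11))
  }
  .fixtures$big_pop
}

default_pipeline <- function() {
  if (is.null(.fixtures$big_pl)) {
    .fixtures$big_pl <- build_pipeline(default_population())
  }
  .fixtures$big_pl
}

# posed scan limb in the canonical (right) frame
canonical_limb <- function(population, row) {
  limb <- population$scans$limb[[row]]
  if (shape_side(limb) == "left") limb <- mirror_shape(limb) else limb
}
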