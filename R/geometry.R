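#' Rigid / similarity transforms
#'
#' A `limb_transform` applies to a point `p` (column convention) as
#' `s * R %*% p + t`; on an n-by-3 coordinate matrix `X` that is
#' `s * X %*% t(R) + t` row-wise.
#'
#' @param rotation 3-by-3 orthonormal matrix.
#' @param translation Length-3 numeric (mm).
#' @param scale Positive scalar (1 when scaling is disabled).
#' @param reflection_used Whether `rotation` has determinant -1.
#' @return A `limb_transform` object.
#' @export
limb_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1, reflection_used = FALSE) {
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            scale > 0)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale, reflection_used = isTRUE(reflection_used)),
            class = "limb_transform")
}

#' @export
print.limb_transform <- function(x, ...) {
  ang <- euler_from_rotation(if (x$reflection_used) -x$rotation else x$rotation)
  cat(sprintf(
    "<limb_transform: scale %.4f, translation (%.2f, %.2f, %.2f) mm,%s angles (%.2f, %.2f, %.2f) deg>\n",
    x$scale, x$translation[1], x$translation[2], x$translation[3],
    if (x$reflection_used) " reflected," else "",
    ang[1], ang[2], ang[3]))
  invisible(x)
}

#' Apply a rigid/similarity transform to a shape or coordinate matrix
#'
#' @param transform A [limb_transform()].
#' @param shape A `limb_shape` or an n-by-3 matrix.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(transform, shape) {
  if (is.matrix(shape)) return(transform_coords(transform, shape))
  shape_replace_coords(shape, transform_coords(transform, shape_coords(shape)))
}

transform_coords <- function(tr, m) {
  sweep(tr$scale * m %*% t(tr$rotation), 2L, -tr$translation)
}

# Kabsch core on centered matrices; returns list(rotation, scale, reflection)
kabsch <- function(Xc, Yc, allow_scale = FALSE, allow_reflection = FALSE) {
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  reflection_used <- FALSE
  sig <- rep(1, 3)
  if (d < 0) {
    if (allow_reflection) reflection_used <- TRUE else sig[3] <- -1
  }
  R <- sv$v %*% diag(sig) %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * sig) / sum(Xc^2) else 1
  list(rotation = R, scale = s, reflection_used = reflection_used)
}

# matrix-level Procrustes; source/target n x 3; returns transform + aligned + rmse
procrustes_core <- function(X, Y, allow_scale = FALSE, allow_reflection = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  svx <- svd(Xc, nu = 0, nv = 0)$d
  if (svx[2] <= max(svx[1], 1) * 1e-12) {
    abort("Degenerate landmark configuration (points collinear or coincident): rotation is not identifiable.")
  }
  k <- kabsch(Xc, Yc, allow_scale = allow_scale,
              allow_reflection = allow_reflection)
  tr <- limb_transform(rotation = k$rotation,
                       translation = cy - k$scale * as.vector(k$rotation %*% cx),
                       scale = k$scale, reflection_used = k$reflection_used)
  aligned <- transform_coords(tr, X)
  rmse <- sqrt(mean(rowSums((aligned - Y)^2)))
  list(transform = tr, aligned = aligned, rmse = rmse)
}

#' Ordinary (pairwise) Procrustes superimposition
#'
#' Finds the rigid (optionally similarity) transform minimising the sum of
#' squared distances between corresponding landmarks of `source` and
#' `target`, via the SVD (Kabsch) solution.
#'
#' @param source,target `limb_shape` objects with identical point sets.
#' @param allow_scale Estimate a uniform scale factor (default `FALSE`:
#'   size is biologically meaningful and kept).
#' @param allow_reflection Permit an improper rotation (default `FALSE`;
#'   reflections are reserved for [mirror_shape()]).
#' @return A list with elements `transform` ([limb_transform()]), `aligned`
#'   (the transformed source shape, frame tagged as the target's) and
#'   `rmse` (root-mean-square residual per landmark, mm).
#' @examples
#' s <- landmark_shape(matrix(rnorm(24), 8, 3))
#' fit <- procrustes_align(s, s)
#' fit$rmse  # 0
#' @export
procrustes_align <- function(source, target, allow_scale = FALSE,
                             allow_reflection = FALSE) {
  check_same_points(source, target)
  res <- procrustes_core(shape_coords(source), shape_coords(target),
                         allow_scale = allow_scale,
                         allow_reflection = allow_reflection)
  aligned <- shape_replace_coords(source, res$aligned,
                                  frame = shape_frame(target))
  list(transform = res$transform, aligned = aligned, rmse = res$rmse)
}

# GPA on a list of n x 3 matrices. Scaling (if enabled) rescales each shape
# to the consensus via the similarity Procrustes fit; the consensus keeps the
# mean centroid size of the input so coordinates stay in mm.
gpa_core <- function(mats, allow_scale = FALSE, tol = 1e-8, max_iter = 100L) {
  nsh <- length(mats)
  if (nsh < 2L) abort("Generalized Procrustes needs at least 2 shapes.")
  # initial consensus: mean of centred shapes, so that already-aligned
  # input converges in a single iteration; fall back to the first shape
  # when random orientations cancel the mean out
  centred <- lapply(mats, function(m) sweep(m, 2L, colMeans(m)))
  cons <- Reduce(`+`, centred) / nsh
  if (sqrt(sum(cons^2)) < 0.1 * sqrt(sum(centred[[1L]]^2))) {
    cons <- centred[[1L]]
  }
  aligned <- mats
  resid_hist <- numeric(0)
  n_iter <- 0L
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    tot <- 0
    for (i in seq_len(nsh)) {
      f <- procrustes_core(mats[[i]], cons, allow_scale = allow_scale)
      aligned[[i]] <- f$aligned
      tot <- tot + f$rmse^2
    }
    resid_hist <- c(resid_hist, sqrt(tot / nsh))
    new_cons <- Reduce(`+`, aligned) / nsh
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    change <- sqrt(mean(rowSums((new_cons - cons)^2)))
    cons <- new_cons
    if (change < tol) { converged <- TRUE; break }
    prev_rms <- resid_hist[it]
  }
  if (!converged) {
    warn(sprintf("Generalized Procrustes did not converge in %d iterations (last consensus change above tol).",
                 max_iter))
  }
  # final pass so every shape is aligned to the reported consensus
  for (i in seq_len(nsh)) {
    aligned[[i]] <- procrustes_core(mats[[i]], cons,
                                    allow_scale = allow_scale)$aligned
  }
  list(aligned = aligned, consensus = cons, n_iter = n_iter,
       residual_history = resid_hist, converged = converged)
}

#' Generalized Procrustes alignment of many shapes
#'
#' Iteratively superimposes all shapes onto their evolving consensus (mean)
#' configuration, removing translation and rotation (and, optionally, scale)
#' until the consensus stabilises. The total residual is non-increasing
#' across iterations.
#'
#' @param shapes List of `limb_shape` objects with identical point sets.
#' @inheritParams procrustes_align
#' @param tol Convergence tolerance on the RMS change of the consensus (mm).
#' @param max_iter Maximum number of iterations; non-convergence is reported
#'   with a warning, not an error.
#' @return A list with `aligned` (list of shapes, frame `"gpa-aligned"`),
#'   `consensus` (mean shape), `n_iter`, `residual_history` and `converged`.
#' @export
generalized_procrustes <- function(shapes, allow_scale = FALSE, tol = 1e-8,
                                   max_iter = 100L) {
  if (length(shapes) == 0L) abort("Empty shape list.")
  for (s in shapes[-1L]) check_same_points(shapes[[1L]], s)
  res <- gpa_core(lapply(shapes, shape_coords), allow_scale = allow_scale,
                  tol = tol, max_iter = max_iter)
  aligned <- map2(shapes, res$aligned, function(s, m) {
    shape_replace_coords(s, m, frame = "gpa-aligned")
  })
  consensus <- shape_replace_coords(shapes[[1L]], res$consensus,
                                    frame = "gpa-aligned")
  list(aligned = aligned, consensus = consensus, n_iter = res$n_iter,
       residual_history = res$residual_history, converged = res$converged)
}

#' Mirror a shape across the sagittal plane
#'
#' Reflects coordinates (`x` to `-x` in the template frame), re-pairs
#' landmarks through `relabel_map` (a named character vector mapping each
#' point_id to its contralateral homologue; identity by default, which is
#' appropriate for dense quasi-landmarks without cross-midline structure)
#' and toggles the side flag. Applying it twice returns the input.
#'
#' @param shape A `limb_shape`.
#' @param relabel_map Named character vector (`new_id = old_id` pairing);
#'   must be a bijection on the point ids. `NULL` for identity.
#' @return The mirrored `limb_shape`.
#' @export
mirror_shape <- function(shape, relabel_map = NULL) {
  m <- shape_coords(shape)
  m[, 1] <- -m[, 1]
  if (!is.null(relabel_map)) {
    ids <- shape$point_id
    if (!setequal(names(relabel_map), ids) ||
        !setequal(unname(relabel_map), ids) ||
        anyDuplicated(unname(relabel_map))) {
      abort("`relabel_map` must be a bijection on the shape's point_ids.")
    }
    # landmark `p` takes the reflected coordinates of its partner
    m <- m[match(unname(relabel_map[ids]), ids), , drop = FALSE]
  }
  out <- shape_replace_coords(shape, m)
  attr(out, "side") <- if (shape_side(shape) == "right") "left" else "right"
  out
}

# --- Euler angles -----------------------------------------------------------

#' Euler-angle pose convention
#'
#' Angles follow the clinical naming of lower-limb joint kinematics in a
#' template frame with +X anterior, +Y subject-left (medio-lateral) and +Z
#' superior: flexion is rotation about Y, abduction about X, endorotation
#' about Z, composed in the intrinsic order Y.X.Z, i.e.
#' `R = Ry(flexion) Rx(abduction) Rz(endorotation)`. All angles in degrees.
#'
#' @param flexion,abduction,endorotation Angles in degrees.
#' @return A `pose_angles` named numeric vector with a `convention`
#'   attribute (`"YXZ-intrinsic"`).
#' @export
pose_angles <- function(flexion = 0, abduction = 0, endorotation = 0) {
  structure(c(flexion = flexion, abduction = abduction,
              endorotation = endorotation),
            convention = "YXZ-intrinsic", class = "pose_angles")
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from flexion/abduction/endorotation angles
#'
#' @param angles A [pose_angles()] vector (degrees), or a numeric length-3
#'   vector in the order flexion, abduction, endorotation.
#' @return 3-by-3 rotation matrix (`Ry(flex) Rx(abd) Rz(endo)`).
#' @export
rotation_from_euler <- function(angles) {
  a <- deg2rad(as.numeric(angles))
  rot_y(a[1]) %*% rot_x(a[2]) %*% rot_z(a[3])
}

#' Decompose a rotation matrix into pose angles
#'
#' Inverse of [rotation_from_euler()] under the declared Y.X.Z intrinsic
#' convention. Near gimbal lock (|abduction| -> 90 deg) flexion and
#' endorotation are not separable; the tie-break sets endorotation to 0 and
#' assigns the remaining rotation to flexion, and the result is flagged.
#'
#' @param rotation 3-by-3 orthonormal matrix with determinant +1.
#' @return A [pose_angles()] vector; attribute `gimbal_lock` is `TRUE` when
#'   the tie-break was used.
#' @export
euler_from_rotation <- function(rotation) {
  R <- rotation
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6) {
    abort("`rotation` must be orthonormal with determinant +1.")
  }
  sb <- -R[2, 3]
  sb <- min(1, max(-1, sb))
  gimbal <- abs(sb) > 1 - 1e-10
  if (gimbal) {
    b <- asin(sb)
    cang <- 0
    aang <- atan2(-R[3, 1], R[1, 1])
  } else {
    b <- asin(sb)
    aang <- atan2(R[1, 3], R[3, 3])
    cang <- atan2(R[2, 1], R[2, 2])
  }
  out <- pose_angles(rad2deg(aang), rad2deg(b), rad2deg(cang))
  attr(out, "gimbal_lock") <- gimbal
  out
}
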