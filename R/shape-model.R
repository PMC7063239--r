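#' Fit a point-distribution (statistical) shape model
#'
#' Models GPA-aligned landmark configurations as `S = Sbar + P b`: the mean
#' shape plus a linear combination of orthonormal eigenvectors of the sample
#' covariance of the flattened coordinates. Eigenvectors are computed from
#' the SVD of the centred data matrix (numerically stable), the covariance
#' divisor is n - 1, and each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param aligned List of GPA-aligned `limb_shape` objects (frame
#'   `"gpa-aligned"` or `"template"`), or a numeric n-by-3p matrix of
#'   flattened coordinates (then `meta` must describe the landmarks).
#' @param variance_kept Fraction of total variance the retained modes must
#'   cover (default 0.98). Ignored when `t` is given.
#' @param t Retained mode count (overrides `variance_kept`).
#' @param meta Optional list with `point_id`, `part`, `side`, used when
#'   `aligned` is a matrix.
#' @return A `limb_ssm` object: `mean` (flattened, mm), `components`
#'   (3p-by-t orthonormal), `eigenvalues` (retained, mm^2),
#'   `eigenvalues_full` (all non-trivial), `t`, `n_train` and landmark
#'   metadata.
#' @export
fit_ssm <- function(aligned, variance_kept = 0.98, t = NULL, meta = NULL) {
  if (is.matrix(aligned)) {
    X <- aligned
    if (is.null(meta)) abort("`meta` is required when fitting from a matrix.")
  } else {
    if (length(aligned) < 2L) abort("Need at least 2 shapes to fit a model.")
    fr <- shape_frame(aligned[[1L]])
    if (!fr %in% c("gpa-aligned", "template", "model")) {
      abort(sprintf("Shapes must be aligned before model fitting (frame is '%s'; run generalized_procrustes()).", fr))
    }
    for (s in aligned[-1L]) check_same_points(aligned[[1L]], s)
    X <- do.call(rbind, lapply(aligned, function(s) flatten_coords(shape_coords(s))))
    meta <- list(point_id = aligned[[1L]]$point_id,
                 part = aligned[[1L]]$part, side = shape_side(aligned[[1L]]))
  }
  n <- nrow(X)
  if (n < 2L) abort("Need at least 2 training shapes.")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  nz <- ev > max(ev[1], .Machine$double.eps) * 1e-12
  if (!any(nz)) { ev <- ev[1]; nz <- TRUE }
  ev_full <- ev[nz]
  V <- sv$v[, nz, drop = FALSE]
  if (is.null(t)) {
    frac <- cumsum(ev_full) / sum(ev_full)
    t <- which(frac >= variance_kept - 1e-12)[1L]
  }
  t <- min(t, length(ev_full))
  V <- V[, seq_len(t), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(t)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = mu, components = V,
                 eigenvalues = ev_full[seq_len(t)],
                 eigenvalues_full = ev_full, t = t, n_train = n,
                 variance_kept = variance_kept,
                 point_id = meta$point_id, part = meta$part,
                 side = meta$side %||% "right"),
            class = "limb_ssm")
}

#' @export
print.limb_ssm <- function(x, ...) {
  cat(sprintf(
    "<limb_ssm: %d landmarks (%s), %d training shapes, %d/%d modes (%.1f%% variance)>\n",
    length(x$point_id), paste(unique(x$part), collapse = "+"), x$n_train,
    x$t, length(x$eigenvalues_full),
    100 * sum(x$eigenvalues) / sum(x$eigenvalues_full)))
  invisible(x)
}

model_mean_shape <- function(model, frame = "model") {
  landmark_shape(unflatten_coords(model$mean), point_id = model$point_id,
                 part = model$part, side = model$side, frame = frame)
}

# align a shape (or coords) rigidly to the model mean; returns flattened vector
align_to_model <- function(model, shape, allow_scale = FALSE) {
  m <- if (is.matrix(shape)) shape else shape_coords(shape)
  target <- unflatten_coords(model$mean)
  flatten_coords(procrustes_core(m, target, allow_scale = allow_scale)$aligned)
}

#' Project a shape into a model's score space
#'
#' The score vector is the orthogonal projection `b = P' (S - Sbar)`.
#'
#' @param model A `limb_ssm`.
#' @param shape A `limb_shape` in the model's frame, or an n-by-3 matrix.
#' @param align Rigidly superimpose the shape on the model mean first
#'   (default `FALSE`: the shape is assumed already in the model frame).
#' @return Numeric score vector of length `model$t`.
#' @export
ssm_project <- function(model, shape, align = FALSE) {
  v <- if (align) align_to_model(model, shape) else {
    m <- if (is.matrix(shape)) shape else shape_coords(shape)
    flatten_coords(m)
  }
  if (length(v) != length(model$mean)) abort("Dimension mismatch between shape and model.")
  as.vector(crossprod(model$components, v - model$mean))
}

#' Reconstruct a shape from model scores
#'
#' Computes `S = Sbar + P b` exactly. Missing trailing scores are taken as 0.
#'
#' @param model A `limb_ssm`.
#' @param b Numeric score vector (length at most `model$t`).
#' @return A `limb_shape` in the model frame.
#' @export
ssm_reconstruct <- function(model, b) {
  if (length(b) > model$t) abort("Score vector longer than the model's mode count.")
  if (length(b) < model$t) b <- c(b, rep(0, model$t - length(b)))
  v <- model$mean + as.vector(model$components %*% b)
  landmark_shape(unflatten_coords(v), point_id = model$point_id,
                 part = model$part, side = model$side, frame = "model")
}

# rows of scores for a data matrix already in model frame
ssm_project_rows <- function(model, X) {
  sweep(X, 2L, model$mean) %*% model$components
}
ssm_reconstruct_rows <- function(model, B) {
  sweep(B %*% t(model$components), 2L, -model$mean)
}

#' Cumulative explained-variance (compactness) curve
#'
#' @param model A `limb_ssm`.
#' @return A tibble with `n_modes`, `eigenvalue`, `prop_variance` and
#'   `cumulative_variance` over all non-trivial modes (ends at 1).
#' @export
compactness_curve <- function(model) {
  ev <- model$eigenvalues_full
  tibble(n_modes = seq_along(ev), eigenvalue = ev,
         prop_variance = ev / sum(ev),
         cumulative_variance = cumsum(ev) / sum(ev))
}

#' Percentage of data variance a model cannot explain
#'
#' Each datum is rigidly superimposed on the model mean (no scaling), and
#' the residual after orthogonal projection onto the model's retained modes
#' is accumulated. The statistic is `100 * RSS / total`, where `total` is
#' the variance of the (aligned) data about its own mean. Applied to
#' articulated-construct data against the recoupled model it estimates the
#' fraction of apparent shape variance that is positional noise.
#'
#' @param data List of `limb_shape` objects (or n-by-3 matrices) with the
#'   model's landmark definition.
#' @param model A `limb_ssm`.
#' @param align Superimpose each datum on the model first (default `TRUE`;
#'   without alignment the statistic conflates frame offsets with shape).
#'   Alignment starts at the model mean and is refined against the datum's
#'   own model reconstruction (fixed-point, `align_iter` passes), so that
#'   a datum far from the mean is not penalised for its alignment to it.
#' @param align_iter Alignment refinement passes.
#' @return Percent (0-100).
#' @export
unexplained_variance <- function(data, model, align = TRUE, align_iter = 3L) {
  if (length(data) == 0L) abort("Empty data.")
  V <- vapply(data, function(s) {
    m <- if (is.matrix(s)) s else shape_coords(s)
    if (!align) return(flatten_coords(m))
    target <- unflatten_coords(model$mean)
    for (it in seq_len(align_iter)) {
      v <- flatten_coords(procrustes_core(m, target)$aligned)
      b <- as.vector(crossprod(model$components, v - model$mean))
      target <- unflatten_coords(model$mean + as.vector(model$components %*% b))
    }
    v
  }, numeric(length(model$mean)))
  V <- t(V)
  D <- sweep(V, 2L, model$mean)
  resid <- D - (D %*% model$components) %*% t(model$components)
  rss <- sum(resid^2)
  total <- sum(sweep(V, 2L, colMeans(V))^2)
  100 * rss / total
}
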