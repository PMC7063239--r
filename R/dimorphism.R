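# Sexual-dimorphism analysis on (pose-corrected) shape models: canonical
# correlation, PLSR explained variance, amplified effect shapes and
# per-landmark permutation significance.

#' Sex-shape association analysis on a shape model's score space
#'
#' Canonical correlation analysis between the first `n_pcs` PC scores and
#' the binary sex label gives the correlation `r` (with a seeded
#' permutation p-value); a one-component PLS regression gives the percent
#' of shape variance the label explains.
#'
#' @param model The `limb_ssm` the scores come from.
#' @param scores Score matrix (rows match `sex`), raw (unstandardised) PC
#'   scores.
#' @param sex Labels: +1 male / -1 female (or any two-level coding).
#' @param n_pcs Number of leading PCs to use (default 20, capped at the
#'   model's mode count).
#' @param n_perm Label permutations for the p-value of `r`.
#' @param seed Permutation seed.
#' @return A `limb_dimorphism` object: `r`, `p_value`, `percent_variance`,
#'   score-space `weights` and `loadings`, canonical `scores`, `n_pcs`.
#' @export
sex_shape_analysis <- function(model, scores, sex, n_pcs = 20L,
                               n_perm = 1000L, seed = 1L) {
  scores <- as.matrix(scores)
  n_pcs <- min(n_pcs, ncol(scores), model$t)
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  cca <- fit_cca(X, sex)
  y <- cca$y
  p_value <- with_seed(substream_seed(seed, "cca-perm"), {
    rs <- vapply(seq_len(n_perm), function(i) fit_cca(X, sample(y))$r, 1)
    (1 + sum(rs >= cca$r)) / (n_perm + 1)
  })
  percent <- plsr_explained_variance(X, y)
  structure(list(model = model, r = cca$r, p_value = p_value,
                 percent_variance = percent, weights = cca$weights,
                 loadings = cca$loadings, cov_xu = cca$cov_xu,
                 x_mean = cca$x_mean, scores = cca$scores, y = y,
                 n_pcs = n_pcs, n = length(y)),
            class = "limb_dimorphism")
}

#' @export
print.limb_dimorphism <- function(x, ...) {
  cat(sprintf(
    "<limb_dimorphism: r = %.3f (p = %.4g), sex explains %.1f%% of shape variance over %d PCs, n = %d>\n",
    x$r, x$p_value, x$percent_variance, x$n_pcs, x$n))
  invisible(x)
}

#' Amplified male/female effect shapes and per-landmark displacement
#'
#' Reconstructs the model shape at the group-average canonical scores
#' amplified by a factor (default 2), along the canonical loading
#' direction in score space. With size correction both effect shapes are
#' rescaled to the common mean centroid size before differencing, so the
#' displacement map reflects shape rather than overall size.
#'
#' @param model The `limb_ssm` (same model as the analysis).
#' @param result A [sex_shape_analysis()] result.
#' @param amplification Positive amplification factor.
#' @param size_correct Normalise centroid size before differencing.
#' @return A `limb_sex_effect` list: `male`, `female` (`limb_shape`s) and
#'   `displacement` (tibble `point_id`, `part`, `displacement_mm`).
#' @export
sex_effect_shapes <- function(model, result, amplification = 2,
                              size_correct = TRUE) {
  if (amplification < 0) abort("`amplification` must be non-negative.")
  ubar_m <- mean(result$scores[result$y > 0])
  ubar_f <- mean(result$scores[result$y < 0])
  # E[scores | canonical variate u] = x_mean + cov(scores, u) * u, with u
  # at unit variance, so cov_xu is the score-space slope
  build <- function(u) {
    b <- numeric(model$t)
    b[seq_len(result$n_pcs)] <- result$x_mean + result$cov_xu * u
    ssm_reconstruct(model, b)
  }
  shape_m <- build(amplification * ubar_m)
  shape_f <- build(amplification * ubar_f)
  if (size_correct) {
    cs <- function(s) {
      m <- shape_coords(s); sqrt(sum(sweep(m, 2L, colMeans(m))^2))
    }
    target <- mean(c(cs(shape_m), cs(shape_f)))
    rescale <- function(s) {
      m <- shape_coords(s); c0 <- colMeans(m)
      shape_replace_coords(s, sweep(sweep(m, 2L, c0) * (target / cs(s)),
                                    2L, -c0))
    }
    shape_m <- rescale(shape_m); shape_f <- rescale(shape_f)
  }
  disp <- sqrt(rowSums((shape_coords(shape_m) - shape_coords(shape_f))^2))
  structure(list(male = shape_m, female = shape_f,
                 displacement = tibble(point_id = shape_m$point_id,
                                       part = shape_m$part,
                                       displacement_mm = disp),
                 amplification = amplification,
                 size_correct = size_correct),
            class = "limb_sex_effect")
}

#' Per-landmark permutation significance of the sex effect
#'
#' For each landmark the statistic is the Euclidean distance between the
#' male and female mean positions (on aligned shapes); significance comes
#' from a label-permutation test with Benjamini-Hochberg FDR correction
#' across landmarks. Bit-reproducible for a fixed seed.
#'
#' @param shapes List of GPA-aligned `limb_shape`s (or an n-by-3p matrix of
#'   flattened aligned coordinates with `meta`).
#' @param sex Labels as in [sex_shape_analysis()].
#' @param n_perm Number of permutations (at least 100).
#' @param seed Permutation seed.
#' @param meta Landmark metadata when `shapes` is a matrix.
#' @return Tibble with `point_id`, `part`, `effect_mm`, `p_value`,
#'   `q_value`.
#' @export
landmark_significance <- function(shapes, sex, n_perm = 1000L, seed = 1L,
                                  meta = NULL) {
  if (n_perm < 100L) abort("Use at least 100 permutations.")
  if (is.matrix(shapes)) {
    X <- shapes
    if (is.null(meta)) abort("`meta` required with a matrix input.")
  } else {
    X <- do.call(rbind, lapply(shapes, function(s) flatten_coords(shape_coords(s))))
    meta <- list(point_id = shapes[[1L]]$point_id, part = shapes[[1L]]$part)
  }
  if (is.factor(sex) || is.character(sex)) {
    lev <- sort(unique(as.character(sex)))
    if (length(lev) != 2L) abort("`sex` must have two classes.")
    sex <- ifelse(as.character(sex) == lev[2L], 1, -1)
  }
  if (length(unique(sex)) < 2L) abort("Both sexes must be present.")
  n <- nrow(X)
  per_landmark <- function(y) {
    im <- y > 0
    d <- colMeans(X[im, , drop = FALSE]) - colMeans(X[!im, , drop = FALSE])
    sqrt(colSums(matrix(d^2, nrow = 3L)))
  }
  obs <- per_landmark(sex)
  exceed <- with_seed(substream_seed(seed, "landmark-perm"), {
    ex <- integer(length(obs))
    for (b in seq_len(n_perm)) {
      ex <- ex + (per_landmark(sample(sex)) >= obs)
    }
    ex
  })
  p <- (1 + exceed) / (n_perm + 1)
  tibble(point_id = meta$point_id, part = meta$part, effect_mm = obs,
         p_value = p, q_value = p.adjust(p, method = "BH"))
}
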