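# Error metrics and validation experiments: left/right dissimilarity,
# joint-angle deviation, mock and rescan validation reports, error
# evolution curves.

#' Left/right dissimilarity of a two-bone construct
#'
#' Mirrors the left construct, rigidly superimposes the whole construct on
#' the right one (no scaling), and returns the RMSE. Because the
#' superimposition is whole-construct, relative bone-pose differences
#' between the sides remain in the residual — the measure is dominated by
#' pose when anatomical asymmetry is small. Invariant to global rigid
#' motion of either side.
#'
#' @param right,left `limb_shape` constructs with the same landmark
#'   definition.
#' @param relabel_map Optional left/right homologue pairing for
#'   [mirror_shape()].
#' @param mirror Mirror the left side first (set `FALSE` if it is already
#'   in the right frame).
#' @return RMSE in mm.
#' @export
lr_dissimilarity <- function(right, left, relabel_map = NULL, mirror = TRUE) {
  if (mirror) left <- mirror_shape(left, relabel_map)
  check_same_points(right, left)
  procrustes_core(shape_coords(left), shape_coords(right))$rmse
}

# matrix-level deviation measurement
measure_deviation_core <- function(test, control, part, joint) {
  prox <- part == joint$proximal
  dist <- part == joint$distal
  f1 <- procrustes_core(test[prox, , drop = FALSE],
                        control[prox, , drop = FALSE])
  test2 <- transform_coords(f1$transform, test)
  fd <- procrustes_core(control[dist, , drop = FALSE],
                        test2[dist, , drop = FALSE])
  angles <- euler_from_rotation(fd$transform$rotation)
  rmse <- sqrt(mean(rowSums((test2 - control)^2)))
  list(angles = angles, rmse = rmse)
}

#' Joint-angle and point deviation of a construct from an unposed control
#'
#' Superimposes the proximal parts, then decomposes the rigid rotation
#' best mapping the control's distal part onto the test's distal part into
#' flexion/abduction/endorotation under the package convention; it is the
#' exact inverse of [apply_pose()]. The RMSE is computed over all construct
#' landmarks after the proximal superimposition.
#'
#' @param test,control `limb_shape` constructs with identical landmarks;
#'   `control` is the unposed reference.
#' @param joint A [joint_spec()].
#' @return List with `angles` (a [pose_angles()]) and `rmse` (mm).
#' @export
measure_joint_deviation <- function(test, control, joint) {
  check_same_points(test, control)
  measure_deviation_core(shape_coords(test), shape_coords(control),
                         test$part, joint)
}

# one-sided paired permutation test that `after` < `before`
paired_permutation_p <- function(before, after, n_perm = 10000L, seed = 1L) {
  d <- before - after
  obs <- mean(d)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                    nrow = n_perm)
    perm <- as.vector(signs %*% d) / length(d)
    (1 + sum(perm >= obs)) / (n_perm + 1)
  })
}

validation_report <- function(cases, experiment, n_perm, seed) {
  metrics <- c("flexion", "abduction", "endorotation", "rmse")
  out <- list()
  for (jn in unique(cases$joint)) {
    cj <- cases[cases$joint == jn, ]
    for (met in metrics) {
      b <- abs(cj[[paste0("before_", met)]])
      a <- abs(cj[[paste0("after_", met)]])
      out[[length(out) + 1L]] <- tibble(
        joint = jn, metric = met,
        unit = if (met == "rmse") "mm" else "degrees",
        n = nrow(cj),
        before_mean = mean(b), before_sd = sd(b),
        after_mean = mean(a), after_sd = sd(a),
        p_value = paired_permutation_p(b, a, n_perm = n_perm,
                                       seed = substream_seed(seed, paste(jn, met))))
    }
  }
  structure(bind_rows(out), experiment = experiment, cases = cases,
            class = c("limb_validation", class(tibble())))
}

#' @export
print.limb_validation <- function(x, ...) {
  cat(sprintf("<limb_validation: %s experiment, %d cases>\n",
              attr(x, "experiment"), max(x$n)))
  NextMethod()
}

case_row <- function(joint_name, before, after) {
  tibble(joint = joint_name,
         before_flexion = before$angles[["flexion"]],
         before_abduction = before$angles[["abduction"]],
         before_endorotation = before$angles[["endorotation"]],
         before_rmse = before$rmse,
         after_flexion = after$angles[["flexion"]],
         after_abduction = after$angles[["abduction"]],
         after_endorotation = after$angles[["endorotation"]],
         after_rmse = after$rmse)
}

#' Validate the pipeline on a mock pose-corrupted set
#'
#' Measures each mock case's angular and point deviation from its unposed
#' control before correction (the raw posed construct) and after
#' correction (the denoised construct), and reports per-joint, per-metric
#' mean and SD with a one-sided paired permutation p-value for the
#' reduction.
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param mock A [make_mock_set()] result.
#' @param method Denoising path (`"offline"` or `"instant"`).
#' @param n_perm Permutations for the paired test.
#' @param seed Seed for the permutation test.
#' @return A `limb_validation` tibble (per-case values in the `cases`
#'   attribute).
#' @export
validate_mock <- function(pipeline, mock, method = "offline",
                          n_perm = 10000L, seed = 1L) {
  if (nrow(mock) == 0L) abort("Empty mock set.")
  joint <- attr(mock, "joint")
  rows <- lapply(seq_len(nrow(mock)), function(i) {
    control <- mock_shape(mock, mock$control[[i]])
    posed <- mock_shape(mock, mock$posed[[i]])
    before <- measure_joint_deviation(posed, control, joint)
    den <- denoise(pipeline, posed, joint$name, method = method)
    after <- measure_joint_deviation(den, control, joint)
    case_row(joint$name, before, after)
  })
  validation_report(bind_rows(rows), "mock", n_perm = n_perm, seed = seed)
}

#' Validate the pipeline on rescan pairs
#'
#' Rescan pairs share anatomy and neutral alignment but differ in pose;
#' each pair's two scans are compared to each other (no external control)
#' before and after denoising, per joint.
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param population The `limb_population` holding the rescan scans.
#' @inheritParams validate_mock
#' @return A `limb_validation` tibble.
#' @export
validate_rescan <- function(pipeline, population, method = "offline",
                            n_perm = 10000L, seed = 1L) {
  scans <- population$scans
  second <- scans[scans$scan_no == 2L, ]
  if (nrow(second) == 0L) abort("Population contains no rescan pairs.")
  joints <- pipeline$joints
  rows <- list()
  for (i in seq_len(nrow(second))) {
    first <- scans[scans$subject_id == second$subject_id[i] &
                     scans$side == second$side[i] & scans$scan_no == 1L, ]
    l1 <- first$limb[[1L]]; l2 <- second$limb[[i]]
    if (shape_side(l1) == "left") { l1 <- mirror_shape(l1); l2 <- mirror_shape(l2) }
    for (jn in names(joints)) {
      j <- joints[[jn]]$joint
      c1 <- scan_construct(l1, j); c2 <- scan_construct(l2, j)
      before <- measure_joint_deviation(c2, c1, j)
      d1 <- denoise(pipeline, c1, jn, method = method)
      d2 <- denoise(pipeline, c2, jn, method = method)
      after <- measure_joint_deviation(d2, d1, j)
      rows[[length(rows) + 1L]] <- case_row(jn, before, after)
    }
  }
  validation_report(bind_rows(rows), "rescan", n_perm = n_perm, seed = seed)
}

#' Per-case values behind a validation report
#'
#' @param report A `limb_validation`.
#' @return Tibble of per-case before/after deviations.
#' @export
validation_cases <- function(report) attr(report, "cases")

#' Error-evolution curves of a trained pipeline
#'
#' Mean left/right dissimilarity against the number of PLS components, for
#' the decoupled-to-regressed mapping (recorded during component
#' selection; an interior minimum marks where additional components start
#' reintroducing pose) and, optionally, the articulated-to-recoupled
#' (instant) mapping, recomputed from the nested instant fit.
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param joints Joint names (default all).
#' @param instant_k Component counts for the instant-path curve (`NULL` to
#'   skip).
#' @return Tibble with `joint`, `mapping`, `k`, `lr_dissimilarity`.
#' @export
error_evolution <- function(pipeline, joints = names(pipeline$joints),
                            instant_k = NULL) {
  out <- list()
  idx <- pipeline$scan_index
  first <- idx$scan_no == 1
  rsub <- which(first & idx$side == "right")
  lsub <- which(first & idx$side == "left")
  pair_ids <- intersect(idx$subject_id[rsub], idx$subject_id[lsub])
  for (jn in joints) {
    jf <- pipeline$joints[[jn]]
    out[[length(out) + 1L]] <- mutate(jf$error_curve, joint = jn,
                                      mapping = "regressed")
    if (!is.null(instant_k) && length(pair_ids) > 0L) {
      ir <- rsub[match(pair_ids, idx$subject_id[rsub])]
      il <- lsub[match(pair_ids, idx$subject_id[lsub])]
      for (k in pmin(instant_k, jf$k_instant)) {
        Yh <- predict(jf$instant_pls,
                      jf$articulated_scores[c(ir, il), , drop = FALSE], k = k)
        Rc <- ssm_reconstruct_rows(jf$recoupled, Yh)
        np <- length(pair_ids)
        dis <- mean(vapply(seq_len(np), function(i) {
          procrustes_core(unflatten_coords(Rc[np + i, ]),
                          unflatten_coords(Rc[i, ]))$rmse
        }, 1))
        out[[length(out) + 1L]] <- tibble(k = k, lr_dissimilarity = dis,
                                          joint = jn, mapping = "instant")
      }
    }
  }
  select(bind_rows(out), "joint", "mapping", "k", "lr_dissimilarity")
}
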