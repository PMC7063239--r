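#' Configuration of the synthetic articulated-limb generator
#'
#' Defines the study conditions the generator emulates: a population of
#' subjects whose per-bone shape is driven by a dominant size latent plus a
#' few minor shape latents, a neutral inter-bone alignment that is an
#' affine function of the size latent (bounded below 10 degrees), additive
#' scan-time pose applied as rigid rotations through idealized joint
#' centers, mirrored left sides with small anatomical asymmetry, repeated
#' "rescan" pairs sharing anatomy but not pose, and a planted binary sex
#' effect on pelvic width calibrated to a target fraction of hip-construct
#' shape variance.
#'
#' @param n_subjects Number of subjects (each contributes one limb per
#'   side).
#' @param landmarks Named integer vector of landmarks per bone.
#' @param femur_length Template femur length (mm); the whole template
#'   scales with it.
#' @param size_sd Relative scale change per standard deviation of the size
#'   latent (0.06 = 6 percent).
#' @param latent_truncation Truncation bound (in SD) on the size latent,
#'   keeping neutral alignment angles within 10 degrees.
#' @param n_minor_latents Number of minor shape latents (at most 4:
#'   bending, torsion, thickness, distal width).
#' @param minor_strength Total minor-latent variance as a fraction of size
#'   variance.
#' @param sex_effect_fraction Target fraction of hip-construct shape
#'   variance explained by sex.
#' @param sex_ratio_male Probability of male (+1); default 2:1
#'   male-to-female.
#' @param alignment_coefficients Per-joint degrees of neutral (flexion,
#'   abduction, endorotation) per unit size latent.
#' @param pose_profile `"scanner"` (truncated-normal per-axis pose, widest
#'   at the hip — endorotation especially — and small at the knee, echoing
#'   clinical repositioning variability) or `"uniform"` (independent
#'   uniform on `[-pose_limit_deg, pose_limit_deg]`, the mock-experiment
#'   profile).
#' @param pose_limit_deg Hard per-axis pose limit (degrees).
#' @param scanner_pose_sd Per-joint per-axis SDs (degrees) for the
#'   `"scanner"` profile.
#' @param asymmetry_sd SD (mm) of isotropic Gaussian landmark noise on left
#'   bones, so left/right dissimilarity is pose-dominated.
#' @param latent_asymmetry_sd SD of the left-side offset on the latent
#'   vector (directional asymmetry living in shape space).
#' @param n_rescan_subjects Subjects receiving a second scan per side.
#' @param sides,joints Which sides / joints to generate.
#' @param global_pose_sd,global_shift_sd SD of the random whole-limb
#'   placement rotation (degrees/axis) and translation (mm) per scan.
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A `limb_config` list.
#' @export
generator_config <- function(n_subjects = 300L,
                             landmarks = c(pelvis = 120L, femur = 160L,
                                           tibia = 140L, foot = 100L),
                             femur_length = 450,
                             size_sd = 0.06,
                             latent_truncation = 2.7,
                             n_minor_latents = 4L,
                             minor_strength = 0.10,
                             sex_effect_fraction = 0.10,
                             sex_ratio_male = 2 / 3,
                             alignment_coefficients = list(
                               hip = c(2, -1.2, 1.6),
                               knee = c(2, 0.7, -1.1),
                               ankle = c(1.8, -1, 1.3)),
                             pose_profile = c("scanner", "uniform"),
                             pose_limit_deg = 15,
                             scanner_pose_sd = list(hip = c(3, 3.5, 7),
                                                    knee = c(1.1, 0.6, 1),
                                                    ankle = c(2.3, 2, 1.9)),
                             asymmetry_sd = 0.3,
                             latent_asymmetry_sd = 0.05,
                             n_rescan_subjects = 20L,
                             sides = c("right", "left"),
                             joints = c("hip", "knee", "ankle"),
                             global_pose_sd = 5,
                             global_shift_sd = 20,
                             seed = 1L) {
  pose_profile <- arg_match(pose_profile)
  stopifnot(n_subjects >= 2L, pose_limit_deg >= 0, asymmetry_sd >= 0,
            minor_strength >= 0, size_sd >= 0,
            sex_effect_fraction >= 0, sex_effect_fraction < 1)
  structure(list(n_subjects = as.integer(n_subjects), landmarks = landmarks,
                 femur_length = femur_length, size_sd = size_sd,
                 latent_truncation = latent_truncation,
                 n_minor_latents = as.integer(n_minor_latents),
                 minor_strength = minor_strength,
                 sex_effect_fraction = sex_effect_fraction,
                 sex_ratio_male = sex_ratio_male,
                 alignment_coefficients = alignment_coefficients,
                 pose_profile = pose_profile,
                 pose_limit_deg = pose_limit_deg,
                 scanner_pose_sd = scanner_pose_sd,
                 asymmetry_sd = asymmetry_sd,
                 latent_asymmetry_sd = latent_asymmetry_sd,
                 n_rescan_subjects = as.integer(n_rescan_subjects),
                 sides = sides, joints = joints,
                 global_pose_sd = global_pose_sd,
                 global_shift_sd = global_shift_sd,
                 seed = as.integer(seed)),
            class = "limb_config")
}

# rotate `rows` of coordinate matrix m about center `ctr`
rotate_rows <- function(m, rows, R, ctr) {
  m[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2L, ctr) %*% t(R),
                     2L, -ctr)
  m
}

#' Rotate the distal side of a joint construct through its idealized center
#'
#' Applies a rigid rotation (from [rotation_from_euler()]) to the distal
#' part — and any parts listed in `distal_parts`, for chained whole-limb
#' use — about the joint center recovered from the construct's articular
#' landmarks. The proximal part is untouched.
#'
#' @param shape A `limb_shape` containing both joint parts.
#' @param joint A [joint_spec()].
#' @param angles A [pose_angles()] vector (degrees).
#' @param distal_parts Parts to rotate (default the joint's distal bone).
#' @return The posed `limb_shape`.
#' @export
apply_pose <- function(shape, joint, angles, distal_parts = joint$distal) {
  if (!all(c(joint$proximal, joint$distal) %in% shape$part)) {
    abort(sprintf("Construct is missing parts of joint '%s'.", joint$name))
  }
  ctr <- joint_center(shape, joint)
  m <- rotate_rows(shape_coords(shape), shape$part %in% distal_parts,
                   rotation_from_euler(angles), ctr)
  shape_replace_coords(shape, m)
}

# distal chains for hierarchical pose application on a full limb
limb_chain <- list(hip = c("femur", "tibia", "foot"),
                   knee = c("tibia", "foot"), ankle = "foot")

# apply per-joint rotations hierarchically (hip, then knee, then ankle)
pose_limb <- function(limb, joints, angles_by_joint) {
  for (jn in intersect(c("hip", "knee", "ankle"), names(angles_by_joint))) {
    ang <- angles_by_joint[[jn]]
    if (all(ang == 0)) next
    limb <- apply_pose(limb, joints[[jn]], ang,
                       distal_parts = intersect(limb_chain[[jn]],
                                                unique(limb$part)))
  }
  limb
}

# neutral limb of one subject in the template frame (right side)
subject_limb <- function(template, latents, sex, config) {
  tm <- shape_coords(template$limb)
  coords <- tm
  Dm <- template$fields$minor
  for (m in seq_along(Dm)) {
    coords <- coords + latents[m + 1L] * template$fields$minor_sd[m] * Dm[[m]]
  }
  coords <- coords + sex * template$fields$sex_delta * template$fields$sex
  C <- template$calibration$centroid
  coords <- sweep((1 + config$size_sd * latents[1L]) * sweep(coords, 2L, C),
                  2L, -C)
  limb <- shape_replace_coords(template$limb, coords)
  angles <- lapply(config$alignment_coefficients,
                   function(co) co * latents[1L])
  list(limb = pose_limb(limb, template$joints, angles),
       neutral_angles = angles)
}

draw_pose <- function(config, joint) {
  lim <- config$pose_limit_deg
  if (config$pose_profile == "uniform" || lim == 0) {
    ang <- runif(3, -lim, lim)
  } else {
    sds <- config$scanner_pose_sd[[joint]]
    ang <- vapply(sds, function(s) {
      if (s <= 0) return(0)
      lo <- stats::pnorm(-lim / s); hi <- stats::pnorm(lim / s)
      stats::qnorm(runif(1, lo, hi)) * s
    }, 1)
  }
  pose_angles(ang[1], ang[2], ang[3])
}

#' Sample a synthetic articulated-limb population
#'
#' Subjects are drawn i.i.d.: a truncated-normal size latent, standard
#' normal minor latents, sex with the configured ratio. Each side's neutral
#' limb is assembled from the subject's latents (left sides use latents
#' perturbed by the latent asymmetry, are mirrored, and receive landmark
#' noise). Every scan then applies independent per-joint pose and a random
#' whole-limb placement; rescan subjects get a second scan sharing anatomy
#' and neutral alignment but not pose. The population regenerates
#' bit-identically from the configuration (which carries the master seed).
#'
#' @param config A [generator_config()].
#' @return A `limb_population` with elements `config`, `template`,
#'   `subjects`, `anatomy` (per subject/side neutral limb and ground-truth
#'   neutral angles) and `scans` (per scan pose angles and posed limb).
#' @export
sample_population <- function(config) {
  template <- make_template(config)
  n <- config$n_subjects

  subjects <- with_seed(substream_seed(config$seed, "subjects"), {
    sex <- ifelse(runif(n) < config$sex_ratio_male, 1, -1)
    a <- config$latent_truncation
    z1 <- vapply(seq_len(n), function(i) {
      repeat { z <- rnorm(1); if (abs(z) <= a) return(z) }
    }, 1)
    minors <- matrix(rnorm(n * length(template$fields$minor)), nrow = n)
    eta <- matrix(rnorm(n * (1L + ncol(minors)),
                        sd = config$latent_asymmetry_sd), nrow = n)
    tibble(subject_id = sprintf("S%04d", seq_len(n)), sex = sex,
           latents = lapply(seq_len(n), function(i) c(z1[i], minors[i, ])),
           latents_left = lapply(seq_len(n),
                                 function(i) c(z1[i], minors[i, ]) + eta[i, ]))
  })

  anatomy <- with_seed(substream_seed(config$seed, "asymmetry"), {
    rows <- list()
    for (i in seq_len(n)) {
      for (side in config$sides) {
        lat <- if (side == "right") subjects$latents[[i]] else subjects$latents_left[[i]]
        sl <- subject_limb(template, lat, subjects$sex[i], config)
        limb <- sl$limb
        if (side == "left") {
          limb <- mirror_shape(limb)
          if (config$asymmetry_sd > 0) {
            m <- shape_coords(limb)
            limb <- shape_replace_coords(
              limb, m + matrix(rnorm(length(m), sd = config$asymmetry_sd),
                               ncol = 3L))
          }
        }
        rows[[length(rows) + 1L]] <-
          tibble(subject_id = subjects$subject_id[i], side = side,
                 limb = list(limb), neutral_angles = list(sl$neutral_angles))
      }
    }
    bind_rows(rows)
  })

  n_rescan <- min(config$n_rescan_subjects, n)
  scans <- with_seed(substream_seed(config$seed, "pose"), {
    rows <- list()
    for (k in seq_len(nrow(anatomy))) {
      sid <- anatomy$subject_id[k]
      i <- match(sid, subjects$subject_id)
      n_scans <- if (i <= n_rescan) 2L else 1L
      for (sc in seq_len(n_scans)) {
        pose <- lapply(setNames(nm = config$joints),
                       function(j) draw_pose(config, j))
        posed <- pose_limb(anatomy$limb[[k]], template$joints, pose)
        gang <- rnorm(3, sd = config$global_pose_sd)
        gtr <- limb_transform(rotation = rotation_from_euler(gang),
                              translation = rnorm(3, sd = config$global_shift_sd))
        posed <- apply_transform(gtr, posed)
        rows[[length(rows) + 1L]] <-
          tibble(scan_id = sprintf("%s_%s_sc%d", sid, anatomy$side[k], sc),
                 subject_id = sid, side = anatomy$side[k], scan_no = sc,
                 pose = list(pose), limb = list(posed))
      }
    }
    bind_rows(rows)
  })

  structure(list(config = config, template = template, subjects = subjects,
                 anatomy = anatomy, scans = scans),
            class = "limb_population")
}

#' @export
print.limb_population <- function(x, ...) {
  cat(sprintf(
    "<limb_population: %d subjects (%d male / %d female), %d scans, sides [%s], seed %d>\n",
    nrow(x$subjects), sum(x$subjects$sex == 1), sum(x$subjects$sex == -1),
    nrow(x$scans), paste(x$config$sides, collapse = ", "), x$config$seed))
  invisible(x)
}

#' Per-scan table of a synthetic population
#'
#' @param population A `limb_population`.
#' @return The `scans` tibble (one row per scan; `limb` is a list column of
#'   posed full-limb shapes in world frame).
#' @export
population_scans <- function(population) population$scans

#' Extract a two-bone joint construct from a full-limb shape
#'
#' @param limb A full-limb `limb_shape`.
#' @param joint A [joint_spec()].
#' @return The construct `limb_shape` (proximal + distal parts).
#' @export
scan_construct <- function(limb, joint) {
  shape_part(limb, c(joint$proximal, joint$distal))
}

#' Ground-truth neutral construct of a subject, in the canonical frame
#'
#' Returns the neutrally aligned construct of one subject/side. Left sides
#' are mirrored into the canonical (right) frame so the result is directly
#' comparable to pipeline outputs, which pool mirrored left sides.
#'
#' @param population A `limb_population`.
#' @param subject_id,side Subject and side.
#' @param joint A [joint_spec()] (or its name).
#' @return A `limb_shape`.
#' @export
neutral_control <- function(population, subject_id, side, joint) {
  if (is.character(joint)) joint <- population$template$joints[[joint]]
  k <- which(population$anatomy$subject_id == subject_id &
               population$anatomy$side == side)
  if (length(k) != 1L) abort("Unknown subject/side.")
  limb <- population$anatomy$limb[[k]]
  if (side == "left") limb <- mirror_shape(limb)
  scan_construct(limb, joint)
}

#' Generate a mock validation set from a trained shape model
#'
#' Draws `K` shapes along the model's first principal component (weights
#' `Normal(0, lambda_1)`), then corrupts each with independent per-axis
#' rotations uniform on `[-limit_deg, +limit_deg]` applied through the
#' idealized joint center. Ground-truth controls and applied angles are
#' retained.
#'
#' @param model A `limb_ssm` of the joint construct (typically the
#'   recoupled model).
#' @param joint A [joint_spec()].
#' @param K Number of mock cases.
#' @param limit_deg Per-axis rotation limit (degrees).
#' @param seed Seed for the draws.
#' @return A `limb_mock_set`: tibble with `id`, applied `flexion`,
#'   `abduction`, `endorotation`, and list columns `control` / `posed` of
#'   coordinate matrices; landmark metadata in attributes.
#' @export
make_mock_set <- function(model, joint, K = 1000L, limit_deg = 15,
                          seed = 1L) {
  if (K < 1L) abort("K must be at least 1.")
  mu <- unflatten_coords(model$mean)
  pc1 <- unflatten_coords(model$components[, 1L])
  lam1 <- model$eigenvalues[1L]
  idx <- match(joint$center_ids, model$point_id)
  if (anyNA(idx)) abort("Model landmarks do not include the joint's articular ids.")
  distal_rows <- model$part == joint$distal
  with_seed(seed, {
    b1 <- rnorm(K, sd = sqrt(lam1))
    ang <- matrix(runif(3L * K, -limit_deg, limit_deg), ncol = 3L)
    control <- vector("list", K); posed <- vector("list", K)
    for (i in seq_len(K)) {
      ctl <- mu + b1[i] * pc1
      ctr <- colMeans(ctl[idx, , drop = FALSE])
      posed[[i]] <- rotate_rows(ctl, distal_rows,
                                rotation_from_euler(ang[i, ]), ctr)
      control[[i]] <- ctl
    }
    structure(tibble(id = seq_len(K), b1 = b1, flexion = ang[, 1],
                     abduction = ang[, 2], endorotation = ang[, 3],
                     control = control, posed = posed),
              point_id = model$point_id, part = model$part, joint = joint,
              limit_deg = limit_deg, class = c("limb_mock_set",
                                               class(tibble())))
  })
}

mock_shape <- function(mock, coords) {
  landmark_shape(coords, point_id = attr(mock, "point_id"),
                 part = attr(mock, "part"), side = "right", frame = "model")
}
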