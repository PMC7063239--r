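# Deterministic parametric landmark templates for a synthetic lower limb.
#
# Template frame: +X anterior, +Y subject-left (medio-lateral), +Z superior.
# All coordinates in mm; the reference femur spans 450 mm so point-distance
# errors are on the same scale as clinical CT morphometrics.

golden_angle <- pi * (3 - sqrt(5))

fib_sphere <- function(n, center = c(0, 0, 0), radius = 1) {
  k <- seq_len(n)
  z <- 1 - 2 * (k - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * golden_angle
  cbind(center[1] + radius * r * cos(phi),
        center[2] + radius * r * sin(phi),
        center[3] + radius * z)
}

fib_ellipsoid <- function(n, center, radii) {
  m <- fib_sphere(n)
  sweep(sweep(m, 2L, radii, "*"), 2L, -center)
}

# low-discrepancy sequence on [0,1)
ld_seq <- function(n, mult = 0.6180339887498949, offset = 0.5) {
  ((seq_len(n) - offset) * mult) %% 1
}

template_pelvis <- function(n) {
  n_ring <- max(12L, round(n / 3))
  n_acet <- max(8L, round(n / 4))
  n_blade <- n - n_ring - n_acet
  th <- 2 * pi * (seq_len(n_ring) - 0.5) / n_ring
  ring <- cbind(55 * cos(th), 90 + 65 * sin(th), 980 + 8 * sin(2 * th))
  acet <- fib_sphere(n_acet, c(0, 0, 900), 26)
  u <- (seq_len(n_blade) - 0.5) / n_blade
  v <- ld_seq(n_blade)
  blade <- cbind(30 * (v - 0.5) * (1 - 0.5 * u),
                 20 + 80 * u,
                 950 + 90 * u + 15 * sin(2 * pi * v) * (0.3 + 0.7 * u))
  list(coords = rbind(ring, acet, blade),
       region = rep(c("inlet_ring", "acetabulum", "blade"),
                    c(n_ring, n_acet, n_blade)))
}

# Right femur: medially offset head on a short neck, lateral greater
# trochanter, elliptical bowed shaft, asymmetric condyles — strongly
# non-axisymmetric so rigid superimposition of the bone is well
# conditioned about its long axis.
template_femur <- function(n) {
  n_head <- max(10L, round(n * 0.18))
  n_neck <- max(4L, round(n * 0.06))
  n_troc <- max(4L, round(n * 0.06))
  n_cond <- 2L * max(5L, round(n * 0.09))
  n_shaft <- n - n_head - n_neck - n_troc - n_cond
  head <- fib_sphere(n_head, c(0, 28, 890), 24)
  un <- (seq_len(n_neck) - 0.5) / n_neck
  phn <- seq_len(n_neck) * golden_angle
  neck <- cbind(9 * cos(phn), 24 - 22 * un + 9 * sin(phn) * 0.4,
                884 - 16 * un)
  troc <- fib_sphere(n_troc, c(0, -26, 872), 10)
  u <- (seq_len(n_shaft) - 0.5) / n_shaft
  phi <- seq_len(n_shaft) * golden_angle
  shaft <- cbind(13 * cos(phi) + 8 * sin(pi * u), 16 * sin(phi),
                 860 - 382 * u)
  cond <- rbind(fib_sphere(n_cond / 2, c(0, 20, 453), 13),
                fib_sphere(n_cond / 2, c(2, -17, 456), 11))
  list(coords = rbind(head, neck, troc, shaft, cond),
       region = rep(c("head", "neck", "trochanter", "shaft", "condyles"),
                    c(n_head, n_neck, n_troc, n_shaft, n_cond)))
}

# Right tibia: elliptical plateau, shaft with anterior crest, distal
# mortise with a medial malleolus.
template_tibia <- function(n) {
  n_plat <- max(8L, round(n * 0.2))
  n_mort <- max(8L, round(n * 0.16))
  n_mall <- max(4L, round(n * 0.06))
  n_shaft <- n - n_plat - n_mort - n_mall
  u <- (seq_len(n_plat) - 0.5) / n_plat
  th <- seq_len(n_plat) * golden_angle
  plat <- cbind(-3 + 24 * sqrt(u) * cos(th), 27 * sqrt(u) * sin(th),
                446 + 2 * sin(th))
  us <- (seq_len(n_shaft) - 0.5) / n_shaft
  phi <- seq_len(n_shaft) * golden_angle
  crest <- 5 * pmax(0, cos(phi))^3
  shaft <- cbind(10 * cos(phi) + crest + 3 * sin(pi * us), 13 * sin(phi),
                 438 - 343 * us)
  mort <- fib_sphere(n_mort, c(0, 4, 78), 14)
  mall <- fib_sphere(n_mall, c(0, 26, 66), 7)
  list(coords = rbind(plat, shaft, mort, mall),
       region = rep(c("plateau", "shaft", "mortise", "malleolus"),
                    c(n_plat, n_shaft, n_mort, n_mall)))
}

template_foot <- function(n) {
  n_tal <- max(8L, round(n * 0.2))
  n_cal <- max(8L, round(n * 0.3))
  n_fore <- n - n_tal - n_cal
  tal <- fib_sphere(n_tal, c(0, 0, 60), 14)
  cal <- fib_ellipsoid(n_cal, c(-35, 0, 35), c(25, 18, 16))
  u <- (seq_len(n_fore) - 0.5) / n_fore
  v <- ld_seq(n_fore)
  w <- ld_seq(n_fore, mult = 0.7548776662466927, offset = 0.25)
  fore <- cbind(20 + 130 * u,
                70 * (v - 0.5) * (1 - 0.6 * u),
                15 + 18 * w)
  list(coords = rbind(tal, cal, fore),
       region = rep(c("talus", "calcaneus", "forefoot"),
                    c(n_tal, n_cal, n_fore)))
}

#' Joint specification
#'
#' Describes a two-bone articulation: part labels of the proximal and
#' distal bones, the landmark ids whose centroid defines the idealized
#' joint center (so the center can be recovered in any frame from the
#' construct itself), and a joint-type tag used only by the synthetic
#' corruptor and angle measurement.
#'
#' @param name Joint name (`"hip"`, `"knee"`, `"ankle"`, or custom).
#' @param proximal,distal Part labels.
#' @param center_ids Character vector of point ids (articular landmarks).
#' @param type `"spherical"` or `"hinge-like"`.
#' @return A `limb_joint` object.
#' @export
joint_spec <- function(name, proximal, distal, center_ids,
                       type = "spherical") {
  structure(list(name = name, proximal = proximal, distal = distal,
                 center_ids = center_ids, type = type),
            class = "limb_joint")
}

#' @export
print.limb_joint <- function(x, ...) {
  cat(sprintf("<limb_joint %s: %s -> %s, %d articular landmarks, %s>\n",
              x$name, x$proximal, x$distal, length(x$center_ids), x$type))
  invisible(x)
}

#' Idealized joint center of a construct
#'
#' Centroid of the joint's articular landmarks in the construct's current
#' frame.
#'
#' @param shape A `limb_shape` containing the articular landmarks.
#' @param joint A [joint_spec()].
#' @return Length-3 numeric (mm).
#' @export
joint_center <- function(shape, joint) {
  idx <- match(joint$center_ids, shape$point_id)
  if (anyNA(idx)) abort(sprintf("Construct is missing articular landmarks of joint '%s'.", joint$name))
  colMeans(shape_coords(shape)[idx, , drop = FALSE])
}

# remove the rigid-motion (3 translations + 3 linearized rotations)
# component of a displacement field over the given coordinates
project_out_rigid <- function(D, coords) {
  n <- nrow(coords)
  ctr <- sweep(coords, 2L, colMeans(coords))
  basis <- matrix(0, 3L * n, 6L)
  for (a in 1:3) basis[seq(a, 3L * n, by = 3L), a] <- 1
  gens <- list(rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)),   # about x
               rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0)),   # about y
               rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)))   # about z
  for (a in 1:3) basis[, 3L + a] <- as.vector(t(ctr %*% t(gens[[a]])))
  qb <- qr.Q(qr(basis))
  d <- as.vector(t(D))
  matrix(d - qb %*% crossprod(qb, d), ncol = 3L, byrow = TRUE)
}

# effective sum of squares of a field after removing its rigid component
effective_ss <- function(D, coords) sum(project_out_rigid(D, coords)^2)

#' Build the deterministic synthetic lower-limb template
#'
#' Constructs per-bone landmark clouds (iliac blade, inlet ring and
#' acetabulum for the pelvis; head, bowed shaft and condylar clusters for
#' the femur; plateau, shaft and mortise for the tibia; talus, calcaneus
#' and forefoot wedge), the three joint specifications with articular
#' landmark subsets, the latent deformation fields (limb bending, torsion,
#' shaft thickness, distal width), the sex-offset field (pelvic width) and
#' the calibration constants used by [sample_population()]. Everything is a
#' deterministic function of the configuration.
#'
#' @param config A [generator_config()].
#' @return A `limb_template` list: `limb` (full-limb `limb_shape`, frame
#'   `"template"`), `bones` (part labels), `joints` (named list of
#'   [joint_spec()]), `fields`, `calibration`, `region` labels.
#' @export
make_template <- function(config) {
  lm <- config$landmarks
  if (any(lm < 4L)) abort("Each bone needs at least 4 landmarks.")
  parts <- c("pelvis", "femur", "tibia", "foot")
  pieces <- list(pelvis = template_pelvis(lm[["pelvis"]]),
                 femur = template_femur(lm[["femur"]]),
                 tibia = template_tibia(lm[["tibia"]]),
                 foot = template_foot(lm[["foot"]]))
  coords <- do.call(rbind, lapply(pieces, `[[`, "coords"))
  coords <- coords * (config$femur_length / 450)
  region <- unlist(lapply(pieces, `[[`, "region"), use.names = FALSE)
  part <- rep(parts, vapply(pieces, function(p) nrow(p$coords), 1L))
  abbrev <- c(pelvis = "pel", femur = "fem", tibia = "tib", foot = "foo")
  point_id <- unlist(lapply(parts, function(p) {
    sprintf("%s%04d", abbrev[[p]], seq_len(sum(part == p)))
  }), use.names = FALSE)
  limb <- landmark_shape(coords, point_id = point_id, part = part,
                         side = "right", frame = "template")

  id_of <- function(p, reg) point_id[part == p & region == reg]
  joints <- list(
    hip = joint_spec("hip", "pelvis", "femur", id_of("femur", "head"),
                     "spherical"),
    knee = joint_spec("knee", "femur", "tibia", id_of("femur", "condyles"),
                      "hinge-like"),
    ankle = joint_spec("ankle", "tibia", "foot", id_of("tibia", "mortise"),
                       "hinge-like"))

  # --- latent deformation fields (unit Frobenius norm over the limb) ------
  C <- colMeans(coords)
  ctr <- sweep(coords, 2L, C)
  zc <- ctr[, 3]; halfL <- max(abs(zc))
  zr <- (coords[, 3] - min(coords[, 3])) / diff(range(coords[, 3]))
  n <- nrow(coords)
  D <- list()
  bx <- (zc / halfL)^2 - mean((zc / halfL)^2)
  D$bend <- cbind(bx, rep(0, n), rep(0, n))
  th <- zc / halfL
  D$torsion <- cbind(-th * ctr[, 2], th * ctr[, 1], 0)
  D$thickness <- cbind(ctr[, 1] * sin(pi * zr), ctr[, 2] * sin(pi * zr), 0)
  wdist <- exp(-((coords[, 3] - 455 * config$femur_length / 450) / 150)^2)
  D$width <- cbind(0, ctr[, 2] * wdist, 0)
  # deformation fields are "pure shape" at the bone level: any rigid
  # (translation/rotation) component per bone is unidentifiable from
  # decoupled shapes and would corrupt recoupling, so it is removed
  D <- lapply(D, function(f) {
    for (p in parts) {
      pr <- part == p
      f[pr, ] <- project_out_rigid(f[pr, , drop = FALSE],
                                   coords[pr, , drop = FALSE])
    }
    f / sqrt(sum(f^2))
  })
  D <- D[seq_len(min(config$n_minor_latents, length(D)))]

  is_pelvis <- part == "pelvis"
  sexf <- matrix(0, n, 3L)
  sexf[is_pelvis, 2] <- coords[is_pelvis, 2] - mean(coords[is_pelvis, 2])
  sexf[is_pelvis, ] <- project_out_rigid(sexf[is_pelvis, , drop = FALSE],
                                         coords[is_pelvis, , drop = FALSE])
  sexf <- sexf / sqrt(sum(sexf^2))
  ref_rows <- part %in% c("pelvis", "femur")

  # --- calibration --------------------------------------------------------
  a <- config$latent_truncation
  var_z1 <- 1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)
  size_var_limb <- config$size_sd^2 * sum(ctr^2)
  minor_sd <- rep(sqrt(config$minor_strength * size_var_limb / length(D)),
                  length(D))

  # combined size + hip-alignment direction per unit z1, on the hip rows
  hip_coords <- coords[ref_rows, , drop = FALSE]
  Gsize <- config$size_sd * sweep(hip_coords, 2L, C)
  co <- deg2rad(config$alignment_coefficients$hip)
  gens <- list(y = rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0)),
               x = rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)),
               z = rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)))
  omega <- co[1] * gens$y + co[2] * gens$x + co[3] * gens$z
  chip <- colMeans(coords[match(joints$hip$center_ids, point_id), , drop = FALSE])
  Galign <- matrix(0, sum(ref_rows), 3L)
  fem_in_ref <- part[ref_rows] == "femur"
  Galign[fem_in_ref, ] <- sweep(hip_coords[fem_in_ref, , drop = FALSE], 2L, chip) %*% t(omega)
  G <- Gsize + Galign
  v_anat_hip <- var_z1 * effective_ss(G, hip_coords) +
    sum(vapply(seq_along(D), function(m) {
      minor_sd[m]^2 * effective_ss(D[[m]][ref_rows, , drop = FALSE], hip_coords)
    }, 1))
  p_male <- config$sex_ratio_male
  var_sex <- 1 - (2 * p_male - 1)^2
  f <- config$sex_effect_fraction
  ss_sex <- effective_ss(sexf[ref_rows, , drop = FALSE], hip_coords)
  sex_delta <- if (f <= 0) 0 else sqrt(f / (1 - f) * v_anat_hip / (var_sex * ss_sex))

  structure(list(limb = limb, joints = joints, region = region,
                 fields = list(minor = D, minor_sd = minor_sd,
                               sex = sexf, sex_delta = sex_delta),
                 calibration = list(centroid = C, var_z1 = var_z1,
                                    size_var_limb = size_var_limb,
                                    v_anat_hip = v_anat_hip,
                                    var_sex = var_sex),
                 config = config),
            class = "limb_template")
}

#' @export
print.limb_template <- function(x, ...) {
  cat(sprintf("<limb_template: %d landmarks over %s; joints %s>\n",
              nrow(x$limb), paste(unique(x$limb$part), collapse = "/"),
              paste(names(x$joints), collapse = "/")))
  invisible(x)
}
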