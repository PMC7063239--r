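# The pose-denoising pipeline: decoupled per-bone models, articulated
# per-joint models, the PLS regressed (neutral-alignment) model with
# left/right error-evolution component selection, recoupling, and the
# instant articulated->recoupled predictor.

#' Select the PLS component count by left/right error evolution
#'
#' For each candidate component count the regressed model (decoupled scores
#' predicting articulated scores) is evaluated by reconstructing the
#' regressed construct of each side of every paired subject and averaging
#' the left/right dissimilarity (pose differences between sides dominate
#' this measure, so reintroduced pose shows up as a rising curve). The
#' selected count is the smallest one within 1 percent of the minimum
#' (Occam tie-break).
#'
#' @param X Predictor score matrix (decoupled scores, one row per scan).
#' @param Y Response score matrix (articulated scores, row-matched).
#' @param model The articulated `limb_ssm` used to reconstruct predictions.
#' @param scan_index Tibble with `subject_id`, `side`, `scan_no` matching
#'   the rows of `X`.
#' @param k_range Candidate component counts.
#' @return List with `k_star`, `error_curve` (tibble `k`,
#'   `lr_dissimilarity`) and the full-rank `fit`.
#' @export
select_components <- function(X, Y, model, scan_index, k_range = 1:8) {
  if (length(k_range) == 0L) abort("`k_range` is empty.")
  rk <- qr(sweep(as.matrix(X), 2L, colMeans(as.matrix(X))))$rank
  k_range <- sort(unique(pmin(k_range, rk)))
  fit <- fit_pls(X, Y, k = max(k_range))
  first <- scan_index$scan_no == 1
  rsub <- which(first & scan_index$side == "right")
  lsub <- which(first & scan_index$side == "left")
  pair_ids <- intersect(scan_index$subject_id[rsub], scan_index$subject_id[lsub])
  if (length(pair_ids) == 0L) {
    warn("No left/right pairs available; skipping error-evolution selection.")
    return(list(k_star = max(k_range), error_curve = tibble(
      k = k_range, lr_dissimilarity = NA_real_), fit = fit))
  }
  ir <- rsub[match(pair_ids, scan_index$subject_id[rsub])]
  il <- lsub[match(pair_ids, scan_index$subject_id[lsub])]
  rows <- c(ir, il)
  np <- length(pair_ids)
  curve <- vapply(k_range, function(k) {
    Yh <- predict(fit, as.matrix(X)[rows, , drop = FALSE], k = k)
    Rg <- ssm_reconstruct_rows(model, Yh)
    mean(vapply(seq_len(np), function(i) {
      procrustes_core(unflatten_coords(Rg[np + i, ]),
                      unflatten_coords(Rg[i, ]))$rmse
    }, 1))
  }, 1)
  k_star <- k_range[which(curve <= min(curve) * 1.01)[1L]]
  list(k_star = k_star,
       error_curve = tibble(k = k_range, lr_dissimilarity = curve),
       fit = fit)
}

gpa_fit <- function(mats, meta, variance_kept, allow_scale = FALSE,
                    tol = 1e-8, max_iter = 100L) {
  g <- gpa_core(mats, allow_scale = allow_scale, tol = tol,
                max_iter = max_iter)
  X <- do.call(rbind, lapply(g$aligned, flatten_coords))
  model <- fit_ssm(X, variance_kept = variance_kept, meta = meta)
  list(model = model, data = X, scores = ssm_project_rows(model, X),
       gpa = g[c("n_iter", "residual_history", "converged")])
}

#' Build the full pose-denoising pipeline from a landmark population
#'
#' Runs the complete offline workflow: (1) mirror left scans into the
#' canonical right frame; (2) GPA-align each bone independently and fit the
#' decoupled per-bone models (pose-free by construction); (3) GPA-align
#' each two-bone joint construct as a whole and fit the articulated models
#' (relative bone pose survives as shape variance); (4) learn the regressed
#' model — PLS from decoupled to articulated scores — selecting the
#' component count by left/right error evolution; (5) recouple: rigidly
#' superimpose each scan's original bones onto its regressed construct,
#' preserving all anatomical detail, and fit the recoupled model; (6) learn
#' the instant model mapping articulated scores directly to recoupled
#' scores.
#'
#' @param population A `limb_population`, or a tibble like
#'   [population_scans()] output (columns `scan_id`, `subject_id`, `side`,
#'   `scan_no`, `limb`) together with `template`.
#' @param joints Joint names to train (default: all in the population).
#' @param template Required when `population` is a plain scans tibble.
#' @param variance_kept Variance fraction retained by every shape model.
#' @param k_range Candidate PLS component counts for the regressed model.
#' @param k_instant Component count for the instant model (capped at the
#'   articulated score rank; accuracy is non-decreasing in it).
#' @param allow_scale Estimate scale in all GPA steps (default `FALSE`).
#' @return A `limb_pipeline`.
#' @export
build_pipeline <- function(population, joints = NULL, template = NULL,
                           variance_kept = 0.999, k_range = 1:8,
                           k_instant = 200L, allow_scale = FALSE) {
  if (inherits(population, "limb_population")) {
    scans <- population$scans
    template <- population$template
  } else {
    scans <- population
    if (is.null(template)) abort("`template` is required with a scans tibble.")
  }
  joints <- joints %||% intersect(names(template$joints),
                                  population$config$joints %||% names(template$joints))
  jspecs <- template$joints[joints]
  scan_index <- scans[c("scan_id", "subject_id", "side", "scan_no")]

  # canonical-frame limbs (left mirrored), as coordinate matrices
  ref <- scans$limb[[1L]]
  if (attr(ref, "side") == "left") ref <- mirror_shape(ref)
  limb_meta <- list(point_id = ref$point_id, part = ref$part, side = "right")
  limbs <- lapply(seq_len(nrow(scans)), function(i) {
    l <- scans$limb[[i]]
    if (shape_side(l) == "left") l <- mirror_shape(l)
    shape_coords(l)
  })

  bones <- unique(unlist(lapply(jspecs, function(j) c(j$proximal, j$distal))))
  part <- limb_meta$part
  bone_fits <- lapply(setNames(nm = bones), function(b) {
    rows <- part == b
    gpa_fit(lapply(limbs, function(m) m[rows, , drop = FALSE]),
            meta = list(point_id = limb_meta$point_id[rows],
                        part = part[rows], side = "right"),
            variance_kept = variance_kept, allow_scale = allow_scale)
  })

  joint_fits <- lapply(jspecs, function(j) {
    rows <- part %in% c(j$proximal, j$distal)
    art <- gpa_fit(lapply(limbs, function(m) m[rows, , drop = FALSE]),
                   meta = list(point_id = limb_meta$point_id[rows],
                               part = part[rows], side = "right"),
                   variance_kept = variance_kept, allow_scale = allow_scale)
    X <- cbind(bone_fits[[j$proximal]]$scores, bone_fits[[j$distal]]$scores)
    sel <- select_components(X, art$scores, art$model, scan_index,
                             k_range = k_range)
    Yh <- predict(sel$fit, X, k = sel$k_star)
    Rg <- ssm_reconstruct_rows(art$model, Yh)

    # recouple: original bones rigidly superimposed into regressed placement
    jpart <- part[rows]
    prox_rows <- jpart == j$proximal
    Rc <- matrix(0, nrow(Rg), ncol(Rg))
    for (i in seq_len(nrow(Rg))) {
      reg <- unflatten_coords(Rg[i, ])
      out <- matrix(0, nrow(reg), 3L)
      for (b in c(j$proximal, j$distal)) {
        br <- jpart == b
        orig <- limbs[[i]][part == b, , drop = FALSE]
        out[br, ] <- procrustes_core(orig, reg[br, , drop = FALSE])$aligned
      }
      Rc[i, ] <- flatten_coords(out)
    }
    rec_g <- gpa_core(lapply(seq_len(nrow(Rc)),
                             function(i) unflatten_coords(Rc[i, ])),
                      allow_scale = FALSE)
    Rc <- do.call(rbind, lapply(rec_g$aligned, flatten_coords))
    rec_model <- fit_ssm(Rc, variance_kept = variance_kept,
                         meta = list(point_id = limb_meta$point_id[rows],
                                     part = jpart, side = "right"))
    rec_scores <- ssm_project_rows(rec_model, Rc)

    rk <- qr(sweep(art$scores, 2L, colMeans(art$scores)))$rank
    ki <- min(k_instant, rk)
    instant <- fit_pls(art$scores, rec_scores, k = ki)

    list(joint = j, articulated = art$model, articulated_scores = art$scores,
         articulated_data = art$data, regressed_pls = sel$fit,
         k_star = sel$k_star, error_curve = sel$error_curve,
         regressed_data = Rg, recoupled = rec_model,
         recoupled_scores = rec_scores, recoupled_data = Rc,
         k_instant = ki, instant_pls = instant)
  })

  structure(list(bones = bone_fits, joints = joint_fits,
                 scan_index = scan_index, variance_kept = variance_kept,
                 k_range = k_range, allow_scale = allow_scale,
                 limb_meta = limb_meta,
                 config = if (inherits(population, "limb_population"))
                   population$config else NULL),
            class = "limb_pipeline")
}

#' @export
print.limb_pipeline <- function(x, ...) {
  cat(sprintf("<limb_pipeline: %d scans, bones [%s]>\n",
              nrow(x$scan_index), paste(names(x$bones), collapse = ", ")))
  for (jn in names(x$joints)) {
    jf <- x$joints[[jn]]
    cat(sprintf(
      "  %s: articulated %d modes, recoupled %d modes, k* = %d, instant k = %d\n",
      jn, jf$articulated$t, jf$recoupled$t, jf$k_star, jf$k_instant))
  }
  invisible(x)
}

# concatenated decoupled scores of a construct (or full limb), for `joint`
decoupled_scores <- function(pipeline, shape, joint) {
  jf <- pipeline$joints[[joint]]
  unlist(lapply(c(jf$joint$proximal, jf$joint$distal), function(b) {
    ssm_project(pipeline$bones[[b]]$model,
                shape_coords(shape_part(shape, b)), align = TRUE)
  }))
}

#' Predict the neutrally aligned (regressed) construct for given bones
#'
#' Projects each bone onto its decoupled model, maps the concatenated
#' scores through the regressed PLS model at the selected component count,
#' and reconstructs in the articulated model. Because pose is unpredictable
#' from bone shape, the prediction approximates the pose-averaged neutral
#' alignment; bone-level detail is smoothed by model truncation (restore it
#' with [recouple()]).
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param shape A `limb_shape` holding the joint's two bones (any pose,
#'   canonical right frame).
#' @param joint Joint name.
#' @return The regressed construct (`limb_shape`, model frame).
#' @export
predict_neutral <- function(pipeline, shape, joint) {
  jf <- pipeline$joints[[joint]]
  if (is.null(jf)) abort(sprintf("Pipeline has no joint '%s'.", joint))
  b <- decoupled_scores(pipeline, shape, joint)
  yh <- predict(jf$regressed_pls, b, k = jf$k_star)
  ssm_reconstruct(jf$articulated, as.vector(yh))
}

#' Recouple original bone geometry into a regressed construct
#'
#' Rigidly (no scaling) superimposes each original bone onto its
#' counterpart within the regressed construct, so the output carries the
#' original bone geometry — bit-identical up to a rigid transform — in the
#' regressed relative placement.
#'
#' @param regressed The regressed construct (`limb_shape`).
#' @param original_bones A `limb_shape` with the same parts (e.g. the posed
#'   construct), or a named list of per-bone shapes.
#' @return The recoupled construct.
#' @export
recouple <- function(regressed, original_bones) {
  parts <- unique(regressed$part)
  get_bone <- function(b) {
    if (inherits(original_bones, "limb_shape")) shape_part(original_bones, b)
    else original_bones[[b]]
  }
  m <- shape_coords(regressed)
  for (b in parts) {
    orig <- get_bone(b)
    if (is.null(orig)) abort(sprintf("Missing original bone '%s'.", b))
    br <- regressed$part == b
    m[br, ] <- procrustes_core(shape_coords(orig),
                               m[br, , drop = FALSE])$aligned
  }
  shape_replace_coords(regressed, m, frame = "model")
}

#' Remove pose from an articulated construct
#'
#' The offline path predicts the neutral alignment from the bones
#' (regressed model) and recouples the construct's own bone geometry; the
#' instant path maps articulated scores directly to recoupled scores in
#' one step.
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param construct The articulated construct (`limb_shape`; left-side
#'   constructs are mirrored into the canonical frame automatically).
#' @param joint Joint name.
#' @param method `"offline"` or `"instant"`.
#' @param k Instant-path component count (default: the trained cap).
#' @return The denoised construct (`limb_shape`, model frame).
#' @export
denoise <- function(pipeline, construct, joint,
                    method = c("offline", "instant"), k = NULL) {
  method <- arg_match(method)
  jf <- pipeline$joints[[joint]]
  if (is.null(jf)) abort(sprintf("Pipeline has no joint '%s'.", joint))
  if (shape_side(construct) == "left") construct <- mirror_shape(construct)
  if (method == "offline") {
    recouple(predict_neutral(pipeline, construct, joint), construct)
  } else {
    v <- align_to_model(jf$articulated, construct)
    b <- as.vector(crossprod(jf$articulated$components, v - jf$articulated$mean))
    yh <- predict(jf$instant_pls, b, k = k %||% jf$k_instant)
    ssm_reconstruct(jf$recoupled, as.vector(yh))
  }
}

#' Assemble a neutral full-limb reconstruction from denoised joints
#'
#' Denoises each joint construct and chains them distal-to-proximal
#' (default ankle, knee, hip): consecutive constructs are connected by
#' rigid superimposition of the shared bone (tibia, then femur), and the
#' residual of each shared-bone alignment is reported.
#'
#' @param pipeline A trained `limb_pipeline` with all three joints.
#' @param limb Full-limb `limb_shape` (posed; mirrored automatically if
#'   left).
#' @param method Denoising path, as in [denoise()].
#' @param order Joint assembly order.
#' @return List with `limb` (the assembled neutral limb) and `residuals`
#'   (named mm RMSE of each shared-bone superimposition).
#' @export
chain_joints <- function(pipeline, limb, method = "offline",
                         order = c("ankle", "knee", "hip")) {
  if (!all(order %in% names(pipeline$joints))) {
    abort("All joints in `order` must be trained in the pipeline.")
  }
  if (shape_side(limb) == "left") limb <- mirror_shape(limb)
  den <- lapply(setNames(nm = order), function(jn) {
    denoise(pipeline, scan_construct(limb, pipeline$joints[[jn]]$joint),
            jn, method = method)
  })
  asm <- den[[order[1L]]]
  residuals <- c()
  for (jn in order[-1L]) {
    nxt <- den[[jn]]
    shared <- intersect(unique(asm$part), unique(nxt$part))[1L]
    if (is.na(shared)) abort("Consecutive joints share no bone.")
    f <- procrustes_core(shape_coords(shape_part(nxt, shared)),
                         shape_coords(shape_part(asm, shared)))
    residuals[jn] <- f$rmse
    nxt <- apply_transform(f$transform, nxt)
    new_parts <- setdiff(unique(nxt$part), unique(asm$part))
    asm <- new_limb_shape(bind_rows(asm, shape_part(nxt, new_parts)),
                          side = "right", frame = "model")
  }
  # restore canonical landmark order
  ord <- order(match(asm$point_id, pipeline$limb_meta$point_id))
  asm <- new_limb_shape(asm[ord, ], side = "right", frame = "model")
  list(limb = asm, residuals = residuals)
}

#' Estimate the pose share of articulated-model variance
#'
#' Percentage of variance in the articulated data that cannot be explained
#' by the recoupled (pose-free) model: each articulated construct is
#' rigidly aligned to the recoupled mean and projected onto the recoupled
#' modes; the residual sum of squares is reported relative to the total
#' articulated variance. The recoupled model is refit with a high variance
#' cap (default 0.999) so that model truncation, rather than pose, is not
#' charged to the residual.
#'
#' @param pipeline A trained `limb_pipeline`.
#' @param joint Joint name.
#' @param variance_kept Variance cap of the refitted recoupled model.
#' @return Percent (0-100).
#' @export
estimate_pose_variance <- function(pipeline, joint, variance_kept = 0.999) {
  jf <- pipeline$joints[[joint]]
  if (is.null(jf)) abort(sprintf("Pipeline has no joint '%s'.", joint))
  rec <- fit_ssm(jf$recoupled_data, variance_kept = variance_kept,
                 meta = list(point_id = jf$recoupled$point_id,
                             part = jf$recoupled$part, side = "right"))
  data <- lapply(seq_len(nrow(jf$articulated_data)),
                 function(i) unflatten_coords(jf$articulated_data[i, ]))
  unexplained_variance(data, rec, align = TRUE)
}

#' Save / load a trained pipeline
#'
#' @param pipeline A `limb_pipeline`.
#' @param path File path (RDS container).
#' @return `load_pipeline()` returns the pipeline.
#' @export
save_pipeline <- function(pipeline, path) {
  saveRDS(list(format = "limbalign-pipeline", version = 1L,
               pipeline = pipeline), path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "limbalign-pipeline")) {
    abort("Not a limbalign pipeline file.")
  }
  obj$pipeline
}
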