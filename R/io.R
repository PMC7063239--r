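# Readers and writers: landmark CSV (the canonical exchange format),
# ASCII PLY/OBJ meshes whose vertex order equals the landmark order (with
# a JSON sidecar carrying ids/parts), YAML configuration, and the
# population directory layout used by the command line.

#' Read / write a landmark CSV
#'
#' The canonical format: header `point_id,part,side,x,y,z`, one row per
#' landmark, mm units, `.` decimal separator, UTF-8. Writing uses
#' shortest-round-trip number formatting so `read_landmarks(write_landmarks(s))`
#' reproduces the coordinates bit-exactly.
#'
#' @param path CSV file path.
#' @param frame Frame tag to attach on read.
#' @return A `limb_shape`.
#' @export
read_landmarks <- function(path, frame = "raw") {
  # base-R reader: strtod parsing is correctly rounded, preserving the
  # %.17g round-trip guarantee of write_landmarks()
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(point_id = "character",
                                       part = "character",
                                       side = "character"))
  need <- c("point_id", "part", "side", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Landmark CSV is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite coordinates in '%s' at row(s) %s.",
                  path, paste(head(bad, 5L), collapse = ", ")))
  }
  dup <- which(duplicated(df$point_id))
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate point_id '%s' in '%s' at row %d.",
                  df$point_id[dup[1L]], path, dup[1L]))
  }
  side <- unique(df$side)
  if (length(side) != 1L) abort(sprintf("Mixed side labels in '%s'.", path))
  landmark_shape(cbind(df$x, df$y, df$z), point_id = df$point_id,
                 part = df$part, side = side, frame = frame)
}

#' @rdname read_landmarks
#' @param shape A `limb_shape`.
#' @export
write_landmarks <- function(shape, path) {
  fmt <- function(v) sprintf("%.17g", v)
  writeLines(c("point_id,part,side,x,y,z",
               paste(shape$point_id, shape$part, shape_side(shape),
                     fmt(shape$x), fmt(shape$y), fmt(shape$z), sep = ",")),
             path)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(shape, path) {
  jsonlite::write_json(list(point_id = shape$point_id, part = shape$part,
                            side = shape_side(shape),
                            frame = shape_frame(shape)),
                       sidecar_path(path), auto_unbox = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("Mesh '%s' needs a sidecar JSON ('%s') carrying point_ids and part labels.",
                  path, sp))
  }
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read / write landmark meshes (ASCII PLY or OBJ)
#'
#' Vertices are the landmarks, in order; a sidecar JSON (`<path>.json`)
#' carries the point ids, part labels, side and frame. Vertex order is
#' preserved exactly.
#'
#' @param path Mesh file path (`.ply` or `.obj`).
#' @return A `limb_shape`.
#' @export
read_mesh <- function(path) {
  meta <- read_sidecar(path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    hd_end <- which(lines == "end_header")[1L]
    if (is.na(hd_end)) abort(sprintf("'%s' is not an ASCII PLY file.", path))
    nv_line <- grep("^element vertex", lines[seq_len(hd_end)], value = TRUE)
    nv <- as.integer(sub("element vertex\\s+", "", nv_line[1L]))
    vals <- lines[(hd_end + 1L):(hd_end + nv)]
  } else if (ext == "obj") {
    vals <- sub("^v\\s+", "", grep("^v\\s", lines, value = TRUE))
  } else {
    abort("Only PLY and OBJ meshes are supported.")
  }
  m <- do.call(rbind, lapply(strsplit(trimws(vals), "\\s+"), function(p) {
    as.numeric(p[1:3])
  }))
  if (nrow(m) != length(meta$point_id)) {
    abort(sprintf("Vertex count (%d) does not match sidecar landmarks (%d).",
                  nrow(m), length(meta$point_id)))
  }
  landmark_shape(m, point_id = meta$point_id, part = meta$part,
                 side = meta$side %||% "right", frame = meta$frame %||% "raw")
}

#' @rdname read_mesh
#' @param shape A `limb_shape`.
#' @export
write_mesh <- function(shape, path) {
  m <- shape_coords(shape)
  ext <- tolower(tools::file_ext(path))
  fmt <- function(v) sprintf("%.17g", v)
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(m)),
                 "property double x", "property double y",
                 "property double z", "end_header",
                 paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3]))), path)
  } else if (ext == "obj") {
    writeLines(paste("v", fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3])), path)
  } else {
    abort("Only PLY and OBJ meshes are supported.")
  }
  write_sidecar(shape, path)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys are the arguments of [generator_config()] plus the
#' pipeline options `variance_kept`, `k_range` and `k_instant`; unknown
#' keys are rejected.
#'
#' @param path YAML (or JSON) file.
#' @return List with `generator` (a `limb_config`) and `pipeline` options.
#' @export
read_config <- function(path) {
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pl_keys <- c("variance_kept", "k_range", "k_instant")
  gen_keys <- names(formals(generator_config))
  unknown <- setdiff(names(raw), c(pl_keys, gen_keys))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  gen <- raw[intersect(names(raw), gen_keys)]
  if (!is.null(gen$landmarks)) gen$landmarks <- unlist(gen$landmarks)
  if (!is.null(gen$scanner_pose_sd)) {
    gen$scanner_pose_sd <- lapply(gen$scanner_pose_sd, unlist)
  }
  if (!is.null(gen$alignment_coefficients)) {
    gen$alignment_coefficients <- lapply(gen$alignment_coefficients, unlist)
  }
  pipeline <- raw[intersect(names(raw), pl_keys)]
  if (!is.null(pipeline$k_range)) {
    pipeline$k_range <- seq(pipeline$k_range[1], rev(pipeline$k_range)[1])
  }
  list(generator = do.call(generator_config, gen), pipeline = pipeline)
}

#' Write / read a synthetic population as a directory of landmark CSVs
#'
#' The directory holds one CSV per scan, a `manifest.csv` with the scan
#' metadata, and `ground_truth.json` with the configuration echo, latents,
#' sex, neutral and pose angles and the master seed.
#'
#' @param population A `limb_population`.
#' @param dir Output directory (created if needed).
#' @return `read_population_dir()` returns a list with `scans` (tibble
#'   usable by [build_pipeline()]), `manifest` and, when present,
#'   `ground_truth`.
#' @export
write_population_dir <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans <- population$scans
  files <- sprintf("%s.csv", scans$scan_id)
  for (i in seq_len(nrow(scans))) {
    write_landmarks(scans$limb[[i]], file.path(dir, files[i]))
  }
  readr::write_csv(mutate(scans[c("scan_id", "subject_id", "side", "scan_no")],
                          file = files), file.path(dir, "manifest.csv"))
  cfg <- unclass(population$config)
  cfg$landmarks <- as.list(cfg$landmarks)
  gt <- list(
    config = cfg,
    subjects = lapply(seq_len(nrow(population$subjects)), function(i) {
      s <- population$subjects[i, ]
      list(subject_id = s$subject_id, sex = s$sex,
           latents = s$latents[[1L]], latents_left = s$latents_left[[1L]])
    }),
    neutral_angles = lapply(seq_len(nrow(population$anatomy)), function(k) {
      list(subject_id = population$anatomy$subject_id[k],
           side = population$anatomy$side[k],
           angles = lapply(population$anatomy$neutral_angles[[k]], as.numeric))
    }),
    pose = lapply(seq_len(nrow(scans)), function(i) {
      list(scan_id = scans$scan_id[i],
           angles = lapply(scans$pose[[i]], as.numeric))
    }))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_population_dir
#' @export
read_population_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv in '%s'.", dir))
  manifest <- readr::read_csv(mf, col_types = readr::cols(
    scan_id = readr::col_character(), subject_id = readr::col_character(),
    side = readr::col_character(), scan_no = readr::col_integer(),
    file = readr::col_character()))
  scans <- mutate(manifest,
                  limb = lapply(file.path(dir, manifest$file), read_landmarks))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- NULL; config <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    cfg <- gt$config
    cfg$landmarks <- unlist(cfg$landmarks)
    cfg$alignment_coefficients <- lapply(cfg$alignment_coefficients, unlist)
    cfg$scanner_pose_sd <- lapply(cfg$scanner_pose_sd, unlist)
    config <- do.call(generator_config, cfg)
  }
  list(scans = select(scans, -file), manifest = manifest,
       ground_truth = gt, config = config)
}
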