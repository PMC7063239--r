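#' Landmark shape tibbles
#'
#' A landmark shape is an ordered set of dense homologous (quasi-)landmarks
#' for one structure — a single bone or a multi-bone joint construct — stored
#' as a tibble with one row per landmark and columns `point_id`, `part`,
#' `x`, `y`, `z` (mm). The body side and the coordinate-frame tag
#' (`"raw"`, `"template"`, `"gpa-aligned"`, or `"model"`) travel as
#' attributes so that model-fitting functions can refuse unaligned input.
#'
#' @param coords Numeric n-by-3 matrix of landmark coordinates (mm).
#' @param point_id Character vector of stable landmark identifiers.
#' @param part Character vector of bone membership labels (e.g. `"femur"`).
#' @param side `"right"` or `"left"`.
#' @param frame Coordinate frame tag.
#' @return A `limb_shape` tibble.
#' @examples
#' s <- landmark_shape(diag(3)[rep(1:3, 2), ], point_id = paste0("p", 1:6),
#'                     part = rep(c("a", "b"), each = 3))
#' shape_side(s)
#' @export
landmark_shape <- function(coords, point_id = NULL, part = "bone",
                           side = "right", frame = "raw") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("`coords` must have 3 columns (x, y, z).")
  n <- nrow(coords)
  if (n < 4L) abort("A landmark shape needs at least 4 points.")
  if (!all(is.finite(coords))) abort("Landmark coordinates must be finite.")
  if (is.null(point_id)) point_id <- sprintf("p%04d", seq_len(n))
  point_id <- as.character(point_id)
  if (anyDuplicated(point_id)) {
    dup <- which(duplicated(point_id))[1L]
    abort(sprintf("Duplicate point_id '%s' (row %d).", point_id[dup], dup))
  }
  part <- rep_len(as.character(part), n)
  side <- arg_match0(side, c("right", "left"))
  out <- tibble(point_id = point_id, part = part,
                x = coords[, 1], y = coords[, 2], z = coords[, 3])
  new_limb_shape(out, side = side, frame = frame)
}

new_limb_shape <- function(df, side, frame) {
  structure(df, side = side, frame = frame,
            class = c("limb_shape", class(tibble())))
}

#' @export
print.limb_shape <- function(x, ...) {
  cat(sprintf("<limb_shape: %d landmarks, parts [%s], side %s, frame %s>\n",
              nrow(x), paste(unique(x$part), collapse = ", "),
              shape_side(x), shape_frame(x)))
  NextMethod()
}

#' @rdname landmark_shape
#' @param shape A `limb_shape`.
#' @export
shape_side <- function(shape) attr(shape, "side") %||% "right"

#' @rdname landmark_shape
#' @export
shape_frame <- function(shape) attr(shape, "frame") %||% "raw"

#' Extract or replace the coordinate matrix of a shape
#'
#' @param shape A `limb_shape`.
#' @return `shape_coords()` returns an n-by-3 matrix; `shape_parts()` the
#'   part label vector.
#' @export
shape_coords <- function(shape) {
  m <- cbind(shape$x, shape$y, shape$z)
  rownames(m) <- shape$point_id
  m
}

#' @rdname shape_coords
#' @param coords Replacement n-by-3 matrix.
#' @param frame Optional new frame tag.
#' @export
shape_replace_coords <- function(shape, coords, frame = NULL) {
  stopifnot(nrow(coords) == nrow(shape))
  shape$x <- coords[, 1]; shape$y <- coords[, 2]; shape$z <- coords[, 3]
  if (!is.null(frame)) attr(shape, "frame") <- frame
  shape
}

#' @rdname shape_coords
#' @export
shape_parts <- function(shape) shape$part

#' Subset a construct to one or more parts
#'
#' @param shape A `limb_shape`.
#' @param parts Character vector of part labels to keep.
#' @return A `limb_shape` with the selected landmarks, in the original order.
#' @export
shape_part <- function(shape, parts) {
  keep <- shape$part %in% parts
  if (!any(keep)) abort(sprintf("No landmarks with part in [%s].",
                                paste(parts, collapse = ", ")))
  new_limb_shape(shape[keep, ], side = shape_side(shape),
                 frame = shape_frame(shape))
}

# flatten n x 3 coords row-wise: (x1, y1, z1, x2, y2, z2, ...)
flatten_coords <- function(m) as.vector(t(m))
unflatten_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

check_same_points <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$point_id, b$point_id)) {
    abort("Shapes have mismatched point sets: same point_ids in the same order are required.")
  }
  invisible(TRUE)
}
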