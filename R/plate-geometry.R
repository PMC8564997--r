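# Concave naming follows FDI-style quadrant numbering borrowed for the plate
# landmarks: 1x/2x on the maxillary plate (patient right/left), 4x/3x on the
# mandibular plate, plus the front-center concaves 0 (maxillary) and 0'
# (mandibular).

.MAXILLARY_LABELS  <- c("11", "12", "13", "14", "0",  "21", "22", "23", "24")
.MANDIBULAR_LABELS <- c("41", "42", "43", "44", "0'", "31", "32", "33", "34")
.ALL_LABELS <- c(.MAXILLARY_LABELS, .MANDIBULAR_LABELS)
.PAIR_MAP <- stats::setNames(
  c(.MANDIBULAR_LABELS, .MAXILLARY_LABELS),
  c(.MAXILLARY_LABELS, .MANDIBULAR_LABELS)
)

#' Concave landmark labels
#'
#' The 18 valid concave identifiers: nine on the maxillary mounting plate
#' (`11 12 13 14 0 21 22 23 24`) and nine on the mandibular plate
#' (`41 42 43 44 0' 31 32 33 34`).
#'
#' @param jaw Optionally restrict to `"maxillary"` or `"mandibular"`.
#' @return Character vector of labels.
#' @export
concave_labels <- function(jaw = c("both", "maxillary", "mandibular")) {
  jaw <- match.arg(jaw)
  switch(jaw,
    both       = .ALL_LABELS,
    maxillary  = .MAXILLARY_LABELS,
    mandibular = .MANDIBULAR_LABELS
  )
}

.check_labels <- function(labels) {
  bad <- setdiff(labels, .ALL_LABELS)
  if (length(bad) > 0) {
    stop("invalid concave label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

#' Jaw of a concave label
#'
#' @param label Concave label(s).
#' @return `"maxillary"` or `"mandibular"` per label.
#' @export
concave_jaw <- function(label) {
  .check_labels(label)
  ifelse(label %in% .MAXILLARY_LABELS, "maxillary", "mandibular")
}

#' Opposing-jaw partner of a concave
#'
#' The nine canonical center-point pairs are 11-41, 12-42, 13-43, 14-44,
#' 0-0', 21-31, 22-32, 23-33 and 24-34. `pair_of()` is an involution:
#' `pair_of(pair_of(x)) == x`.
#'
#' @param label Concave label(s).
#' @return The partner label(s) on the opposing plate.
#' @export
pair_of <- function(label) {
  .check_labels(label)
  unname(.PAIR_MAP[label])
}

#' The nine canonical center-point pairs
#'
#' @return Data frame with columns `maxillary` and `mandibular`, one row per
#'   pair, in plate order.
#' @export
canonical_pairs <- function() {
  data.frame(
    maxillary  = .MAXILLARY_LABELS,
    mandibular = .MANDIBULAR_LABELS,
    stringsAsFactors = FALSE
  )
}

#' Default dual mounting-plate layout
#'
#' Builds the nominal geometry of the paired mounting plates: nine
#' hemispherical concaves per plate, three per face (right lateral face:
#' 12/13/14 and 42/43/44; front face: 11/0/21 and 41/0'/31; left lateral
#' face: 22/23/24 and 32/33/34), with every maxillary concave vertically
#' aligned above its mandibular partner. Patient-right (FDI 1x/4x) sits at
#' negative X, the front face at negative Y, and the maxillary plate at
#' positive Z. Concave diameter defaults to 6 mm.
#'
#' The exact inter-concave spacings are free design parameters of the plate;
#' the defaults are plausible articulator-plate dimensions and every number
#' can be overridden so downstream conclusions can be checked for layout
#' sensitivity.
#'
#' @param concave_radius Concave radius in mm (default 3, i.e. 6 mm diameter).
#' @param jaw_separation Vertical distance in mm between the maxillary and
#'   mandibular concave-center planes (default 90).
#' @param face_width Plate face width in mm (default 60).
#' @param lateral_spacing Spacing in mm between adjacent concaves on each
#'   lateral face (default 20).
#' @param front_spacing Spacing in mm between adjacent concaves on the front
#'   face (default 15).
#' @return A `plate_layout`: list with `centers` (18 x 3 matrix, mm,
#'   articulator frame, rownames are concave labels), `axes` (18 x 3 matrix of
#'   outward unit opening directions), `concave_radius` and `jaw_separation`.
#' @examples
#' layout <- default_layout()
#' nrow(layout$centers)  # 18
#' @export
default_layout <- function(concave_radius = 3, jaw_separation = 90,
                           face_width = 60, lateral_spacing = 20,
                           front_spacing = 15) {
  if (!is.numeric(concave_radius) || length(concave_radius) != 1 ||
      !is.finite(concave_radius) || concave_radius <= 0) {
    stop("invalid layout: concave_radius must be a positive length (mm)",
         call. = FALSE)
  }
  for (nm in c("jaw_separation", "face_width", "lateral_spacing",
               "front_spacing")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("invalid layout: ", nm, " must be a positive length (mm)",
           call. = FALSE)
    }
  }

  half <- face_width / 2
  zmax <- jaw_separation / 2
  # (x, y) per maxillary concave; mandibular partners share (x, y).
  xy <- rbind(
    "11" = c(-front_spacing, -half),
    "12" = c(-half, -lateral_spacing),
    "13" = c(-half, 0),
    "14" = c(-half, lateral_spacing),
    "0"  = c(0, -half),
    "21" = c(front_spacing, -half),
    "22" = c(half, -lateral_spacing),
    "23" = c(half, 0),
    "24" = c(half, lateral_spacing)
  )
  xy <- xy[.MAXILLARY_LABELS, , drop = FALSE]
  centers <- rbind(
    cbind(xy, z = rep(zmax, 9)),
    cbind(xy, z = rep(-zmax, 9))
  )
  rownames(centers) <- .ALL_LABELS
  colnames(centers) <- c("x", "y", "z")

  face_axis <- rbind(
    "11" = c(0, -1, 0), "12" = c(-1, 0, 0), "13" = c(-1, 0, 0),
    "14" = c(-1, 0, 0), "0" = c(0, -1, 0), "21" = c(0, -1, 0),
    "22" = c(1, 0, 0), "23" = c(1, 0, 0), "24" = c(1, 0, 0)
  )
  face_axis <- face_axis[.MAXILLARY_LABELS, , drop = FALSE]
  axes <- rbind(face_axis, face_axis)
  rownames(axes) <- .ALL_LABELS
  colnames(axes) <- c("x", "y", "z")

  structure(
    list(centers = centers, axes = axes,
         concave_radius = concave_radius, jaw_separation = jaw_separation),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("plate_layout: 18 hemispherical concaves (9 per jaw)\n")
  cat(sprintf("  concave radius: %g mm (diameter %g mm)\n",
              x$concave_radius, 2 * x$concave_radius))
  cat(sprintf("  jaw separation: %g mm\n", x$jaw_separation))
  invisible(x)
}

#' Construct a labelled landmark set
#'
#' @param points Numeric matrix, n x 3, rownames are concave labels; mm.
#' @param frame_tag Free-text provenance tag, e.g. `"nominal"`, `"standard"`,
#'   `"fitted:maxillary"`, `"aligned:group4"`.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(points, frame_tag = "nominal") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix", call. = FALSE)
  if (is.null(rownames(points))) {
    stop("points must have concave labels as rownames", call. = FALSE)
  }
  .check_labels(rownames(points))
  if (anyDuplicated(rownames(points))) {
    stop("duplicate concave labels in landmark set", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, frame_tag = frame_tag),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set [%s]: %d landmarks\n",
              x$frame_tag, nrow(x$points)))
  print(utils::head(round(x$points, 4)))
  if (nrow(x$points) > 6) cat("  ...\n")
  invisible(x)
}

#' Nominal landmark set of a layout
#'
#' @param layout A `plate_layout`.
#' @param jaw `"both"`, `"maxillary"` or `"mandibular"`.
#' @return A `landmark_set` tagged `"nominal"`.
#' @export
nominal_landmarks <- function(layout, jaw = "both") {
  pts <- layout$centers[concave_labels(jaw), , drop = FALSE]
  landmark_set(pts, frame_tag = "nominal")
}

#' Restrict a landmark set to one jaw
#'
#' @param lms A `landmark_set`.
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @return A `landmark_set` containing only that jaw's labels.
#' @export
jaw_view <- function(lms, jaw = c("maxillary", "mandibular")) {
  jaw <- match.arg(jaw)
  keep <- rownames(lms$points)[concave_jaw(rownames(lms$points)) == jaw]
  landmark_set(lms$points[keep, , drop = FALSE], frame_tag = lms$frame_tag)
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid transform (proper rotation + translation)
#'
#' The only map between coordinate frames in this package. `rotation` must be
#' proper orthogonal (R'R = I and det R = +1, both within 1e-10); inputs
#' failing that are rejected rather than silently re-orthogonalized, unless
#' `repair = TRUE`, which projects onto SO(3) via SVD.
#'
#' @param rotation 3 x 3 matrix.
#' @param translation Length-3 numeric vector, mm.
#' @param repair Project a near-rotation onto the closest proper rotation.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            repair = FALSE) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  }
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("non-finite transform entries", call. = FALSE)
  }
  if (repair) {
    sv <- svd(rotation)
    d <- sign(det(sv$u %*% t(sv$v)))
    rotation <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    stop("rotation is not proper orthogonal (use repair = TRUE to project)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that maps every point to itself.
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to points or landmarks
#'
#' Each point p maps to `R p + t`. Pairwise distances are preserved.
#'
#' @param t A `rigid_transform`.
#' @param x An n x 3 matrix or a `landmark_set`.
#' @param frame_tag Optional new frame tag for a `landmark_set` input.
#' @return Same type as `x`.
#' @export
apply_transform <- function(t, x, frame_tag = NULL) {
  if (inherits(x, "landmark_set")) {
    pts <- apply_transform(t, x$points)
    return(landmark_set(pts,
                        frame_tag = frame_tag %||% x$frame_tag))
  }
  x <- as.matrix(x)
  out <- x %*% t(t$rotation)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out[, 3] <- out[, 3] + t$translation[3]
  dimnames(out) <- dimnames(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param a A `rigid_transform`.
#' @return The inverse `rigid_transform`; `compose_transform(a, invert_transform(a))`
#'   is the identity.
#' @export
invert_transform <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Observation coordinate frame from landmarks 12, 0 and 22
#'
#' Reconstructs the study's observation coordinate system: the plane through
#' maxillary concaves 12, 0 and 22 becomes the XOY plane, point 0 the origin,
#' and the X axis runs parallel to the 12-22 line (left to right, i.e. from
#' 12 toward 22). The Z axis is normal to the plane; when mandibular
#' landmarks are present its sign is chosen so they lie below the maxillary
#' plane (Z vertical, pointing from mandible toward maxilla); the frame is
#' always right-handed.
#'
#' @param landmarks A `landmark_set` containing at least maxillary 12, 0, 22.
#' @return The `rigid_transform` mapping the landmarks' frame into the
#'   observation frame.
#' @export
build_observation_frame <- function(landmarks) {
  pts <- landmarks$points
  need <- c("12", "0", "22")
  missing <- setdiff(need, rownames(pts))
  if (length(missing) > 0) {
    stop("observation frame requires maxillary landmarks 12, 0, 22; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p12 <- pts["12", ]; p0 <- pts["0", ]; p22 <- pts["22", ]
  u <- p22 - p12
  v <- p12 - p0
  area <- sqrt(sum(.cross3(u, p0 - p12)^2)) / 2
  if (area < 1e-9) {
    stop("degenerate observation frame: points 12, 0, 22 are collinear",
         call. = FALSE)
  }
  x_axis <- .unit(u)
  z_axis <- .unit(.cross3(x_axis, v))

  jaw <- concave_jaw(rownames(pts))
  if (any(jaw == "mandibular")) {
    z_max  <- mean(pts[jaw == "maxillary", , drop = FALSE] %*% z_axis)
    z_mand <- mean(pts[jaw == "mandibular", , drop = FALSE] %*% z_axis)
    if (z_mand > z_max) z_axis <- -z_axis
  }
  y_axis <- .cross3(z_axis, x_axis)
  rot <- rbind(x_axis, y_axis, z_axis)
  dimnames(rot) <- NULL
  rigid_transform(rot, as.numeric(-rot %*% p0))
}
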