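# Plain-text interchange: landmark CSV, layout JSON, XYZ point clouds and
# transform JSON. In files the mandibular front-center label 0' is written
# as "0p" to avoid quoting issues; it is mapped back on read.

.label_to_file <- function(label) ifelse(label == "0'", "0p", label)
.label_from_file <- function(token) ifelse(token == "0p", "0'", token)

#' Write a landmark set to CSV
#'
#' Header `id,jaw,x_mm,y_mm,z_mm`; the label `0'` is written as `0p`.
#'
#' @param lms A `landmark_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_landmark_csv <- function(lms, path) {
  labels <- rownames(lms$points)
  df <- data.frame(
    id = .label_to_file(labels),
    jaw = concave_jaw(labels),
    x_mm = lms$points[, 1], y_mm = lms$points[, 2], z_mm = lms$points[, 3],
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmark set from CSV
#'
#' @param path File with header `id,jaw,x_mm,y_mm,z_mm` (`0'` as `0p`).
#' @param frame_tag Frame tag for the resulting set.
#' @return A `landmark_set`.
#' @export
read_landmark_csv <- function(path, frame_tag = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  need <- c("id", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labels <- .label_from_file(df$id)
  pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  rownames(pts) <- labels
  lms <- landmark_set(pts, frame_tag = frame_tag)
  if ("jaw" %in% names(df)) {
    stated <- df$jaw
    derived <- concave_jaw(labels)
    if (any(stated != derived)) {
      stop("landmark CSV jaw column disagrees with label-derived jaw for: ",
           paste(df$id[stated != derived], collapse = ", "), call. = FALSE)
    }
  }
  lms
}

#' Write a plate layout to JSON
#'
#' Keys `concave_radius_mm`, `jaw_separation_mm` and `explicit_centers`
#' (landmark-CSV-shaped rows with per-concave axes).
#'
#' @param layout A `plate_layout`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_layout_json <- function(layout, path) {
  labels <- rownames(layout$centers)
  rows <- data.frame(
    id = .label_to_file(labels),
    jaw = concave_jaw(labels),
    x_mm = layout$centers[, 1], y_mm = layout$centers[, 2],
    z_mm = layout$centers[, 3],
    axis_x = layout$axes[, 1], axis_y = layout$axes[, 2],
    axis_z = layout$axes[, 3],
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(
    list(concave_radius_mm = layout$concave_radius,
         jaw_separation_mm = layout$jaw_separation,
         explicit_centers = rows),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a plate layout from JSON
#'
#' Accepts either parametric keys (`concave_radius_mm`, `jaw_separation_mm`,
#' `face_width_mm`, `lateral_spacing_mm`, `front_spacing_mm`) passed through
#' [default_layout()], or an `explicit_centers` table that overrides the
#' parametric centers/axes entirely.
#'
#' @param path JSON file path.
#' @return A `plate_layout`.
#' @export
read_layout_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  par_keys <- c(concave_radius = "concave_radius_mm",
                jaw_separation = "jaw_separation_mm",
                face_width = "face_width_mm",
                lateral_spacing = "lateral_spacing_mm",
                front_spacing = "front_spacing_mm")
  for (arg in names(par_keys)) {
    if (!is.null(cfg[[par_keys[arg]]])) args[[arg]] <- cfg[[par_keys[arg]]]
  }
  layout <- do.call(default_layout, args)
  if (!is.null(cfg$explicit_centers)) {
    rows <- as.data.frame(cfg$explicit_centers)
    labels <- .label_from_file(rows$id)
    .check_labels(labels)
    if (anyDuplicated(labels)) {
      stop("invalid layout: duplicate concave ids", call. = FALSE)
    }
    if (!setequal(labels, concave_labels())) {
      stop("invalid layout: explicit_centers must cover all 18 concaves",
           call. = FALSE)
    }
    pts <- as.matrix(rows[, c("x_mm", "y_mm", "z_mm")])
    rownames(pts) <- labels
    layout$centers[labels, ] <- pts[labels, ]
    if (all(c("axis_x", "axis_y", "axis_z") %in% names(rows))) {
      ax <- as.matrix(rows[, c("axis_x", "axis_y", "axis_z")])
      rownames(ax) <- labels
      nrm <- sqrt(rowSums(ax^2))
      if (any(abs(nrm - 1) > 1e-12)) {
        stop("invalid layout: axes must be unit vectors", call. = FALSE)
      }
      layout$axes[labels, ] <- ax[labels, ]
    }
  }
  layout
}

#' Write a point cloud as whitespace-delimited XYZ
#'
#' One `x y z` line per point, mm, full precision.
#'
#' @param cloud A `point_cloud`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(cloud, path) {
  pts <- .cloud_points(cloud)
  utils::write.table(format(pts, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a whitespace-delimited XYZ point cloud
#'
#' @param path Input file path.
#' @param source_id Optional concave label.
#' @return A `point_cloud`.
#' @export
read_xyz <- function(path, source_id = NA_character_) {
  pts <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  point_cloud(pts, source_id = source_id, frame_tag = basename(path))
}

#' Export a scan session as XYZ clouds plus a JSON manifest
#'
#' Writes every replicate cloud as `<label>_rep<k>.xyz` (with `0'` as `0p`)
#' and a `manifest.json` recording the jaw, operator, repetition, true pose
#' and per-cloud point counts.
#'
#' @param session A `scan_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (lab in names(session$clouds)) {
    for (k in seq_along(session$clouds[[lab]])) {
      fn <- sprintf("%s_rep%d.xyz", .label_to_file(lab), k)
      write_xyz(session$clouds[[lab]][[k]], file.path(dir, fn))
      files[[length(files) + 1L]] <- list(
        id = .label_to_file(lab), repeat_index = k, file = fn,
        n_points = nrow(session$clouds[[lab]][[k]]$points)
      )
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(jaw = session$jaw, operator = session$operator,
         repetition = session$repetition,
         true_pose = list(
           rotation_row_major = as.numeric(t(session$true_pose$rotation)),
           translation_mm = session$true_pose$translation),
         clouds = files),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Write a rigid transform to JSON
#'
#' Nine rotation entries row-major plus three translation entries (mm).
#'
#' @param t A `rigid_transform`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.numeric(t(t$rotation)),
         translation_mm = t$translation),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path JSON file path (see [write_transform_json()]).
#' @return A `rigid_transform`; improper rotations are rejected.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  obj$translation_mm)
}
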