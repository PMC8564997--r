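# Synthetic-data stage: contact-probe "standard data" and optical-scan point
# clouds with the statistical structure the study design assumes -- isotropic
# device noise, an arbitrary rigid scanner pose per jaw scan, thrice-averaged
# measurements, and an operator effect modeled as random subsampling of each
# concave's cloud before sphere fitting.

#' Measurement noise model
#'
#' Device accuracy figures are interpreted as 1-sigma isotropic Gaussian
#' noise: per coordinate for the contact probe, per surface point for the
#' optical scanner. Repeated measurements are averaged (three by default, for
#' both the contact "standard data" and the scan-derived "fitting data").
#'
#' @param sigma_contact 1-sigma per-coordinate contact-probe noise, mm
#'   (default 0.024).
#' @param sigma_scan 1-sigma per-point surface-sample noise, mm
#'   (default 0.059).
#' @param n_probe_repeats Averaged contact measurements (default 3).
#' @param n_scan_repeats Averaged sphere-fit centers per scan session
#'   (default 3).
#' @return A `noise_model`.
#' @export
noise_model <- function(sigma_contact = 0.024, sigma_scan = 0.059,
                        n_probe_repeats = 3, n_scan_repeats = 3) {
  if (sigma_contact < 0 || sigma_scan < 0) {
    stop("noise sigmas must be >= 0", call. = FALSE)
  }
  if (n_probe_repeats < 1 || n_scan_repeats < 1) {
    stop("repeat counts must be >= 1", call. = FALSE)
  }
  structure(list(sigma_contact = sigma_contact, sigma_scan = sigma_scan,
                 n_probe_repeats = as.integer(n_probe_repeats),
                 n_scan_repeats = as.integer(n_scan_repeats)),
            class = "noise_model")
}

#' Simulation configuration
#'
#' Bundles everything a full in-silico experiment needs: the plate layout,
#' the noise model, how densely each concave cap is sampled, and the study
#' design (repetitions per operator, number of operators, master seed).
#'
#' @param layout A `plate_layout` (default `default_layout()`).
#' @param noise A `noise_model` (default `noise_model()`).
#' @param points_per_concave Surface samples per concave cloud (default 300).
#' @param cap_half_angle Half-angle in degrees of the spherical cap actually
#'   captured by the scan (default 75: near-hemisphere with slight rim loss).
#' @param operator_subsample_fraction Fraction of each cloud each operator
#'   retains when delimiting the concave region in software; scalar or one
#'   value per operator (default 0.7).
#' @param n_repetitions Alignment/measurement repetitions per operator
#'   (default 15).
#' @param n_operators Number of operators (default 2).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(layout = default_layout(),
                              noise = noise_model(),
                              points_per_concave = 300,
                              cap_half_angle = 75,
                              operator_subsample_fraction = 0.7,
                              n_repetitions = 15,
                              n_operators = 2,
                              seed = 1L) {
  if (points_per_concave < 4) stop("points_per_concave must be >= 4",
                                   call. = FALSE)
  if (cap_half_angle <= 0 || cap_half_angle > 90) {
    stop("cap_half_angle must be in (0, 90] degrees", call. = FALSE)
  }
  frac <- operator_subsample_fraction
  if (any(frac <= 0) || any(frac > 1)) {
    stop("operator_subsample_fraction must be in (0, 1]", call. = FALSE)
  }
  if (n_repetitions < 1 || n_operators < 1) {
    stop("n_repetitions and n_operators must be >= 1", call. = FALSE)
  }
  structure(list(layout = layout, noise = noise,
                 points_per_concave = as.integer(points_per_concave),
                 cap_half_angle = cap_half_angle,
                 operator_subsample_fraction = frac,
                 n_repetitions = as.integer(n_repetitions),
                 n_operators = as.integer(n_operators),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config\n")
  cat(sprintf("  %d points/concave on %g deg cap; sigma_scan %g mm, sigma_contact %g mm\n",
              x$points_per_concave, x$cap_half_angle,
              x$noise$sigma_scan, x$noise$sigma_contact))
  cat(sprintf("  design: %d repetitions x %d operators; seed %d\n",
              x$n_repetitions, x$n_operators, x$seed))
  invisible(x)
}

#' Point cloud sampled from one concave
#'
#' @param points n x 3 matrix, mm.
#' @param source_id Concave label the cloud was sampled from.
#' @param frame_tag Provenance tag.
#' @return A `point_cloud`.
#' @export
point_cloud <- function(points, source_id = NA_character_,
                        frame_tag = "nominal") {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 3 || !all(is.finite(points))) {
    stop("point cloud must be a non-empty n x 3 finite matrix", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, source_id = source_id,
                 frame_tag = frame_tag),
            class = "point_cloud")
}

#' Sample noisy points on a spherical cap
#'
#' Draws `n` points uniformly on the spherical cap of half-angle
#' `cap_half_angle` about `axis` on a sphere of given center and radius, then
#' displaces each by isotropic Gaussian noise of sd `sigma`. With `sigma = 0`
#' every point lies exactly at distance `radius` from the center. Consumes
#' the current RNG stream.
#'
#' @param center Sphere center, length-3, mm.
#' @param radius Sphere radius, mm (> 0).
#' @param axis Outward unit vector of the concave opening.
#' @param n Number of points (>= 1).
#' @param sigma Per-coordinate Gaussian noise sd, mm.
#' @param cap_half_angle Cap half-angle, degrees in (0, 90].
#' @param source_id Optional concave label for the cloud.
#' @return A `point_cloud`.
#' @export
sample_concave_surface <- function(center, radius, axis, n, sigma = 0,
                                   cap_half_angle = 75,
                                   source_id = NA_character_) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  axis <- .unit(as.numeric(axis))
  cos_alpha <- cos(cap_half_angle * pi / 180)
  # area-uniform on the cap: cos(theta) uniform on [cos_alpha, 1]
  ct <- 1 - stats::runif(n) * (1 - cos_alpha)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- stats::runif(n, 0, 2 * pi)
  local <- cbind(st * cos(phi), st * sin(phi), ct)
  # orthonormal basis with third column = axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross3(axis, ref))
  e2 <- .cross3(axis, e1)
  basis <- cbind(e1, e2, axis)
  pts <- local %*% t(basis) * radius
  pts <- sweep(pts, 2, center, "+")
  if (sigma > 0) pts <- pts + matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  point_cloud(pts, source_id = source_id)
}

#' Simulate the contact-probe standard data
#'
#' Each nominal concave center is measured `n_probe_repeats` times with
#' isotropic per-coordinate Gaussian error of sd `sigma_contact` and the
#' measurements are averaged, mirroring the thrice-averaged contact protocol
#' that defines the study's reference ("standard") data.
#'
#' @param layout A `plate_layout`.
#' @param noise A `noise_model`.
#' @param seed Optional substream seed; if `NULL`, consumes the current RNG
#'   stream.
#' @return A `landmark_set` tagged `"standard"` with all 18 concaves.
#' @export
simulate_contact_standard <- function(layout, noise = noise_model(),
                                      seed = NULL) {
  draw <- function() {
    centers <- layout$centers
    n <- nrow(centers)
    acc <- matrix(0, n, 3)
    for (r in seq_len(noise$n_probe_repeats)) {
      acc <- acc + centers +
        matrix(stats::rnorm(3 * n, sd = noise$sigma_contact), n, 3)
    }
    acc / noise$n_probe_repeats
  }
  pts <- if (is.null(seed)) draw() else {
    .with_substream(seed, "contact-standard", draw())
  }
  rownames(pts) <- rownames(layout$centers)
  landmark_set(pts, frame_tag = "standard")
}

# Uniform random proper rotation via normalized quaternion.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Simulate one optical scan session of one jaw
#'
#' Draws a random rigid scanner pose (rotation uniform over proper rotations,
#' translation uniform in a +/-50 mm cube), seeded deterministically by
#' `(seed, jaw, operator, repetition)`, and emits noisy cap samples for each
#' of that jaw's nine concaves in the posed frame. The session carries
#' `n_scan_repeats` independent replicate clouds per concave, all sharing the
#' single session pose (the averaging of the corresponding fitted centers
#' happens in [fit_concave_centers()]). The operator effect is an independent
#' random subsample of `operator_subsample_fraction` of each cloud's points.
#'
#' @param config A `simulation_config`.
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @param operator Operator index (1-based).
#' @param repetition Repetition index (1-based).
#' @return A `scan_session`: list with `clouds` (named list, one entry per
#'   concave label, each a list of `n_scan_repeats` `point_cloud`s),
#'   `true_pose` (the `rigid_transform` applied to the plate), plus the
#'   identifying indices.
#' @export
simulate_scan_session <- function(config, jaw = c("maxillary", "mandibular"),
                                  operator = 1L, repetition = 1L) {
  jaw <- match.arg(jaw)
  layout <- config$layout
  noise <- config$noise
  frac <- config$operator_subsample_fraction
  frac <- if (length(frac) >= operator) frac[[operator]] else frac[[1]]

  .with_substream(config$seed, c("scan-session", jaw, operator, repetition), {
    pose <- rigid_transform(.random_rotation(), stats::runif(3, -50, 50))
    labels <- concave_labels(jaw)
    posed_centers <- apply_transform(pose, layout$centers[labels, , drop = FALSE])
    posed_axes <- layout$axes[labels, , drop = FALSE] %*% t(pose$rotation)
    n_keep <- max(4L, floor(frac * config$points_per_concave))
    clouds <- lapply(seq_along(labels), function(i) {
      lapply(seq_len(noise$n_scan_repeats), function(r) {
        cl <- sample_concave_surface(
          posed_centers[i, ], layout$concave_radius, posed_axes[i, ],
          n = config$points_per_concave, sigma = noise$sigma_scan,
          cap_half_angle = config$cap_half_angle, source_id = labels[i]
        )
        if (n_keep < nrow(cl$points)) {
          keep <- sample.int(nrow(cl$points), n_keep)
          cl$points <- cl$points[keep, , drop = FALSE]
        }
        cl$frame_tag <- sprintf("scan:%s:op%d:rep%d", jaw, operator, repetition)
        cl
      })
    })
    names(clouds) <- labels
    structure(list(clouds = clouds, true_pose = pose, jaw = jaw,
                   operator = as.integer(operator),
                   repetition = as.integer(repetition)),
              class = "scan_session")
  })
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("scan_session: %s jaw, operator %d, repetition %d\n",
              x$jaw, x$operator, x$repetition))
  cat(sprintf("  %d concaves x %d replicate clouds (%d points each)\n",
              length(x$clouds), length(x$clouds[[1]]),
              nrow(x$clouds[[1]][[1]]$points)))
  invisible(x)
}
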