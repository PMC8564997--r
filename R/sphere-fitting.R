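# Best-fit sphere extraction from concave point clouds: an algebraic linear
# least-squares initialization followed by geometric (orthogonal-distance)
# refinement with a damped Gauss-Newton / Levenberg-Marquardt iteration.
# The geometric fit is the reported one, as in standard metrology practice.

#' Construct a sphere fit result
#' @param center Length-3 fitted center, mm.
#' @param radius Fitted radius, mm (> 0).
#' @param rms_residual Root-mean-square of `| |p - center| - radius |`, mm.
#' @param n_points Number of points used.
#' @param converged Logical convergence flag.
#' @return A `sphere_fit`.
#' @keywords internal
.sphere_fit <- function(center, radius, rms_residual, n_points,
                        converged = TRUE) {
  if (radius <= 0 || !is.finite(radius)) {
    stop("degenerate sphere fit: non-positive radius", call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = rms_residual, n_points = as.integer(n_points),
                 converged = converged),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "sphere_fit: center (%.4f, %.4f, %.4f) mm, radius %.4f mm\n",
    x$center[1], x$center[2], x$center[3], x$radius))
  cat(sprintf("  rms residual %.3g mm over %d points; converged: %s\n",
              x$rms_residual, x$n_points, x$converged))
  invisible(x)
}

.cloud_points <- function(cloud) {
  if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
}

.sphere_rms <- function(pts, center, radius) {
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  sqrt(mean((d - radius)^2))
}

#' Algebraic least-squares sphere fit
#'
#' Solves the linear system obtained from expanding
#' `|p|^2 = 2 c . p + (r^2 - |c|^2)` for the center `c` and radius `r`.
#' Exact on noiseless spherical data; used to initialize the geometric fit.
#'
#' @param cloud A `point_cloud` or n x 3 matrix (n >= 4, not all coplanar).
#' @return A `sphere_fit`.
#' @export
fit_sphere_algebraic <- function(cloud) {
  pts <- .cloud_points(cloud)
  n <- nrow(pts)
  if (n < 4) stop("degenerate fit: at least 4 points required", call. = FALSE)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4) {
    stop("degenerate fit: points are coplanar or collinear", call. = FALSE)
  }
  beta <- unname(qr.coef(qr_A, b))
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate fit: non-positive squared radius", call. = FALSE)
  }
  radius <- sqrt(r2)
  .sphere_fit(center, radius, .sphere_rms(pts, center, radius), n)
}

#' Geometric (orthogonal-distance) sphere fit
#'
#' Minimizes the geometric objective `sum_i (|p_i - c| - r)^2` by a damped
#' Gauss-Newton (Levenberg-Marquardt) iteration started from `init`. Steps
#' are only accepted when they decrease the objective, so the returned fit is
#' never worse than the initialization. With `fixed_radius` the radius is
#' held and only the center is optimized.
#'
#' Convergence is declared when the gradient norm falls below `gtol`
#' (default 1e-10) within `max_iter` iterations (default 100);
#' non-convergence is flagged, not fatal.
#'
#' @param cloud A `point_cloud` or n x 3 matrix.
#' @param init Initial `sphere_fit`; defaults to [fit_sphere_algebraic()].
#' @param fixed_radius Optional radius in mm to hold fixed.
#' @param gtol Gradient-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `sphere_fit` with `converged` reflecting the stopping reason.
#' @export
fit_sphere_geometric <- function(cloud, init = NULL, fixed_radius = NULL,
                                 gtol = 1e-10, max_iter = 100) {
  pts <- .cloud_points(cloud)
  n <- nrow(pts)
  if (is.null(init)) init <- fit_sphere_algebraic(pts)
  if (!is.null(fixed_radius) && fixed_radius <= 0) {
    stop("fixed_radius must be > 0", call. = FALSE)
  }
  free_r <- is.null(fixed_radius)
  center <- init$center
  radius <- if (free_r) init$radius else fixed_radius

  obj_of <- function(center, radius) {
    d <- sqrt(rowSums(sweep(pts, 2, center)^2))
    list(d = d, e = d - radius, obj = sum((d - radius)^2))
  }
  cur <- obj_of(center, radius)
  if (!is.finite(cur$obj)) {
    stop("numerical failure: non-finite sphere objective", call. = FALSE)
  }
  lambda <- 1e-6
  converged <- FALSE
  npar <- if (free_r) 4L else 3L
  for (iter in seq_len(max_iter)) {
    d <- pmax(cur$d, 1e-12)
    # residual e_i = d_i - r; d e_i / d c = -(p_i - c)/d_i ; d e_i / d r = -1
    U <- -sweep(sweep(pts, 2, center), 1, d, "/")
    J <- if (free_r) cbind(U, -1) else U
    g <- 2 * crossprod(J, cur$e)
    if (sqrt(sum(g^2)) < gtol) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:25) {
      H <- JtJ + lambda * diag(npar)
      delta <- tryCatch(solve(H, -crossprod(J, cur$e)),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand_c <- center + delta[1:3]
        cand_r <- if (free_r) radius + delta[4] else radius
        if (cand_r > 0) {
          cand <- obj_of(cand_c, cand_r)
          if (is.finite(cand$obj) && cand$obj < cur$obj) {
            center <- cand_c; radius <- cand_r; cur <- cand
            lambda <- max(lambda / 10, 1e-12)
            step_ok <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- sqrt(sum(g^2)) < 1e-6; break }
  }
  .sphere_fit(center, radius, sqrt(cur$obj / n), n, converged = converged)
}

#' Fit and average concave centers for one scan session
#'
#' Applies the two-stage sphere fit to each of the session's replicate clouds
#' per concave and averages the fitted centers, producing the per-session
#' "fitting data" landmark set (mean of `n_scan_repeats` fitted centers).
#'
#' @param session A `scan_session` (or a named list of lists of clouds
#'   covering one jaw's nine concaves).
#' @param fixed_radius Optional radius in mm to hold fixed during refinement
#'   (the nominal concave radius is known by design); default free.
#' @return A `landmark_set` tagged `"fitted:<jaw>"`.
#' @export
fit_concave_centers <- function(session, fixed_radius = NULL) {
  clouds <- if (inherits(session, "scan_session")) session$clouds else session
  labels <- names(clouds)
  jaws <- unique(concave_jaw(labels))
  if (length(jaws) != 1 || length(labels) != 9) {
    stop("session clouds must cover exactly one jaw's 9 concaves",
         call. = FALSE)
  }
  centers <- matrix(NA_real_, length(labels), 3,
                    dimnames = list(labels, c("x", "y", "z")))
  for (lab in labels) {
    reps <- clouds[[lab]]
    if (inherits(reps, "point_cloud")) reps <- list(reps)
    fits <- lapply(reps, function(cl) {
      tryCatch(fit_sphere_geometric(cl, fixed_radius = fixed_radius),
               error = function(e) {
                 stop("sphere fit failed for concave ", lab, ": ",
                      conditionMessage(e), call. = FALSE)
               })
    })
    centers[lab, ] <- colMeans(do.call(rbind, lapply(fits, `[[`, "center")))
  }
  landmark_set(centers, frame_tag = paste0("fitted:", jaws))
}
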