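# Equal-weight reference-point rigid alignment: the construction step that
# places each jaw's scan-derived "fitting data" into the frame of the
# contact-measured standard data using a chosen subset of labelled concave
# centers. Closed-form Kabsch solution: centroid subtraction, 3x3
# cross-covariance, SVD, determinant sign correction. No scaling term --
# plates and models are treated as rigid bodies.

#' Equal-weight rigid landmark alignment (Kabsch)
#'
#' Returns the rigid transform `T` minimizing
#' `sum_i || T(source_i) - target_i ||^2` over the given landmark labels,
#' with equal weight on every landmark. The rotation comes from the SVD of
#' the centered cross-covariance with determinant sign correction, so the
#' result is always a proper rotation (never a reflection) and is the global
#' optimum of the equal-weight least-squares objective.
#'
#' @param source,target `landmark_set` objects sharing the labels in `ids`.
#' @param ids Concave labels to align on (at least 3, non-collinear in
#'   `source`).
#' @return The optimal `rigid_transform` mapping source onto target.
#' @export
kabsch_align <- function(source, target, ids = NULL) {
  src <- if (inherits(source, "landmark_set")) source$points else as.matrix(source)
  tgt <- if (inherits(target, "landmark_set")) target$points else as.matrix(target)
  if (is.null(ids)) ids <- intersect(rownames(src), rownames(tgt))
  .check_labels(ids)
  missing_s <- setdiff(ids, rownames(src))
  missing_t <- setdiff(ids, rownames(tgt))
  if (length(missing_s) || length(missing_t)) {
    stop("landmarks missing from ",
         if (length(missing_s)) paste0("source: ", paste(missing_s, collapse = ", ")),
         if (length(missing_s) && length(missing_t)) "; ",
         if (length(missing_t)) paste0("target: ", paste(missing_t, collapse = ", ")),
         call. = FALSE)
  }
  if (length(ids) < 3) {
    stop("insufficient landmarks: at least 3 required for rigid alignment",
         call. = FALSE)
  }
  S <- src[ids, , drop = FALSE]
  Tg <- tgt[ids, , drop = FALSE]
  cs <- colMeans(S)
  ct <- colMeans(Tg)
  Sc <- sweep(S, 2, cs)
  Tc <- sweep(Tg, 2, ct)
  # collinearity = centered source has rank <= 1, i.e. second singular value
  # vanishes (the smallest is always ~0 for coplanar configurations, which
  # are fine)
  sv_src <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_src[2] < 1e-9) {
    stop("degenerate configuration: alignment landmarks are collinear",
         call. = FALSE)
  }
  H <- crossprod(Sc, Tc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(ct - R %*% cs))
}

#' Fiducial registration error
#'
#' Root-mean-square residual `sqrt(mean_i || T(source_i) - target_i ||^2)`
#' at the landmarks used for alignment. Zero iff the correspondence is
#' exact. Distinct from the error at held-out (target) points, which is what
#' the accuracy evaluation measures downstream.
#'
#' @param t A `rigid_transform`.
#' @param source,target `landmark_set` objects.
#' @param ids Labels over which to evaluate (default: common labels).
#' @return RMS residual in mm.
#' @export
fiducial_registration_error <- function(t, source, target, ids = NULL) {
  src <- if (inherits(source, "landmark_set")) source$points else as.matrix(source)
  tgt <- if (inherits(target, "landmark_set")) target$points else as.matrix(target)
  if (is.null(ids)) ids <- intersect(rownames(src), rownames(tgt))
  .check_labels(ids)
  if (length(ids) < 1) stop("no landmarks to evaluate", call. = FALSE)
  mapped <- apply_transform(t, src[ids, , drop = FALSE])
  sqrt(mean(rowSums((mapped - tgt[ids, , drop = FALSE])^2)))
}

#' Construct the intercuspal relation from per-jaw fitted landmarks
#'
#' Aligns the maxillary fitting data onto the standard data using the
#' group's maxillary reference labels, and the mandibular fitting data using
#' the mandibular partners, placing both jaws in the common standard frame --
#' the in-silico equivalent of reconstructing the intercuspal jaw relation
#' from two separate scans. Registration is per-jaw against the standard
#' set (which encodes the articulator-frame jaw relation), never jaw to jaw.
#'
#' @param fitted_max,fitted_mand `landmark_set`s of the two jaws' fitted
#'   centers (any frame).
#' @param standard The contact-measured standard `landmark_set` (18 labels).
#' @param ref_maxillary Maxillary labels of the group's reference pairs;
#'   their mandibular partners are used for the mandibular alignment.
#' @param group Optional group index used in the output frame tags.
#' @return List with aligned `maxillary` and `mandibular` landmark sets
#'   (frame tag `"aligned:group<g>"`), the two transforms and the two
#'   fiducial registration errors.
#' @export
construct_icp_relation <- function(fitted_max, fitted_mand, standard,
                                   ref_maxillary, group = NA_integer_) {
  .check_labels(ref_maxillary)
  if (any(concave_jaw(ref_maxillary) != "maxillary")) {
    stop("ref_maxillary must contain maxillary labels only", call. = FALSE)
  }
  ref_mand <- pair_of(ref_maxillary)
  t_max <- kabsch_align(fitted_max, standard, ref_maxillary)
  t_mand <- kabsch_align(fitted_mand, standard, ref_mand)
  tag <- if (is.na(group)) "aligned" else sprintf("aligned:group%s", group)
  list(
    maxillary  = apply_transform(t_max, fitted_max, frame_tag = tag),
    mandibular = apply_transform(t_mand, fitted_mand, frame_tag = tag),
    transform_maxillary  = t_max,
    transform_mandibular = t_mand,
    fre_maxillary  = fiducial_registration_error(t_max, fitted_max, standard,
                                                 ref_maxillary),
    fre_mandibular = fiducial_registration_error(t_mand, fitted_mand, standard,
                                                 ref_mand)
  )
}
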