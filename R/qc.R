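# Shape-based quality control: four scores and interquartile-range fences.

#' Mean contour-to-model fit error
#'
#' Mean over contour points of the Euclidean distance to the nearest model
#' point. The nearest model *surface* point is approximated by the nearest
#' model vertex; with a dense mesh the difference is negligible, and no
#' face connectivity is assumed.
#'
#' @param mesh a [surface_mesh] (the fitted model).
#' @param contours a `contour_set` (e.g. from [degrade_to_contours]).
#' @return mean distance in mm.
#' @export
contour_fit_error <- function(mesh, contours) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(contours, "contour_set"))
  cp <- contours$points
  if (is.null(cp) || nrow(cp) == 0L) stop("empty contour set")
  mp <- mesh$points
  # squared distance matrix via |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(cp^2), rowSums(mp^2), "+") - 2 * tcrossprod(cp, mp)
  mean(sqrt(pmax(0, apply(d2, 1L, min))))
}

#' Mahalanobis shape distance
#'
#' Root sum of squares of the leading PC Z-scores (by default the first 10).
#' Because training-set Z-scores are unit-variance and uncorrelated, this is
#' the Mahalanobis distance of the shape in the retained mode subspace.
#'
#' @param z10 numeric vector of Z-scores.
#' @param expected_length required component count (default 10).
#' @return the distance `D = sqrt(sum(z^2))`.
#' @export
mahalanobis_distance <- function(z10, expected_length = 10L) {
  if (length(z10) != expected_length)
    stop(sprintf("expected %d z-score components, got %d",
                 expected_length, length(z10)))
  sqrt(sum(z10^2))
}

#' Residual of a mesh after projection onto leading modes
#'
#' RMS per-point distance (mm) between the aligned mesh and its
#' reconstruction from the first `n_modes` atlas modes.
#'
#' @param atlas a `shape_atlas`.
#' @param mesh a [surface_mesh].
#' @param n_modes number of leading modes (must not exceed the atlas rank).
#' @param align rigid-align the mesh to the atlas mean first (default).
#' @return RMS residual in mm.
#' @export
projection_residual <- function(atlas, mesh, n_modes = 10L, align = TRUE) {
  stopifnot(inherits(atlas, "shape_atlas"), inherits(mesh, "surface_mesh"))
  if (n_modes > ncol(atlas$modes)) stop("n_modes exceeds the atlas rank")
  if (align)
    mesh <- rigid_align_pair(mesh,
                             surface_mesh(vec_to_points(atlas$mean_shape),
                                          "mean"))
  d <- mesh_to_vec(mesh) - atlas$mean_shape
  V <- atlas$modes[, seq_len(n_modes), drop = FALSE]
  resid <- d - drop(V %*% crossprod(V, d))
  sqrt(sum(resid^2) / atlas$n_points)
}

#' Interquartile-range outlier flags
#'
#' Tukey-style fences with a wide multiplier: values outside
#' `[Q1 - m*IQR, Q3 + m*IQR]` are flagged (`fence_variant = "symmetric"`,
#' the default). The literal asymmetric reading of the rule -- flag values
#' more than `m*IQR` *above the lower quartile* or *below the upper
#' quartile* -- is available as `fence_variant = "literal"`. Quartiles use
#' linear interpolation between order statistics ([stats::quantile] type 7);
#' fence placement depends on this convention, hence it is fixed and
#' documented. A zero IQR with non-constant data flags every value away
#' from the median beyond a small absolute tolerance; constant data flags
#' nothing.
#'
#' @param scores numeric vector (at least 4 finite values).
#' @param multiplier fence multiplier `m` (default 5).
#' @param fence_variant `"symmetric"` (default) or `"literal"`.
#' @return logical vector of flags (NA scores are flagged).
#' @export
iqr_outlier_flags <- function(scores, multiplier = 5,
                              fence_variant = c("symmetric", "literal")) {
  fence_variant <- match.arg(fence_variant)
  ok <- is.finite(scores)
  if (sum(ok) < 4L) stop("need at least 4 finite values")
  q <- quantile(scores[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  flags <- !ok
  if (iqr <= 0) {
    if (any(scores[ok] != scores[ok][1L]))
      flags[ok] <- abs(scores[ok] - q[2]) >
        1e-8 * max(1, abs(q[2]))
    return(flags)
  }
  if (fence_variant == "symmetric") {
    lo <- q[1] - multiplier * iqr
    hi <- q[3] + multiplier * iqr
  } else {
    lo <- q[3] - multiplier * iqr
    hi <- q[1] + multiplier * iqr
  }
  flags[ok] <- scores[ok] < lo | scores[ok] > hi
  flags
}

#' Shape quality-control report
#'
#' Computes the four shape-based quality scores for every subject --
#' (1) mean contour fit error in mm, (2) the individual Z-scores of the
#' first `n_modes` PCs, (3) the Mahalanobis distance over those scores, and
#' (4) the projection residual in mm -- and applies the `multiplier` x IQR
#' fence to each. A subject is excluded if any score is flagged; for the
#' Z-scores the fence is applied per component and a subject is flagged if
#' any component falls outside its fence.
#'
#' @param atlas a `shape_atlas`.
#' @param meshes list of [surface_mesh].
#' @param contours optional list of `contour_set`, parallel to `meshes`;
#'   when absent the contour-error score is skipped.
#' @param n_modes leading modes used for scores 2-4 (default 10).
#' @param multiplier IQR fence multiplier (default 5).
#' @param fence_variant passed to [iqr_outlier_flags].
#' @return data.frame with one row per subject: the scores, per-score
#'   flags (`flag_contour`, `flag_z`, `flag_mahalanobis`, `flag_residual`)
#'   and `excluded`.
#' @export
shape_qc <- function(atlas, meshes, contours = NULL, n_modes = 10L,
                     multiplier = 5, fence_variant = "symmetric") {
  stopifnot(inherits(atlas, "shape_atlas"))
  if (n_modes > ncol(atlas$modes)) stop("n_modes exceeds the atlas rank")
  if (!is.null(contours) && length(contours) != length(meshes))
    stop("`contours` must parallel `meshes`")
  mean_mesh <- surface_mesh(vec_to_points(atlas$mean_shape), "mean")
  V <- atlas$modes[, seq_len(n_modes), drop = FALSE]
  root_l <- sqrt(atlas$eigenvalues[seq_len(n_modes)])
  n <- length(meshes)
  z <- matrix(NA_real_, n, n_modes)
  residual <- numeric(n)
  cerr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- rigid_align_pair(meshes[[i]], mean_mesh)
    d <- mesh_to_vec(m) - atlas$mean_shape
    proj <- drop(crossprod(V, d))
    z[i, ] <- proj / root_l
    r <- d - drop(V %*% proj)
    residual[i] <- sqrt(sum(r^2) / atlas$n_points)
    if (!is.null(contours))
      cerr[i] <- contour_fit_error(m, contours[[i]])
  }
  mahal <- sqrt(rowSums(z^2))

  flag_z_mat <- apply(z, 2L, iqr_outlier_flags, multiplier = multiplier,
                      fence_variant = fence_variant)
  flag_z <- rowSums(flag_z_mat) > 0
  flag_m <- iqr_outlier_flags(mahal, multiplier, fence_variant)
  flag_r <- iqr_outlier_flags(residual, multiplier, fence_variant)
  flag_c <- if (is.null(contours)) rep(FALSE, n)
            else iqr_outlier_flags(cerr, multiplier, fence_variant)

  out <- data.frame(
    subject_id = vapply(meshes, `[[`, character(1), "subject_id"),
    contour_error_mm = cerr, mahalanobis = mahal, residual_mm = residual,
    stringsAsFactors = FALSE)
  colnames(z) <- paste0("z", seq_len(n_modes))
  out <- cbind(out, z)
  out$flag_contour <- flag_c
  out$flag_z <- flag_z
  out$flag_mahalanobis <- flag_m
  out$flag_residual <- flag_r
  out$excluded <- flag_c | flag_z | flag_m | flag_r
  out
}
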