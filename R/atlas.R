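# Shape atlas: rigid alignment, generalized Procrustes, PCA modes, scores.

#' Rigidly align one mesh to a reference
#'
#' Least-squares rigid superimposition of corresponded points: translation
#' plus proper rotation only (Kabsch solution via SVD of the 3x3
#' cross-covariance with determinant sign correction). Scale is never
#' removed and reflections are never applied, so centroid size is preserved.
#'
#' @param mesh,reference [surface_mesh] objects with equal point counts.
#' @return The aligned [surface_mesh] (same `subject_id`/`wall`).
#' @export
rigid_align_pair <- function(mesh, reference) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(reference, "surface_mesh"))
  a <- mesh$points
  b <- reference$points
  if (nrow(a) != nrow(b)) stop("meshes must share the same point count")
  ca <- mesh_centroid(a)
  cb <- mesh_centroid(b)
  ac <- sweep(a, 2, ca)
  bc <- sweep(b, 2, cb)
  if (max(abs(ac)) < 1e-12 || max(abs(bc)) < 1e-12)
    stop("degenerate mesh: all points coincident")
  h <- crossprod(ac, bc)                  # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(ac %*% t(rot), 2, cb, "+")
  surface_mesh(out, mesh$subject_id, wall = mesh$wall)
}

#' Generalized Procrustes alignment of a mesh cohort
#'
#' Iterates rigid alignment of every mesh to the current consensus and
#' replacement of the consensus by the pointwise mean (re-centred at the
#' origin) until the consensus moves less than `tol` mm RMS or `max_iter`
#' iterations are reached. The first mesh seeds the consensus.
#'
#' @param meshes list of at least two [surface_mesh] with common `P`.
#' @param tol RMS consensus-change convergence tolerance, mm.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   best iterate.
#' @return list with `aligned` (list of meshes), `consensus` (mean shape,
#'   centred at the origin) and `n_iterations`.
#' @export
generalized_procrustes <- function(meshes, tol = 1e-9, max_iter = 100L) {
  if (length(meshes) < 2L) stop("need at least two meshes")
  P <- nrow(meshes[[1L]]$points)
  if (!all(vapply(meshes, function(m) nrow(m$points), integer(1)) == P))
    stop("all meshes must share the same point count")
  consensus <- sweep(meshes[[1L]]$points, 2,
                     mesh_centroid(meshes[[1L]]$points))
  aligned <- meshes
  n_it <- 0L
  converged <- FALSE
  cons_mesh <- surface_mesh(consensus, "consensus")
  for (it in seq_len(max_iter)) {
    n_it <- it
    aligned <- lapply(aligned, rigid_align_pair, reference = cons_mesh)
    new_cons <- Reduce(`+`, lapply(aligned, `[[`, "points")) / length(aligned)
    new_cons <- sweep(new_cons, 2, mesh_centroid(new_cons))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    cons_mesh <- surface_mesh(consensus, "consensus")
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge; returning best iterate")
  list(aligned = lapply(aligned, rigid_align_pair, reference = cons_mesh),
       consensus = cons_mesh, n_iterations = n_it)
}

#' Build a PCA shape atlas from aligned meshes
#'
#' Eigendecomposition of the sample covariance (divisor `n - 1`) of the
#' stacked 3P shape vectors, computed through the thin SVD of the centred
#' data matrix for stability when `3P >> n`. Modes are ordered by
#' descending eigenvalue with a deterministic sign convention: the
#' largest-magnitude loading of each mode is positive. Variance fractions
#' are `lambda_k / sum(lambda)`; because the retained eigenvalues carry the
#' whole trace, the fractions sum to one over the full rank.
#'
#' @param aligned list of aligned [surface_mesh] (output of
#'   [generalized_procrustes]), at least two.
#' @return A `shape_atlas`: `mean_shape` (3P vector), `modes`
#'   (3P x K orthonormal), `eigenvalues`, `variance_fractions`, `n_train`,
#'   `n_points`.
#' @export
build_atlas <- function(aligned) {
  n <- length(aligned)
  if (n < 2L) stop("need at least two meshes to build an atlas")
  X <- t(vapply(aligned, mesh_to_vec,
                numeric(3L * nrow(aligned[[1L]]$points))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  r <- min(n - 1L, ncol(X))
  lambda <- (sv$d^2 / (n - 1L))[seq_len(r)]
  modes <- sv$v[, seq_len(r), drop = FALSE]
  for (k in seq_len(r)) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(list(mean_shape = mu, modes = modes, eigenvalues = lambda,
                 variance_fractions = lambda / sum(lambda),
                 n_train = n, n_points = nrow(aligned[[1L]]$points)),
            class = "shape_atlas")
}

#' @export
print.shape_atlas <- function(x, ...) {
  cat(sprintf("<shape_atlas> %d training shapes, %d points, %d modes\n",
              x$n_train, x$n_points, ncol(x$modes)))
  top <- head(x$variance_fractions, 5)
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", top), collapse = " "), "\n")
  invisible(x)
}

.check_mode_idx <- function(atlas, modes) {
  modes <- as.integer(modes)
  if (any(modes < 1L | modes > ncol(atlas$modes)))
    stop("mode index out of range")
  modes
}

.nonzero_lambda <- function(atlas, modes) {
  tol <- 1e-12 * max(atlas$eigenvalues[1], 1)
  if (any(atlas$eigenvalues[modes] <= tol))
    stop("requested mode has a zero eigenvalue; Z-scores undefined")
}

#' Score meshes against an atlas
#'
#' Projects each (optionally rigid-aligned) mesh onto the atlas modes and
#' standardizes by `sqrt(lambda_k)`, so training-set scores have unit
#' variance per mode: `z_k = v_k' (x - mu) / sqrt(lambda_k)`. These PC
#' Z-scores are the phenotypes used downstream.
#'
#' @param atlas a `shape_atlas`.
#' @param meshes list of [surface_mesh] with the atlas point count.
#' @param align rigid-align each mesh to the atlas mean first (default).
#' @param modes mode indices to score (default all).
#' @return data.frame: `subject_id` plus columns `z1..zK`.
#' @export
score_shapes <- function(atlas, meshes, align = TRUE,
                         modes = seq_len(ncol(atlas$modes))) {
  stopifnot(inherits(atlas, "shape_atlas"))
  modes <- .check_mode_idx(atlas, modes)
  .nonzero_lambda(atlas, modes)
  mean_mesh <- surface_mesh(vec_to_points(atlas$mean_shape), "mean")
  V <- atlas$modes[, modes, drop = FALSE]
  root_l <- sqrt(atlas$eigenvalues[modes])
  rows <- lapply(meshes, function(m) {
    if (nrow(m$points) != atlas$n_points)
      stop("mesh point count does not match the atlas")
    if (align) m <- rigid_align_pair(m, mean_mesh)
    drop(crossprod(V, mesh_to_vec(m) - atlas$mean_shape)) / root_l
  })
  z <- do.call(rbind, rows)
  out <- data.frame(subject_id = vapply(meshes, `[[`, character(1),
                                        "subject_id"),
                    z, stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("z", modes)
  out
}

#' Select modes above a variance-fraction threshold
#'
#' Returns the indices of modes whose variance fraction strictly exceeds
#' `threshold` (the "individually captured > 1% variance" convention).
#'
#' @param atlas a `shape_atlas`.
#' @param threshold fraction in (0, 1); default 0.01.
#' @return integer vector of mode indices, in order.
#' @export
select_modes <- function(atlas, threshold = 0.01) {
  stopifnot(inherits(atlas, "shape_atlas"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  which(atlas$variance_fractions > threshold)
}

#' Reconstruct a shape from atlas scores
#'
#' `x = mu + sum_k z_k * sqrt(lambda_k) * v_k`. Setting a single score to
#' +/-2 renders the familiar two-SD extreme shapes of a mode.
#'
#' @param atlas a `shape_atlas`.
#' @param z numeric scores, one per entry of `modes`.
#' @param modes mode indices (default `seq_along(z)`).
#' @return A [surface_mesh].
#' @export
reconstruct_shape <- function(atlas, z, modes = seq_along(z)) {
  stopifnot(inherits(atlas, "shape_atlas"))
  modes <- .check_mode_idx(atlas, modes)
  if (length(z) != length(modes)) stop("`z` and `modes` lengths differ")
  x <- atlas$mean_shape +
    drop(atlas$modes[, modes, drop = FALSE] %*%
           (z * sqrt(atlas$eigenvalues[modes])))
  surface_mesh(vec_to_points(x), "reconstruction")
}

#' Percent subgroup variance captured by listed modes
#'
#' After rigid alignment of each subgroup mesh to the atlas mean, computes
#' `100 *` (variance of the subgroup's raw mode projections, taken about the
#' subgroup's own mean) / (total subgroup variance about the subgroup's own
#' mean). On the training set with all modes this is 100 by construction.
#'
#' @param atlas a `shape_atlas`.
#' @param meshes subgroup meshes (non-empty list).
#' @param modes mode indices defining the captured subspace.
#' @param align rigid-align each mesh to the atlas mean first (default).
#' @return percentage (scalar).
#' @export
subgroup_variance_explained <- function(atlas, meshes,
                                        modes = seq_len(ncol(atlas$modes)),
                                        align = TRUE) {
  stopifnot(inherits(atlas, "shape_atlas"))
  if (length(meshes) == 0L) stop("empty subgroup")
  modes <- .check_mode_idx(atlas, modes)
  mean_mesh <- surface_mesh(vec_to_points(atlas$mean_shape), "mean")
  X <- t(vapply(meshes, function(m) {
    if (align) m <- rigid_align_pair(m, mean_mesh)
    mesh_to_vec(m)
  }, numeric(length(atlas$mean_shape))))
  Xc <- sweep(X, 2, colMeans(X))
  total <- sum(Xc^2) / (nrow(X) - 1L)
  proj <- Xc %*% atlas$modes[, modes, drop = FALSE]
  captured <- sum(proj^2) / (nrow(X) - 1L)
  100 * captured / total
}
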