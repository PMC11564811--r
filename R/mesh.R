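#' Surface mesh objects
#'
#' A `surface_mesh` holds one subject's corresponded 3-D surface points: a
#' `P x 3` coordinate matrix in millimetres. Point rows correspond across
#' subjects of a cohort (same anatomical location, same row), which is what
#' makes pointwise averaging and PCA of stacked coordinates meaningful.
#'
#' @param points numeric `P x 3` matrix of coordinates (mm).
#' @param subject_id identifier for the subject (scalar character).
#' @param wall optional per-point labels (e.g. `"lv"`/`"rv"` shell membership).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(points, subject_id = "template", wall = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns (x, y, z)")
  if (!all(is.finite(points))) stop("mesh coordinates must be finite")
  if (!is.null(wall) && length(wall) != nrow(points))
    stop("`wall` must have one label per point")
  structure(list(subject_id = as.character(subject_id)[1L],
                 points = unname(points), wall = wall),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> subject '%s', %d points\n",
              x$subject_id, nrow(x$points)))
  invisible(x)
}

# Flatten to (x1, y1, z1, x2, ...) -- the 3P shape vector used throughout.
mesh_to_vec <- function(mesh) as.numeric(t(mesh$points))

vec_to_points <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

mesh_centroid <- function(points) colMeans(points)

# Deterministic near-uniform point set on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Build the biventricular template mesh
#'
#' Samples `n_points` deterministic points on two intersecting ellipsoidal
#' shells standing in for the left- and right-ventricular surfaces of a
#' subdivision-surface heart template. Only the point correspondence and the
#' latent mode structure built on top of it matter for the downstream
#' statistics, not anatomical fidelity.
#'
#' @param n_points total number of template points (at least 12; split as
#'   evenly as possible between the two shells, LV first).
#' @param geometry_params optional list overriding any of `lv_center`,
#'   `lv_axes`, `rv_center`, `rv_axes` (ellipsoid centres and semi-axes, mm).
#' @return A [surface_mesh] with `wall` labels `"lv"`/`"rv"`.
#' @examples
#' tpl <- make_template(300)
#' @export
make_template <- function(n_points = 300L, geometry_params = list()) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 12L)
    stop("`n_points` must be at least 12 to cover both shells")
  geo <- utils::modifyList(
    list(lv_center = c(0, 0, 0),   lv_axes = c(35, 35, 50),
         rv_center = c(40, 0, -5), rv_axes = c(45, 30, 45)),
    geometry_params)
  n_lv <- ceiling(n_points / 2)
  n_rv <- n_points - n_lv
  lv <- sweep(fibonacci_sphere(n_lv) %*% diag(geo$lv_axes), 2, geo$lv_center, "+")
  rv <- sweep(fibonacci_sphere(n_rv) %*% diag(geo$rv_axes), 2, geo$rv_center, "+")
  surface_mesh(rbind(lv, rv), subject_id = "template",
               wall = rep(c("lv", "rv"), c(n_lv, n_rv)))
}
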