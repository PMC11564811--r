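# Synthetic shape populations: template + latent modes + noise + rigid motion.

# Uniform random proper rotation (QR of a Gaussian 3x3 with sign fix).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Orthonormal basis of the rigid-motion subspace at a template: three
# translations and three infinitesimal rotations about its centroid.
rigid_motion_basis <- function(points) {
  P <- nrow(points)
  ctr <- sweep(points, 2, colMeans(points))
  fields <- matrix(0, 3L * P, 6L)
  for (a in 1:3) fields[seq(a, 3L * P, by = 3L), a] <- 1
  ex <- cbind(rep(0, P), -ctr[, 3], ctr[, 2])
  ey <- cbind(ctr[, 3], rep(0, P), -ctr[, 1])
  ez <- cbind(-ctr[, 2], ctr[, 1], rep(0, P))
  fields[, 4] <- as.numeric(t(ex))
  fields[, 5] <- as.numeric(t(ey))
  fields[, 6] <- as.numeric(t(ez))
  qr.Q(qr(fields))
}

# K orthonormal 3P-vector displacement fields with a deterministic sign
# convention (largest-|entry| coordinate positive). Fields are built
# orthogonal to the template's rigid-motion subspace: a rigid component is
# pose, not shape, and would be removed by Procrustes alignment anyway.
orthonormal_fields <- function(three_p, k, template_points) {
  m <- matrix(rnorm(three_p * k), three_p, k)
  rb <- rigid_motion_basis(template_points)
  m <- m - rb %*% crossprod(rb, m)
  q <- qr.Q(qr(m))
  for (j in seq_len(k)) {
    i <- which.max(abs(q[, j]))
    if (q[i, j] < 0) q[, j] <- -q[, j]
  }
  q
}

#' Simulate a mesh population with latent shape modes
#'
#' Subject `i`'s shape vector is
#' `template + sum_k z_ik * sd_k * sqrt(3P) * U_k + noise`, where the `U_k`
#' are fixed orthonormal 3P displacement fields, `z_ik` are unit-variance
#' latent scores and the noise is iid Gaussian per coordinate. Scaling by
#' `sqrt(3P)` makes `mode_sds[k]` the per-coordinate RMS displacement in mm,
#' so the population eigenvalue of mode `k` is `3P * sd_k^2`. Each mesh is
#' then given an independent random rotation and translation, which the
#' Procrustes alignment must undo.
#'
#' With `genotypes` supplied, each latent score is split into a genetic part
#' (a weighted sum of standardized causal dosages, one causal variant per LD
#' block so causal dosages are mutually independent) and an environmental
#' part, with exact in-sample variance shares `per_mode_h2[k]` and
#' `1 - per_mode_h2[k]`.
#'
#' `cfg$n_outliers` subjects can be displaced `cfg$outlier_sd` latent SDs
#' along `cfg$outlier_mode` to provide ground-truth outliers for QC tests.
#'
#' @param cfg a [sim_config].
#' @param template a [surface_mesh], usually from [make_template].
#' @param genotypes optional result of [sample_genotypes] (same config).
#' @param mode_fields optional 3P x K orthonormal matrix reusing another
#'   population's displacement fields (e.g. to draw a held-out cohort from
#'   the same generative model).
#' @param true_betas optional m x K matrix of standardized-dosage effects
#'   reusing another population's genetic architecture (implies
#'   `genotypes`).
#' @return list with `meshes` (list of [surface_mesh]) and `truth`, a
#'   `truth_record` holding `true_latent_scores` (n x K), per-mode
#'   `causal_variant_ids`, `true_betas` (m x K, standardized-dosage scale),
#'   `true_h2`, `injected_outlier_ids`, and the generating `mode_fields`,
#'   `mode_sds` and `template`.
#' @export
sample_shape_population <- function(cfg, template, genotypes = NULL,
                                    mode_fields = NULL, true_betas = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(template, "surface_mesh"))
  P <- nrow(template$points)
  three_p <- 3L * P
  K <- cfg$n_latent_modes
  n <- cfg$n_subjects
  if (K > three_p - 6L)
    stop("cannot build orthonormal fields: K exceeds 3P - 6 (the rigid-motion subspace is reserved)")

  set.seed(cfg$seed + 101L)
  U <- if (is.null(mode_fields))
         orthonormal_fields(three_p, K, template$points)
       else {
         if (!all(dim(mode_fields) == c(three_p, K)))
           stop("`mode_fields` dimensions do not match the config")
         mode_fields
       }

  causal_ids <- vector("list", K)
  if (!is.null(true_betas)) {
    if (is.null(genotypes)) stop("`true_betas` requires `genotypes`")
    geno <- genotypes$geno
    if (nrow(geno) != n) stop("genotype matrix does not match n_subjects")
    zg_all <- scale(geno)
    z <- matrix(0, n, K)
    for (k in seq_len(K)) {
      j <- which(true_betas[, k] != 0)
      causal_ids[[k]] <- genotypes$variants$variant_id[j]
      g <- as.numeric(zg_all[, j, drop = FALSE] %*% true_betas[j, k])
      z[, k] <- g + rnorm(n, sd = sqrt(max(0, 1 - cfg$per_mode_h2[k])))
    }
  } else if (is.null(genotypes)) {
    z <- matrix(rnorm(n * K), n, K)
  } else {
    geno <- genotypes$geno
    vtab <- genotypes$variants
    if (nrow(geno) != n) stop("genotype matrix does not match n_subjects")
    blocks <- vtab$block
    n_blocks <- max(blocks)
    if (K * cfg$causal_per_mode > n_blocks)
      stop("not enough LD blocks for the requested causal architecture")
    true_betas <- matrix(0, ncol(geno), K,
                         dimnames = list(vtab$variant_id, NULL))
    z <- matrix(0, n, K)
    blk_first <- match(seq_len(n_blocks), blocks)  # first variant per block
    for (k in seq_len(K)) {
      # round-robin block assignment spreads each mode's causal variants
      # across the genome, so distinct causal variants land in distinct loci
      blk <- seq(k, n_blocks, by = K)[seq_len(cfg$causal_per_mode)]
      j <- blk_first[blk]
      causal_ids[[k]] <- vtab$variant_id[j]
      h2 <- cfg$per_mode_h2[k]
      e <- rnorm(n)
      if (h2 > 0) {
        b <- sample(c(-1, 1), length(j), replace = TRUE) *
          sqrt(h2 / length(j))
        zg <- scale(geno[, j, drop = FALSE])
        g <- as.numeric(zg %*% b)
        adj <- sqrt(h2) / sd(g)          # exact in-sample genetic share
        g <- g * adj
        true_betas[j, k] <- b * adj
        z[, k] <- g + e * sqrt(1 - h2) / sd(e)
      } else {
        z[, k] <- e / sd(e)
      }
    }
  }

  outlier_ids <- character(0)
  subject_ids <- sprintf("S%05d", seq_len(n))
  if (cfg$n_outliers > 0) {
    idx <- sample(n, cfg$n_outliers)
    z[idx, cfg$outlier_mode] <- cfg$outlier_sd *
      sample(c(-1, 1), cfg$n_outliers, replace = TRUE)
    outlier_ids <- subject_ids[idx]
  }

  amp <- cfg$mode_sds * sqrt(three_p)
  shapes <- tcrossprod(sweep(z, 2, amp, "*"), U)  # n x 3P displacements
  tvec <- mesh_to_vec(template)
  meshes <- vector("list", n)
  for (i in seq_len(n)) {
    x <- tvec + shapes[i, ] + rnorm(three_p, sd = cfg$noise_sd)
    pts <- vec_to_points(x)
    rot <- random_rotation()
    pts <- pts %*% t(rot)
    pts <- sweep(pts, 2, rnorm(3, sd = 10), "+")
    meshes[[i]] <- surface_mesh(pts, subject_ids[i], wall = template$wall)
  }

  truth <- structure(list(
    true_latent_scores = z, causal_variant_ids = causal_ids,
    true_betas = true_betas, true_h2 = cfg$per_mode_h2,
    injected_outlier_ids = outlier_ids, mode_fields = U,
    mode_sds = cfg$mode_sds, template = template,
    subject_ids = subject_ids), class = "truth_record")
  list(meshes = meshes, truth = truth)
}

#' Degrade a mesh to noisy contour points
#'
#' Emulates the sparse, jittered contour points a segmentation pipeline
#' yields: a random subset of mesh points with isotropic Gaussian jitter,
#' optionally with a fraction of points displaced by at least 20 mm to mimic
#' grossly erroneous contours.
#'
#' @param mesh a [surface_mesh].
#' @param keep_fraction fraction of mesh points kept, in `(0, 1]`.
#' @param jitter_sd isotropic jitter SD per axis, mm.
#' @param corrupt if `TRUE`, displace `corrupt_fraction` of the kept points
#'   by `corrupt_shift` mm along random directions.
#' @param corrupt_fraction,corrupt_shift corruption controls
#'   (`corrupt_shift` must be >= 20 mm).
#' @param seed optional seed for this draw (left `NULL`, the current RNG
#'   stream is used).
#' @return A `contour_set`: list with `points`, `source_point_id`,
#'   `subject_id`.
#' @export
degrade_to_contours <- function(mesh, keep_fraction = 1, jitter_sd = 0,
                                corrupt = FALSE, corrupt_fraction = 0.05,
                                corrupt_shift = 25, seed = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("`keep_fraction` must be in (0, 1]")
  if (corrupt && corrupt_shift < 20)
    stop("`corrupt_shift` must be at least 20 mm")
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(mesh$points)
  n_keep <- round(P * keep_fraction)
  if (n_keep < 1) stop("contour subset is empty")
  idx <- if (n_keep == P) seq_len(P) else sort(sample(P, n_keep))
  pts <- mesh$points[idx, , drop = FALSE]
  if (jitter_sd > 0)
    pts <- pts + matrix(rnorm(length(pts), sd = jitter_sd), nrow(pts), 3)
  if (corrupt) {
    nc <- max(1L, round(corrupt_fraction * n_keep))
    ci <- sample(n_keep, nc)
    dir <- matrix(rnorm(nc * 3), nc, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pts[ci, ] <- pts[ci, ] + dir * corrupt_shift
  }
  structure(list(points = pts, source_point_id = idx,
                 subject_id = mesh$subject_id), class = "contour_set")
}
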