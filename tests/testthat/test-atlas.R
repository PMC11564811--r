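# Rigid alignment, generalized Procrustes, PCA atlas and Z-scores.

test_that("rigid alignment handles identity, rigid motion and scale", {
  tpl <- make_template(60)
  # identity
  al <- rigid_align_pair(tpl, tpl)
  expect_lt(max(abs(al$points - tpl$points)), 1e-10)
  # pure rigid motion is undone
  set.seed(1)
  R <- rotation_about_axis(rnorm(3), 1.1)
  moved <- surface_mesh(sweep(tpl$points %*% t(R), 2, c(5, -3, 7), "+"), "m")
  back <- rigid_align_pair(moved, tpl)
  expect_lt(sqrt(mean((back$points - tpl$points)^2)), 1e-8)
  # scale is preserved, never removed
  scaled <- surface_mesh(tpl$points * 2, "s")
  al2 <- rigid_align_pair(scaled, tpl)
  size <- function(p) sqrt(sum(sweep(p, 2, colMeans(p))^2))
  expect_equal(size(al2$points), 2 * size(tpl$points), tolerance = 1e-10)
  # degenerate input
  flat <- surface_mesh(matrix(1, 4, 3), "d")
  expect_error(rigid_align_pair(flat, flat), "degenerate")
})

test_that("recovered rotation matches a grid-search oracle", {
  set.seed(42)
  pts <- matrix(rnorm(12, sd = 10), 4, 3)   # asymmetric 4-point set
  axis <- rnorm(3)
  truth_angle <- 37 * pi / 180
  rotated <- pts %*% t(rotation_about_axis(axis, truth_angle))
  ref <- surface_mesh(pts, "ref")
  al <- rigid_align_pair(surface_mesh(rotated, "rot"), ref)
  expect_lt(sqrt(mean((al$points - pts)^2)), 1e-8)
  # oracle: exhaustive search over rotation angle about the known axis at
  # 0.1 degree resolution must find ~37 degrees for the inverse rotation
  grid <- seq(0, 2 * pi, by = 0.1 * pi / 180)
  ssd <- vapply(grid, function(a) {
    sum((rotated %*% t(rotation_about_axis(axis, -a)) - pts)^2)
  }, numeric(1))
  best <- grid[which.min(ssd)]
  expect_lt(abs(best - truth_angle), 0.1 * pi / 180 + 1e-9)
  # and our alignment is at least as good as the best grid rotation
  expect_lte(sum((al$points - pts)^2), min(ssd) + 1e-9)
})

test_that("generalized Procrustes reaches its fixed point", {
  tpl <- make_template(40)
  # identical inputs: one iteration, consensus = mean = the shape
  copies <- lapply(1:4, function(i) surface_mesh(tpl$points, paste0("c", i)))
  g <- generalized_procrustes(copies)
  expect_equal(g$n_iterations, 1)
  ctr <- sweep(tpl$points, 2, colMeans(tpl$points))
  expect_lt(max(abs(g$consensus$points - ctr)), 1e-8)

  # one shape under random rigid transforms: all aligned shapes coincide
  set.seed(7)
  moved <- lapply(1:6, function(i) {
    R <- rotation_about_axis(rnorm(3), runif(1, 0, pi))
    surface_mesh(sweep(tpl$points %*% t(R), 2, rnorm(3, sd = 20), "+"),
                 paste0("m", i))
  })
  g2 <- generalized_procrustes(moved)
  ref <- g2$aligned[[1]]$points
  for (m in g2$aligned[-1])
    expect_lt(max(abs(m$points - ref)), 1e-6)

  # long-run oracle: consensus equals the 100-iteration fixed point
  set.seed(8)
  three <- lapply(1:3, function(i)
    surface_mesh(tpl$points + matrix(rnorm(120, sd = 2), 40, 3),
                 paste0("s", i)))
  g3 <- generalized_procrustes(three, tol = 1e-10)
  cons <- sweep(three[[1]]$points, 2, colMeans(three[[1]]$points))
  al <- three
  for (it in 1:100) {
    al <- lapply(al, rigid_align_pair,
                 reference = surface_mesh(cons, "c"))
    cons <- Reduce(`+`, lapply(al, `[[`, "points")) / 3
    cons <- sweep(cons, 2, colMeans(cons))
  }
  expect_lt(max(abs(g3$consensus$points - cons)), 1e-8)
})

test_that("atlas eigenstructure: rank, trace conservation, known shares", {
  tpl <- make_template(30)
  set.seed(3)
  two <- lapply(1:2, function(i)
    surface_mesh(tpl$points + matrix(rnorm(90), 30, 3), paste0("s", i)))
  a2 <- build_atlas(two)
  expect_equal(length(a2$eigenvalues), 1)
  expect_equal(a2$variance_fractions[1], 1)

  set.seed(4)
  many <- lapply(1:12, function(i)
    surface_mesh(tpl$points + matrix(rnorm(90, sd = 2), 30, 3),
                 paste0("s", i)))
  atl <- build_atlas(many)
  X <- t(sapply(many, function(m) as.numeric(t(m$points))))
  total <- sum(scale(X, scale = FALSE)^2) / (12 - 1)
  expect_equal(sum(atl$eigenvalues), total, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(atl$modes) - diag(ncol(atl$modes)))), 1e-8)

  # generator with known mode SDs: fractions match theory (averaged over
  # seeds; a single draw fluctuates by ~sqrt(2/n) relative per eigenvalue)
  est <- rowMeans(sapply(12:14, function(s) {
    cfg <- sim_config(n_subjects = 400, n_points = 100, n_latent_modes = 3,
                      mode_sds = c(8, 4, 2), noise_sd = 0.3,
                      per_mode_h2 = rep(0, 3), outcome_log_odds = NULL,
                      seed = s)
    build_test_atlas(cfg)$atlas$variance_fractions[1:3]
  }))
  theor <- c(64, 16, 4) / (84 + 0.3^2)
  expect_true(all(abs(est - theor) / theor < 0.10))
})

test_that("Z-scores standardize, decorrelate and round-trip", {
  cfg <- sim_config(n_subjects = 60, n_points = 40, n_latent_modes = 3,
                    mode_sds = c(6, 3, 1.5), noise_sd = 0.2,
                    per_mode_h2 = rep(0, 3), outcome_log_odds = NULL,
                    seed = 14)
  fit <- build_test_atlas(cfg)
  atl <- fit$atlas

  # mean shape scores to zero
  mean_mesh <- surface_mesh(matrix(atl$mean_shape, ncol = 3, byrow = TRUE),
                            "mean")
  z0 <- score_shapes(atl, list(mean_mesh), align = FALSE)
  expect_lt(max(abs(as.numeric(z0[, -1]))), 1e-8)

  # constructed shape two SDs along mode 1
  m2 <- reconstruct_shape(atl, c(2, 0, 0), 1:3)
  z2 <- score_shapes(atl, list(m2), align = FALSE, modes = 1:3)
  expect_equal(as.numeric(z2[, -1]), c(2, 0, 0), tolerance = 1e-8)

  # training set: unit variance per mode, zero cross-correlation
  sc <- score_shapes(atl, fit$gpa$aligned, align = FALSE)
  zm <- as.matrix(sc[, -1])
  expect_true(all(abs(apply(zm, 2, var) - 1) < 1e-6))
  cc <- cor(zm)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)

  # full-mode round trip reproduces each training shape
  k <- ncol(atl$modes)
  for (i in c(1, 30)) {
    zi <- as.numeric(score_shapes(atl, fit$gpa$aligned[i],
                                  align = FALSE)[, -1])
    rec <- reconstruct_shape(atl, zi, seq_len(k))
    expect_lt(max(abs(rec$points - fit$gpa$aligned[[i]]$points)), 1e-6)
  }

  # residual after 2 modes equals the QC projection residual
  mesh <- fit$gpa$aligned[[5]]
  zi <- as.numeric(score_shapes(atl, list(mesh), align = FALSE,
                                modes = 1:2)[, -1])
  rec <- reconstruct_shape(atl, zi, 1:2)
  manual <- sqrt(sum((rec$points - mesh$points)^2) / 40)
  expect_equal(projection_residual(atl, mesh, n_modes = 2, align = FALSE),
               manual, tolerance = 1e-10)
})

test_that("mode selection is strict and ordered", {
  atl <- structure(list(variance_fractions = c(0.5, 0.3, 0.15, 0.04, 0.009),
                        modes = matrix(0, 3, 5)), class = "shape_atlas")
  expect_equal(select_modes(atl, 0.01), 1:4)
  atl$variance_fractions[1] <- 0.01
  expect_false(1 %in% select_modes(atl, 0.01))
})

test_that("subgroup variance respects subspace structure", {
  cfg <- sim_config(n_subjects = 150, n_points = 60, n_latent_modes = 3,
                    mode_sds = c(6, 3, 1.5), noise_sd = 0.1,
                    per_mode_h2 = rep(0, 3), outcome_log_odds = NULL,
                    seed = 16)
  fit <- build_test_atlas(cfg)
  atl <- fit$atlas
  expect_equal(
    subgroup_variance_explained(atl, fit$gpa$aligned, align = FALSE),
    100, tolerance = 1e-6)
  # fresh draw from the same generative model (same mode fields): >= 95%
  cfg2 <- cfg; cfg2$seed <- 17L; cfg2$n_subjects <- 80L
  pop2 <- sample_shape_population(cfg2, make_template(60),
                                  mode_fields = fit$pop$truth$mode_fields)
  expect_gt(subgroup_variance_explained(atl, pop2$meshes, modes = 1:3), 95)

  # adding an orthogonal mode of known power drops the percentage by its
  # variance share
  extra_dir <- matrix(0, 180, 1)
  extra_dir[seq(1, 180, by = 3), 1] <- 1
  extra_dir <- extra_dir - atl$modes %*% crossprod(atl$modes, extra_dir)
  extra_dir <- extra_dir / sqrt(sum(extra_dir^2))
  amp <- 4 * sqrt(180)
  set.seed(18)
  zx <- rnorm(80)
  meshes3 <- lapply(seq_along(pop2$meshes), function(i) {
    v <- as.numeric(t(pop2$meshes[[i]]$points))
    # displacement applied in atlas frame: align first, then displace
    m <- rigid_align_pair(pop2$meshes[[i]],
                          surface_mesh(matrix(atl$mean_shape, ncol = 3,
                                              byrow = TRUE), "mean"))
    surface_mesh(m$points + matrix(extra_dir * amp * zx[i], ncol = 3,
                                   byrow = TRUE), paste0("x", i))
  })
  pct3 <- subgroup_variance_explained(atl, meshes3, modes = 1:3,
                                      align = FALSE)
  share <- (4^2) / (4^2 + sum(c(6, 3, 1.5)^2) + 0.1^2)
  pct2 <- subgroup_variance_explained(atl, pop2$meshes, modes = 1:3)
  expect_equal((pct2 - pct3) / 100, share, tolerance = 0.35)
})

test_that("atlas spectra and |z| are invariant to global rigid motion", {
  cfg <- sim_config(n_subjects = 50, n_points = 40, n_latent_modes = 2,
                    mode_sds = c(5, 2.5), noise_sd = 0.2,
                    per_mode_h2 = rep(0, 2), outcome_log_odds = NULL,
                    seed = 19)
  pop <- sample_shape_population(cfg, make_template(40))
  fit1 <- generalized_procrustes(pop$meshes)
  a1 <- build_atlas(fit1$aligned)
  set.seed(20)
  R <- rotation_about_axis(rnorm(3), 0.8)
  shift <- c(12, -7, 3)
  moved <- lapply(pop$meshes, function(m)
    surface_mesh(sweep(m$points %*% t(R), 2, shift, "+"), m$subject_id))
  fit2 <- generalized_procrustes(moved)
  a2 <- build_atlas(fit2$aligned)
  expect_true(all(abs(a1$eigenvalues - a2$eigenvalues) /
                    a1$eigenvalues[1] < 1e-6))
  z1 <- abs(as.matrix(score_shapes(a1, fit1$aligned, align = FALSE)[, -1]))
  z2 <- abs(as.matrix(score_shapes(a2, fit2$aligned, align = FALSE)[, -1]))
  expect_lt(max(abs(z1[, 1:2] - z2[, 1:2])), 1e-6)
})
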