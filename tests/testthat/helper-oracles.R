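# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (enumeration, grid search, hand-rolled IRLS) so they
# share no code path with the implementation they check.

# Exact HWE p-value by direct enumeration with choose(): probability of h
# heterozygotes conditional on allele counts, all configurations summed.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(na, nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    exp(h * log(2) + lfactorial(n) - lfactorial(h) -
          lfactorial((rare - h) / 2) - lfactorial(n - (rare + h) / 2) +
          lfactorial(na) + lfactorial(nA) - lfactorial(2 * n))
  })
  prob <- prob / sum(prob)           # guards rounding
  obs <- prob[hets == min(n_Aa, rare)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Hand-rolled IRLS for logistic regression (Newton steps on the canonical
# link), independent of stats::glm.
oracle_irls_logistic <- function(X, y, tol = 1e-10, max_iter = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(crossprod(X, X * w), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Greedy locus definition re-implemented naively (repeated full scans of a
# data.frame, no shared helpers).
oracle_loci <- function(results, variants, geno, gw_p = 5e-8,
                        window_bp = 5e5, signal_r2 = 0.1) {
  tab <- merge(results, variants, by = "variant_id")
  sig <- tab[tab$p < gw_p, ]
  sig <- sig[order(sig$p, sig$chr, sig$pos), ]
  loci <- list()
  while (nrow(sig) > 0) {
    lead <- sig[1, ]
    memb <- variants$variant_id[variants$chr == lead$chr &
                                  abs(variants$pos - lead$pos) <= window_bp]
    r2 <- sapply(memb, function(id) {
      if (id == lead$variant_id) return(1)
      suppressWarnings(cor(geno[, lead$variant_id], geno[, id])^2)
    })
    r2[is.na(r2)] <- 0
    loci[[length(loci) + 1]] <- list(lead = lead$variant_id,
                                     members = sort(memb),
                                     signal = sort(memb[r2 > signal_r2]))
    sig <- sig[!(sig$variant_id %in% memb), ]
  }
  loci
}

# Greedy LD clumping re-implemented naively.
oracle_clump <- function(inst, geno, r2_max = 0.001, window_bp = 1e7) {
  inst <- inst[order(inst$p_exposure), ]
  kept <- character(0)
  for (i in seq_len(nrow(inst))) {
    drop_it <- FALSE
    for (k in kept) {
      krow <- inst[inst$variant_id == k, ]
      if (krow$chr == inst$chr[i] &&
          abs(krow$pos - inst$pos[i]) <= window_bp &&
          cor(geno[, k], geno[, inst$variant_id[i]])^2 > r2_max)
        drop_it <- TRUE
    }
    if (!drop_it) kept <- c(kept, inst$variant_id[i])
  }
  sort(kept)
}

# Brute-force weighted median by scanning candidate values.
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = 0.5, rule = 2)$y
}

# Rotation by `angle` about unit `axis` (Rodrigues formula), for the
# grid-search alignment oracle.
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Kabsch rotation R with centered(A) %*% t(R) ~ centered(B).
kabsch_rotation <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Ac, Bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Apply a global 3x3 rotation to every point of a stacked 3P mode matrix
# (used to carry PCA modes from the consensus frame into the template
# frame before comparing subspaces).
rotate_mode_matrix <- function(V, R) {
  out <- V
  for (k in seq_len(ncol(V))) {
    pts <- matrix(V[, k], ncol = 3, byrow = TRUE)
    out[, k] <- as.numeric(t(pts %*% t(R)))
  }
  out
}

# Small helper: build an aligned, scored atlas from a config.
build_test_atlas <- function(cfg, template = make_template(cfg$n_points),
                             genotypes = NULL) {
  pop <- sample_shape_population(cfg, template, genotypes)
  gpa <- generalized_procrustes(pop$meshes)
  atlas <- build_atlas(gpa$aligned)
  list(pop = pop, gpa = gpa, atlas = atlas)
}
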