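# Plain-text I/O: mesh point tables, score tables, summary statistics,
# dosage tables and the atlas archive.

#' Write / read mesh point tables
#'
#' TSV with columns `subject_id`, `point_id`, `x_mm`, `y_mm`, `z_mm`; one
#' block of rows per subject.
#'
#' @param meshes list of [surface_mesh].
#' @param path file path.
#' @return `write_mesh_tsv` the path invisibly; `read_mesh_tsv` a list of
#'   [surface_mesh].
#' @export
write_mesh_tsv <- function(meshes, path) {
  tab <- data.table::rbindlist(lapply(meshes, function(m)
    data.table::data.table(subject_id = m$subject_id,
                           point_id = seq_len(nrow(m$points)),
                           x_mm = m$points[, 1], y_mm = m$points[, 2],
                           z_mm = m$points[, 3])))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_mesh_tsv
#' @export
read_mesh_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  ids <- unique(tab$subject_id)
  lapply(ids, function(id) {
    s <- tab[tab$subject_id == id, ]
    s <- s[order(s$point_id), ]
    surface_mesh(cbind(s$x_mm, s$y_mm, s$z_mm), id)
  })
}

#' Write / read GWAS summary statistics
#'
#' Uses the exact header `PC, SNP, CHR, POS, EA, NEA, EAF, BETA, SE, P`.
#' `read_sumstats` returns the internal column naming (`variant_id`,
#' `chr`, `pos`, ...).
#'
#' @param results scan results ([association_scan] output).
#' @param variants variant table supplying CHR/POS/EA/NEA/EAF.
#' @param path file path.
#' @export
write_sumstats <- function(results, variants, path) {
  i <- match(results$variant_id, variants$variant_id)
  tab <- data.frame(PC = results$pc, SNP = results$variant_id,
                    CHR = variants$chr[i], POS = variants$pos[i],
                    EA = variants$EA[i], NEA = variants$NEA[i],
                    EAF = variants$EAF[i], BETA = results$beta,
                    SE = results$se, P = results$p)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  data.frame(pc = tab$PC, variant_id = tab$SNP, chr = tab$CHR,
             pos = tab$POS, EA = tab$EA, NEA = tab$NEA, EAF = tab$EAF,
             BETA = tab$BETA, SE = tab$SE, P = tab$P,
             stringsAsFactors = FALSE)
}

#' Write / read dosage tables
#'
#' Variants-in-rows TSV: first column `variant_id`, one column per subject.
#'
#' @param geno subjects x variants dosage matrix (dimnames required).
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  tab <- data.table::data.table(variant_id = colnames(geno), t(geno))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  ids <- tab$variant_id
  g <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(g) <- ids
  g
}

#' Serialize / restore a shape atlas
#'
#' Single JSON archive holding the mean shape, modes, eigenvalues and
#' metadata at full double precision.
#'
#' @param atlas a `shape_atlas`.
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "shape_atlas"))
  obj <- list(mean_shape = atlas$mean_shape,
              modes = as.numeric(atlas$modes),
              n_modes = ncol(atlas$modes),
              eigenvalues = atlas$eigenvalues,
              n_train = atlas$n_train, n_points = atlas$n_points)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  modes <- matrix(obj$modes, ncol = obj$n_modes)
  structure(list(mean_shape = obj$mean_shape, modes = modes,
                 eigenvalues = obj$eigenvalues,
                 variance_fractions = obj$eigenvalues / sum(obj$eigenvalues),
                 n_train = obj$n_train, n_points = obj$n_points),
            class = "shape_atlas")
}
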