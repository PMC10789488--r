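#' Scalar map on a voxel grid
#'
#' A 3D scalar field with an optional gray-matter mask. Out-of-mask voxels
#' carry `NA`; in-mask values must be finite.
#'
#' @param values Numeric 3D array (or vector reshaped by `grid_shape`).
#' @param mask Logical array of the same shape; default all `TRUE`.
#' @param grid_shape Integer length-3 vector, required when `values` is a
#'   plain vector.
#' @return An object of class `scalar_map`: list with `values` (NA outside
#'   the mask) and `mask`.
#' @export
scalar_map <- function(values, mask = NULL, grid_shape = NULL) {
  if (is.null(dim(values))) {
    stopifnot(!is.null(grid_shape), length(grid_shape) == 3L)
    values <- array(values, dim = grid_shape)
  }
  stopifnot(length(dim(values)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat("scalar_map:", paste(dim(x$values), collapse = " x "),
      "grid,", sum(x$mask), "in-mask voxels\n")
  invisible(x)
}

#' Atlas parcellation
#'
#' Integer label volume plus a region-label table. Labels must be contiguous
#' 1..R with 0 = background, and every nonzero label present in the table.
#'
#' @param labels Integer 3D array of region labels.
#' @param region_table Data frame with columns `region` (1..R) and `name`.
#' @return An object of class `atlas`.
#' @export
atlas <- function(labels, region_table = NULL) {
  stopifnot(length(dim(labels)) == 3L, all(labels >= 0), all(labels == round(labels)))
  present <- sort(unique(as.integer(labels[labels > 0])))
  r_max <- if (length(present)) max(present) else 0L
  if (!identical(present, seq_len(r_max)))
    stop("atlas: labels must be contiguous 1..R")
  if (is.null(region_table))
    region_table <- data.frame(region = seq_len(r_max),
                               name = sprintf("region_%03d", seq_len(r_max)))
  stopifnot(all(present %in% region_table$region))
  structure(list(labels = labels, region_table = region_table,
                 n_regions = r_max), class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("atlas:", x$n_regions, "regions on a",
      paste(dim(x$labels), collapse = " x "), "grid\n")
  invisible(x)
}

#' Restrict a map to a gray-matter mask
#'
#' In-mask values pass through unchanged; out-of-mask voxels become `NA`.
#'
#' @param map A `scalar_map` (or bare 3D array).
#' @param mask Logical array of matching shape.
#' @return A `scalar_map`.
#' @export
apply_gm_mask <- function(map, mask) {
  vals <- if (inherits(map, "scalar_map")) map$values else map
  if (!identical(dim(vals), dim(mask))) stop("apply_gm_mask: shape mismatch")
  scalar_map(vals, mask = mask & (if (inherits(map, "scalar_map")) map$mask else TRUE))
}

# Dummy-coded design matrix for confound regression and GLMs. Categorical
# covariates get one indicator per non-reference level; reference level is
# the lexicographically first. Non-intercept columns are mean-centered when
# center = TRUE so the intercept is the grand mean.
build_design <- function(subject_table, covariate_names, center = FALSE) {
  n <- nrow(subject_table)
  cols <- list(intercept = rep(1, n))
  for (cv in covariate_names) {
    v <- subject_table[[cv]]
    if (is.null(v)) stop("build_design: no column '", cv, "' in subject table")
    if (is.numeric(v)) {
      cols[[cv]] <- v
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1]) cols[[paste0(cv, "_", l)]] <- as.numeric(as.character(v) == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (center && ncol(X) > 1L)
    X[, -1] <- sweep(X[, -1, drop = FALSE], 2, colMeans(X[, -1, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    stop("build_design: rank-deficient design; collinear columns: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  X
}

# Convert a list of scalar_maps (shared mask) to subjects x in-mask-voxel matrix.
maps_to_matrix <- function(maps) {
  mask <- maps[[1]]$mask
  t(vapply(maps, function(m) {
    stopifnot(identical(dim(m$values), dim(mask)))
    m$values[mask]
  }, numeric(sum(mask))))
}

matrix_to_maps <- function(mat, mask) {
  lapply(seq_len(nrow(mat)), function(i) {
    v <- array(NA_real_, dim = dim(mask))
    v[mask] <- mat[i, ]
    scalar_map(v, mask = mask)
  })
}

#' Regress confounds out of a set of subject images
#'
#' Per voxel, ordinary least squares of value on intercept + covariates
#' (categoricals dummy-coded). Covariate columns are centered so the fitted
#' intercept is the voxel's grand mean, which is added back to the residuals:
#' the output preserves the grand mean and the operation is idempotent.
#'
#' @param maps List of `scalar_map`, one per subject, sharing a mask.
#' @param subject_table Data frame with one row per subject.
#' @param covariate_names Character vector of column names (e.g.
#'   `c("age", "sex", "site")`; add `"tiv"` for volumetric maps).
#' @return List of confound-cleaned `scalar_map`s.
#' @export
regress_confounds_images <- function(maps, subject_table, covariate_names) {
  stopifnot(length(maps) == nrow(subject_table))
  X <- build_design(subject_table, covariate_names, center = TRUE)
  Y <- maps_to_matrix(maps)
  fit <- stats::lm.fit(X, Y)
  res <- fit$residuals + rep(colMeans(Y), each = nrow(Y))
  matrix_to_maps(res, maps[[1]]$mask)
}

#' Regional means under an atlas
#'
#' Arithmetic mean of in-mask, non-missing voxels per region. Regions with no
#' eligible voxel are flagged `NA` (missing), never zero-filled.
#'
#' @param map A `scalar_map`.
#' @param atlas An `atlas` on the same grid.
#' @return Named numeric vector, one entry per atlas region (names = region
#'   ids); `NA` marks missing regions.
#' @export
extract_regional_means <- function(map, atlas) {
  if (!identical(dim(map$values), dim(atlas$labels)))
    stop("extract_regional_means: grid mismatch")
  lab <- as.integer(atlas$labels)
  val <- as.numeric(map$values)
  keep <- lab > 0L & !is.na(val)
  out <- rep(NA_real_, atlas$n_regions)
  if (any(keep)) {
    sums <- rowsum(val[keep], lab[keep])
    cnts <- rowsum(rep(1, sum(keep)), lab[keep])
    out[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  }
  names(out) <- as.character(seq_len(atlas$n_regions))
  out
}

#' Regional means for a whole cohort
#'
#' @param maps List of `scalar_map`, one per subject.
#' @param atlas An `atlas`.
#' @return Subjects x regions matrix of regional means (`NA` = missing).
#' @export
extract_regional_means_cohort <- function(maps, atlas) {
  t(vapply(maps, extract_regional_means, numeric(atlas$n_regions), atlas = atlas))
}

#' First eigenvariate of a cluster
#'
#' First singular component of the column-centered subject x cluster-voxel
#' matrix, scaled to unit variance, with the sign fixed so the score
#' correlates nonnegatively with the cluster-mean signal.
#'
#' @param maps List of `scalar_map`, one per subject (>= 2).
#' @param cluster_mask Logical array selecting the cluster voxels (nonempty).
#' @return Numeric vector of one score per subject.
#' @export
extract_eigenvariate <- function(maps, cluster_mask) {
  if (!any(cluster_mask)) stop("extract_eigenvariate: empty cluster")
  stopifnot(length(maps) >= 2L)
  M <- t(vapply(maps, function(m) m$values[cluster_mask], numeric(sum(cluster_mask))))
  Mc <- sweep(M, 2, colMeans(M))
  sv <- svd(Mc, nu = 1, nv = 0)
  scores <- sv$u[, 1] * sv$d[1]
  s <- stats::sd(scores)
  if (s > 0) scores <- scores / s
  cm <- rowMeans(M)
  if (stats::sd(cm) > 0 && stats::cor(scores, cm) < 0) scores <- -scores
  scores
}
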