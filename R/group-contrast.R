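#' Voxel-wise group GLM t-map
#'
#' Per voxel, OLS of the map value on group + covariates (dummy-coded); the
#' t statistic is the group-contrast estimate over its standard error with
#' the pooled residual variance at that voxel. Residual df = n - rank(design).
#'
#' @param maps List of `scalar_map`, one per subject.
#' @param subject_table Data frame with a `group` column (two levels) and any
#'   covariate columns.
#' @param covariates Character vector of covariate column names (may be empty).
#' @param contrast `"group1-group2"` direction: `"control-patient"` tests
#'   control > patient, `"patient-control"` the reverse.
#' @return List of class `tmap`: `t` (3D array, NA outside mask), `df`,
#'   `mask`, `contrast`.
#' @export
fit_voxelwise_glm <- function(maps, subject_table, covariates = character(),
                              contrast = c("control-patient", "patient-control")) {
  contrast <- match.arg(contrast)
  stopifnot(length(maps) == nrow(subject_table))
  grp <- as.character(subject_table$group)
  if (!all(grp %in% c("patient", "control")) || length(unique(grp)) != 2L)
    stop("fit_voxelwise_glm: group must contain both 'patient' and 'control'")
  Y <- maps_to_matrix(maps)
  tb <- subject_table
  tb$.grp <- as.numeric(grp == "control")  # indicator: 1 = control
  X <- build_design(tb, c(".grp", covariates))
  fit <- glm_tmap_matrix(X, Y, which_col = match(".grp", colnames(X)))
  sgn <- if (contrast == "control-patient") 1 else -1
  mask <- maps[[1]]$mask
  tarr <- array(NA_real_, dim = dim(mask))
  tarr[mask] <- sgn * fit$t
  structure(list(t = tarr, df = fit$df, mask = mask, contrast = contrast),
            class = "tmap")
}

# Vectorized per-voxel t for one design column: X n x p (full rank), Y n x v.
glm_tmap_matrix <- function(X, Y, which_col) {
  n <- nrow(X); p <- ncol(X)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, Y)           # p x v
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtX_inv[which_col, which_col])
  tv <- B[which_col, ] / se
  # voxels whose residual variance is numerically zero (relative to the data
  # scale) carry no evidence: t = 0, not floating-point noise
  zero <- sigma2 <= 1e-20 * pmax(colSums(Y^2) / n, .Machine$double.xmin)
  tv[zero | se == 0] <- 0
  list(t = tv, df = df)
}

# 3D connected components among the TRUE voxels of a logical array.
# connectivity: 6 (faces), 18 (faces+edges, default), 26 (+corners).
# Returns a list of integer matrices of voxel coordinates, one per cluster.
connected_components <- function(supra, connectivity = 18L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  dims <- dim(supra)
  idx <- which(supra)
  if (!length(idx)) return(list())
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(off))
  off <- off[dist > 0 & dist <= switch(as.character(connectivity),
                                       "6" = 1L, "18" = 2L, "26" = 3L), , drop = FALSE]
  coords <- arrayInd(idx, dims)
  in_set <- new.env(hash = TRUE, size = length(idx))
  for (k in seq_along(idx)) assign(as.character(idx[k]), k, envir = in_set)
  visited <- logical(length(idx))
  comps <- list()
  for (start in seq_along(idx)) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE; members <- integer()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      members <- c(members, cur)
      cc <- coords[cur, ]
      nb <- sweep(off, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
      for (l in lin) {
        key <- as.character(l)
        j <- if (exists(key, envir = in_set, inherits = FALSE))
          get(key, envir = in_set, inherits = FALSE) else NA_integer_
        if (!is.na(j) && !visited[j]) { visited[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    comps[[length(comps) + 1L]] <- coords[members, , drop = FALSE]
  }
  comps
}

#' Permutation-based cluster-level inference for a group contrast
#'
#' The observed t-map is thresholded at the one-sided voxel-level critical t
#' for `voxel_p` (Student df = n - rank), connected components are found, and
#' the null distribution of the maximum cluster size is built by recomputing
#' the thresholded map under random group-label permutations with covariate
#' rows kept attached to their subjects. Cluster-level
#' p = (1 + #\{permutation max size >= observed size\}) / (1 + n_perm).
#'
#' @inheritParams fit_voxelwise_glm
#' @param n_perm Number of label permutations (>= 100; study default 1000).
#' @param voxel_p Uncorrected voxel threshold (default 0.001).
#' @param cluster_p Cluster-level significance threshold (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @param connectivity 6, 18 (default) or 26 neighborhood.
#' @param all_clusters Return every supra-threshold cluster, not only those
#'   with p < `cluster_p`.
#' @return List of class `cluster_table`: data frame `clusters` (size,
#'   peak coordinates, peak t, cluster p), the observed `tmap`, the critical
#'   t, and the null maximum-size draws.
#' @export
permutation_cluster_inference <- function(maps, subject_table,
                                          covariates = character(),
                                          contrast = c("control-patient", "patient-control"),
                                          n_perm = 1000L, voxel_p = 0.001,
                                          cluster_p = 0.05, seed = 1L,
                                          connectivity = 18L,
                                          all_clusters = FALSE) {
  contrast <- match.arg(contrast)
  stopifnot(n_perm >= 100L, voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  grp <- as.character(subject_table$group)
  obs <- fit_voxelwise_glm(maps, subject_table, covariates, contrast)
  t_crit <- stats::qt(1 - voxel_p, df = obs$df)
  if (!any(obs$mask)) {
    warning("permutation_cluster_inference: no in-mask voxels")
    return(structure(list(clusters = empty_cluster_table(), tmap = obs,
                          t_crit = t_crit, null_max_sizes = integer()),
                     class = "cluster_table"))
  }
  comps <- connected_components(!is.na(obs$t) & obs$t >= t_crit, connectivity)
  # permutation null of the maximum cluster size
  Y <- maps_to_matrix(maps)
  sgn <- if (contrast == "control-patient") 1 else -1
  tb <- subject_table
  null_max <- integer(n_perm)
  dims <- dim(obs$mask)
  mask_idx <- which(obs$mask)
  # draw label permutations against a canonical subject order (by id when
  # present), so reordering subject rows leaves the whole result identical
  ord <- if (!is.null(subject_table$id)) order(subject_table$id)
         else seq_along(grp)
  grp_canon <- grp[ord]
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    tb$group[ord] <- sample(grp_canon)
    tbp <- tb
    tbp$.grp <- as.numeric(tbp$group == "control")
    X <- build_design(tbp, c(".grp", covariates))
    tv <- sgn * glm_tmap_matrix(X, Y, match(".grp", colnames(X)))$t
    supra <- array(FALSE, dim = dims)
    supra[mask_idx[tv >= t_crit]] <- TRUE
    cs <- connected_components(supra, connectivity)
    null_max[b] <- if (length(cs)) max(vapply(cs, nrow, integer(1))) else 0L
  }
  rows <- lapply(comps, function(cc) {
    tvals <- obs$t[cc]
    pk <- cc[which.max(tvals), ]
    size <- nrow(cc)
    data.frame(size = size, peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
               peak_t = max(tvals),
               p = (1 + sum(null_max >= size)) / (1 + n_perm))
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else empty_cluster_table()
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  rownames(clusters) <- NULL
  if (!all_clusters) clusters <- clusters[clusters$p < cluster_p, , drop = FALSE]
  structure(list(clusters = clusters, tmap = obs, t_crit = t_crit,
                 null_max_sizes = null_max, comps = comps),
            class = "cluster_table")
}

empty_cluster_table <- function() {
  data.frame(size = integer(), peak_x = integer(), peak_y = integer(),
             peak_z = integer(), peak_t = numeric(), p = numeric())
}

#' Voxel mask of the largest supra-threshold cluster
#'
#' @param ct A `cluster_table` from [permutation_cluster_inference()].
#' @return Logical array marking the largest cluster's voxels, or `NULL` when
#'   no cluster was found.
#' @export
largest_cluster_mask <- function(ct) {
  if (!length(ct$comps)) return(NULL)
  sizes <- vapply(ct$comps, nrow, integer(1))
  cc <- ct$comps[[which.max(sizes)]]
  m <- array(FALSE, dim = dim(ct$tmap$mask))
  m[cc] <- TRUE
  m
}
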