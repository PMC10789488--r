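#' @export
print.coloc_test <- function(x, ...) {
  cat("Co-localization permutation test (", x$n_perm, " permutations, ",
      nrow(x$profiles), " patients)\n", sep = "")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("Permutation cluster inference: critical t =", signif(x$t_crit, 4),
      "(df =", x$tmap$df, ")\n")
  if (nrow(x$clusters)) print(x$clusters, digits = 3, row.names = FALSE)
  else cat("no clusters at the requested threshold\n")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (seed ", x$config$seed, ")\n", sep = "")
  cat("- subjects: ", nrow(x$subjects), " (",
      sum(x$subjects$group == "patient"), " patients)\n", sep = "")
  cat("- fALFF co-localization:\n")
  print(x$coloc_falff$table, digits = 3, row.names = FALSE)
  cat("- variance explained by GMV:",
      signif(x$variance_explained$fraction, 3), "\n")
  cat("- site homogeneity p:", signif(x$site_test$p, 3), "\n")
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", x$n_patients, "patients /", x$n_controls,
      "controls,", x$n_regions, "regions,", x$n_templates, "templates,",
      "beta =", x$effect_size_beta, "\n")
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config: n_perm_cluster =", x$n_perm_cluster,
      ", n_perm_coloc =", x$n_perm_coloc, ", voxel_p =", x$voxel_p,
      ", cluster_p =", x$cluster_p, ", fdr_q =", x$fdr_q, "\n")
  print(x$synthetic)
  invisible(x)
}
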