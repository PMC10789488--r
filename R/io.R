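#' Write / read a scalar map as NIfTI
#'
#' Out-of-mask voxels are stored as `NaN`; reading restores the mask from
#' finiteness.
#'
#' @param map A `scalar_map` (or for the atlas variant an `atlas`).
#' @param path Output file (`.nii` / `.nii.gz`).
#' @return `path`, invisibly (writers); the object (readers).
#' @export
write_scalar_map_nifti <- function(map, path) {
  v <- map$values
  v[!map$mask] <- NaN
  RNifti::writeNifti(RNifti::asNifti(v), path)
  invisible(path)
}

#' @rdname write_scalar_map_nifti
#' @export
read_scalar_map_nifti <- function(path) {
  v <- array(as.numeric(RNifti::readNifti(path)), dim = dim(RNifti::readNifti(path)))
  scalar_map(v, mask = is.finite(v))
}

#' @rdname write_scalar_map_nifti
#' @param atl An `atlas`.
#' @export
write_atlas_nifti <- function(atl, path) {
  RNifti::writeNifti(RNifti::asNifti(atl$labels), path)
  invisible(path)
}

#' @rdname write_scalar_map_nifti
#' @param region_table Optional region table to attach on read.
#' @export
read_atlas_nifti <- function(path, region_table = NULL) {
  v <- RNifti::readNifti(path)
  atlas(array(as.integer(round(v)), dim = dim(v)), region_table)
}

#' Write a data frame as TSV (UTF-8, header row, no quoting)
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
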