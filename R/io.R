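# File interchange: volumes as NIfTI (RNifti), gradient tables as FSL-style
# bval/bvec text, per-vertex maps and tables as CSV.

#' Read and write scalar or vector volumes as NIfTI
#'
#' Vector fields (4D arrays with a trailing component dimension) round-trip
#' as multi-volume NIfTI.
#'
#' @param volume 3D or 4D numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm voxel edge lengths, written into the header.
#' @return the path (writer, invisibly) or the array (reader), with
#'   `voxel_size_mm` attribute.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, length(dim(volume)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  arr
}

#' Write / read an unfolded map as CSV
#'
#' Columns: `vertex`, `row`, `col`, `value` (vertices in column-major grid
#' order).
#'
#' @param map an [unfolded_map()].
#' @param path CSV path.
#' @return the path (writer, invisibly) / an `unfolded_map` (reader).
#' @export
write_unfolded_csv <- function(map, path) {
  gs <- map$grid_shape
  df <- data.frame(vertex = seq_along(map$values),
                   row = rep(seq_len(gs[1]), gs[2]),
                   col = rep(seq_len(gs[2]), each = gs[1]),
                   value = map$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param metric metric name for the reconstructed map.
#' @rdname write_unfolded_csv
#' @export
read_unfolded_csv <- function(path, metric = "metric") {
  df <- utils::read.csv(path)
  unfolded_map(df$value[order(df$vertex)],
               c(max(df$row), max(df$col)), metric = metric)
}

#' Write a hippocampal surface as a set of CSV tables
#'
#' Writes `<prefix>_vertices.csv` (sheet coordinates, unfolded coordinates,
#' thickness, subfield label) and `<prefix>_triangles.csv`.
#'
#' @param surface a `hippocampal_surface`.
#' @param prefix path prefix.
#' @return the prefix, invisibly.
#' @export
write_surface_csv <- function(surface, prefix) {
  v <- data.frame(surface$unfolded,
                  inner_x = surface$vertices_inner[, 1],
                  inner_y = surface$vertices_inner[, 2],
                  inner_z = surface$vertices_inner[, 3],
                  mid_x = surface$vertices_mid[, 1],
                  mid_y = surface$vertices_mid[, 2],
                  mid_z = surface$vertices_mid[, 3],
                  outer_x = surface$vertices_outer[, 1],
                  outer_y = surface$vertices_outer[, 2],
                  outer_z = surface$vertices_outer[, 3],
                  thickness_mm = surface$thickness_mm,
                  subfield = as.character(surface$subfield))
  utils::write.csv(v, paste0(prefix, "_vertices.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(surface$triangles),
                   paste0(prefix, "_triangles.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Write a correlation report as CSV
#'
#' Writes the tidy pair table and a square rho matrix mirroring the
#' lower-triangle-rho / upper-triangle-q heatmap layout.
#'
#' @param report a [all_pairs_report()] result.
#' @param prefix path prefix; writes `<prefix>_pairs.csv` and
#'   `<prefix>_matrix.csv`.
#' @return the prefix, invisibly.
#' @export
write_correlation_csv <- function(report, prefix) {
  utils::write.csv(report$pairs, paste0(prefix, "_pairs.csv"), row.names = FALSE)
  m <- report$rho_matrix
  m[upper.tri(m)] <- report$q_matrix[upper.tri(m)]
  utils::write.csv(m, paste0(prefix, "_matrix.csv"))
  invisible(prefix)
}
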