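#' Cosine similarity between two orientation vectors
#'
#' Absolute normalized inner product
#' \eqn{|\bar a \cdot \bar u| / (|\bar a||\bar u|)}, in \[0, 1\]: 0 for
#' vectors at 90 degrees, 1 for parallel (or antiparallel — orientations are
#' axial, so `u` and `-u` are equivalent).
#'
#' @param a,u non-zero 3-vectors (any scale; normalized internally).
#' @return scalar similarity in \[0, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0, 0), c(0, 1, 0))  # 0
#' cosine_similarity(c(1, 0, 0), c(-2, 0, 0)) # 1
cosine_similarity <- function(a, u) {
  if (length(a) != 3 || length(u) != 3) stop("vectors must have length 3")
  na <- sqrt(sum(a^2)); nu <- sqrt(sum(u^2))
  if (na == 0 || nu == 0 || !is.finite(na) || !is.finite(nu)) {
    stop("cosine similarity undefined for zero or non-finite vectors")
  }
  min(abs(sum(a * u)) / (na * nu), 1)
}

#' Per-voxel cosine similarities between NODDI orientation and axis fields
#'
#' Computes three scalar volumes `cs_AP`, `cs_PD`, `cs_IO`: at each voxel,
#' the cosine similarity between the NODDI microstructural vector \eqn{\mu}
#' and the unit gradient field of each hippocampal axis. Voxels that are
#' invalid in either input (failed NODDI fit, flat Laplace gradient) are
#' propagated as invalid, never zero-filled.
#'
#' @param mu_field 4D array (dims x 3) of per-voxel orientations, NA where
#'   unavailable.
#' @param axes an [gradient_fields()] `axis_fields` object on the same grid.
#' @param mu_valid optional logical array marking fitted voxels; defaults to
#'   voxels whose `mu_field` entries are finite and non-zero.
#' @return a `cosine_maps`: arrays `cs_AP`, `cs_PD`, `cs_IO` in \[0, 1\]
#'   (NA where invalid) and a logical `valid` array per axis.
#' @export
similarity_volumes <- function(mu_field, axes, mu_valid = NULL) {
  stopifnot(inherits(axes, "axis_fields"))
  dims <- dim(axes$G_AP)[1:3]
  if (!identical(dim(mu_field), c(dims, 3L)) &&
      !identical(dim(mu_field), as.integer(c(dims, 3)))) {
    stop("`mu_field` grid does not match the axis fields")
  }
  nrm <- sqrt(mu_field[, , , 1]^2 + mu_field[, , , 2]^2 + mu_field[, , , 3]^2)
  if (is.null(mu_valid)) mu_valid <- is.finite(nrm) & nrm > 0
  out <- list()
  for (ax in c("AP", "PD", "IO")) {
    G <- axes[[paste0("G_", ax)]]
    valid <- mu_valid & axes[[paste0("valid_", ax)]]
    dot <- mu_field[, , , 1] * G[, , , 1] + mu_field[, , , 2] * G[, , , 2] +
      mu_field[, , , 3] * G[, , , 3]
    cs <- abs(dot) / nrm                  # G is already unit-norm
    cs <- pmin(cs, 1)
    cs[!valid] <- NA_real_
    out[[paste0("cs_", ax)]] <- cs
    out[[paste0("valid_", ax)]] <- valid
  }
  class(out) <- "cosine_maps"
  out
}
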