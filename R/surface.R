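SUBFIELDS <- c("Sub", "CA1", "CA2", "CA3", "DG/CA4")

#' Per-vertex map in unfolded coordinates
#'
#' Light container for a scalar map on the unfolded rows x cols vertex grid.
#' Vertices are ordered column-major: `index = (col - 1) * rows + row`.
#' Missing vertices are NA.
#'
#' @param values numeric vector, one value per vertex.
#' @param grid_shape integer pair (rows, cols); `prod(grid_shape)` must equal
#'   `length(values)`.
#' @param metric,subject,hemisphere optional identifying metadata.
#' @return an `unfolded_map`.
#' @export
unfolded_map <- function(values, grid_shape, metric = "metric",
                         subject = NA_character_, hemisphere = NA_character_) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || prod(grid_shape) != length(values)) {
    stop("`values` length must equal prod(grid_shape)")
  }
  structure(list(values = as.numeric(values), grid_shape = grid_shape,
                 metric = metric, subject = subject, hemisphere = hemisphere),
            class = "unfolded_map")
}

#' @export
print.unfolded_map <- function(x, ...) {
  cat(sprintf("Unfolded map '%s' (%d x %d), %d missing vertices\n", x$metric,
              x$grid_shape[1], x$grid_shape[2], sum(is.na(x$values))))
  invisible(x)
}

map_values <- function(m) if (inherits(m, "unfolded_map")) m$values else as.numeric(m)

#' Synthetic flat hippocampal surface
#'
#' Builds a planar inner/mid/outer surface triple over a rows x cols
#' unfolded grid, embedded in world (mm) space: the AP axis runs along x
#' (rows), PD along y (columns) and IO along z. Subfield labels partition
#' the PD extent into five bands ordered proximal to distal (Sub, CA1, CA2,
#' CA3, DG/CA4). This is the synthetic stand-in for a real unfolded
#' hippocampal midthickness surface; it shares its vertex grid, laminar
#' structure and labelling but none of the real folded geometry.
#'
#' @param grid_shape integer pair (rows, cols) of vertices.
#' @param spacing_mm vertex spacing (mm) along AP and PD.
#' @param origin_mm world position of vertex (1, 1) on the midthickness sheet.
#' @param thickness_mm laminar thickness: scalar or per-vertex vector.
#' @return a `hippocampal_surface`: `vertices_inner`, `vertices_mid`,
#'   `vertices_outer` (V x 3 mm), `triangles`, `unfolded` (V x 2 row/col),
#'   `grid_shape`, `thickness_mm`, `subfield` (factor).
#' @export
make_flat_surface <- function(grid_shape, spacing_mm = c(1, 1),
                              origin_mm = c(1, 1, 3), thickness_mm = 2) {
  grid_shape <- as.integer(grid_shape)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  rc <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  v <- nrow(rc)
  mid <- cbind(origin_mm[1] + (rc$row - 1) * spacing_mm[1],
               origin_mm[2] + (rc$col - 1) * spacing_mm[2],
               rep(origin_mm[3], v))
  thickness_mm <- rep_len(thickness_mm, v)
  if (any(thickness_mm < 0)) stop("thickness must be >= 0")
  off <- cbind(0, 0, thickness_mm / 2)
  tri <- .grid_triangles(rows, cols)
  band <- cut(rc$col, breaks = 5, labels = SUBFIELDS)
  structure(list(vertices_inner = mid - off, vertices_mid = mid,
                 vertices_outer = mid + off, triangles = tri,
                 unfolded = as.matrix(rc), grid_shape = grid_shape,
                 thickness_mm = thickness_mm,
                 subfield = factor(band, levels = SUBFIELDS)),
            class = "hippocampal_surface")
}

.grid_triangles <- function(rows, cols) {
  idx <- function(r, c) (c - 1L) * rows + r
  r <- rep(seq_len(rows - 1L), cols - 1L)
  c <- rep(seq_len(cols - 1L), each = rows - 1L)
  rbind(cbind(idx(r, c), idx(r + 1L, c), idx(r, c + 1L)),
        cbind(idx(r + 1L, c), idx(r + 1L, c + 1L), idx(r, c + 1L)))
}

#' @export
print.hippocampal_surface <- function(x, ...) {
  cat(sprintf("Hippocampal surface: %d vertices (%d x %d grid), %d triangles\n",
              nrow(x$vertices_mid), x$grid_shape[1], x$grid_shape[2],
              nrow(x$triangles)))
  invisible(x)
}

#' Ribbon-constrained sampling of a volume onto the midthickness surface
#'
#' Samples a scalar volume at each surface vertex using a supersampled
#' point-in-prism estimate of the inner-outer ribbon: points are spread
#' through the local laminar prism (a tangential patch around the vertex
#' swept from the inner to the outer sheet) and each point's voxel
#' contributes a weight equal to its hit count times a Gaussian in the
#' distance from the midthickness sheet, with standard deviation
#' `sigma_scale * thickness` at that vertex — so voxels away from
#' midthickness are down-weighted more aggressively where the sheet is
#' thin. Weights are renormalized per vertex; vertices whose ribbon misses
#' the volume entirely come back as missing (NA).
#'
#' @param volume 3D numeric array; voxel (i, j, k) is the cube with centre
#'   `((i, j, k) - 0.5) * voxel_size_mm`. NA voxels are excluded.
#' @param surface a [make_flat_surface()]-style `hippocampal_surface` in the
#'   same physical space.
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param n_io number of sampling levels through the lamina (inner to outer).
#' @param n_tan tangential supersampling factor (n_tan x n_tan points).
#' @param sigma_scale Gaussian width as a fraction of local thickness
#'   (default 0.5: sigma = thickness / 2).
#' @param metric,subject,hemisphere metadata for the returned map.
#' @return an [unfolded_map()].
#' @export
sample_to_midthickness <- function(volume, surface, voxel_size_mm = c(1, 1, 1),
                                   n_io = 6, n_tan = 3, sigma_scale = 0.5,
                                   metric = "metric", subject = NA_character_,
                                   hemisphere = NA_character_) {
  stopifnot(inherits(surface, "hippocampal_surface"))
  if (length(dim(volume)) != 3) stop("`volume` must be a 3D array")
  dims <- dim(volume)
  V <- nrow(surface$vertices_mid)
  rows <- surface$grid_shape[1]; cols <- surface$grid_shape[2]

  # tangent steps on the midthickness sheet (central differences on the grid)
  mid <- surface$vertices_mid
  er <- .grid_tangent(mid, rows, cols, along = "row")
  ec <- .grid_tangent(mid, rows, cols, along = "col")

  toff <- if (n_tan > 1) seq(-0.5, 0.5, length.out = n_tan + 2)[-c(1, n_tan + 2)] else 0
  tio <- (seq_len(n_io) - 0.5) / n_io     # ribbon depth fractions (0 inner, 1 outer)

  acc <- numeric(V); wsum <- numeric(V)
  span <- surface$vertices_outer - surface$vertices_inner
  for (or in toff) for (oc in toff) {
    base <- surface$vertices_inner + or * er + oc * ec
    sp <- span
    for (t in tio) {
      p <- base + t * sp
      ii <- floor(p[, 1] / voxel_size_mm[1]) + 1L
      jj <- floor(p[, 2] / voxel_size_mm[2]) + 1L
      kk <- floor(p[, 3] / voxel_size_mm[3]) + 1L
      ok <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] &
        kk >= 1L & kk <= dims[3]
      lin <- ii[ok] + (jj[ok] - 1L) * dims[1] + (kk[ok] - 1L) * dims[1] * dims[2]
      val <- volume[lin]
      keep <- is.finite(val)
      sigma <- sigma_scale * surface$thickness_mm[ok][keep]
      dist <- abs(t - 0.5) * surface$thickness_mm[ok][keep]
      w <- ifelse(sigma > 0, exp(-0.5 * (dist / sigma)^2), 1)
      idx <- which(ok)[keep]
      acc[idx] <- acc[idx] + w * val[keep]
      wsum[idx] <- wsum[idx] + w
    }
  }
  vals <- ifelse(wsum > 0, acc / wsum, NA_real_)
  unfolded_map(vals, surface$grid_shape, metric = metric, subject = subject,
               hemisphere = hemisphere)
}

# Half-step tangent vectors along the unfolded grid (rows or cols), V x 3.
.grid_tangent <- function(mid, rows, cols, along = c("row", "col")) {
  along <- match.arg(along)
  arr <- array(mid, dim = c(rows, cols, 3))
  g <- array(0, dim = c(rows, cols, 3))
  for (d in 1:3) {
    m <- arr[, , d]
    if (along == "row") {
      if (rows > 1) {
        cd <- (rbind(m[-1, , drop = FALSE], m[rows, , drop = FALSE]) -
               rbind(m[1, , drop = FALSE], m[-rows, , drop = FALSE])) /
          ifelse(rows > 2, 2, 1)
        cd[1, ] <- m[2, ] - m[1, ]
        cd[rows, ] <- m[rows, ] - m[rows - 1, ]
        g[, , d] <- cd
      }
    } else {
      if (cols > 1) {
        cd <- (cbind(m[, -1, drop = FALSE], m[, cols]) -
               cbind(m[, 1], m[, -cols, drop = FALSE])) / ifelse(cols > 2, 2, 1)
        cd[, 1] <- m[, 2] - m[, 1]
        cd[, cols] <- m[, cols] - m[, cols - 1]
        g[, , d] <- cd
      }
    }
  }
  matrix(g, nrow = rows * cols, ncol = 3)
}

#' Vertex-wise mean and SD across subject maps
#'
#' Averages a list of unfolded maps vertex-wise, ignoring missing entries.
#'
#' @param maps non-empty list of [unfolded_map()]s on identical grids.
#' @return list with `mean` and `sd` maps and per-vertex contributing count
#'   `n`.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop("empty map list")
  gs <- maps[[1]]$grid_shape
  met <- maps[[1]]$metric
  for (m in maps) {
    if (!identical(m$grid_shape, gs)) stop("maps have mismatched grids")
    if (!identical(m$metric, met)) stop("maps mix different metrics")
  }
  M <- vapply(maps, map_values, numeric(prod(gs)))
  M <- matrix(M, nrow = prod(gs))
  n <- rowSums(!is.na(M))
  mu <- rowMeans(M, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(M, 1, function(r) if (sum(!is.na(r)) > 1) stats::sd(r, na.rm = TRUE) else 0)
  sdv[n == 0] <- NA_real_
  list(mean = unfolded_map(mu, gs, metric = met),
       sd = unfolded_map(sdv, gs, metric = paste0(met, "_sd")),
       n = n)
}

#' Subfield averages of an unfolded map
#'
#' Unweighted mean of non-missing vertex values within each subfield.
#'
#' @param map an [unfolded_map()] or numeric vector.
#' @param labels per-vertex subfield labels (factor or character), e.g.
#'   `surface$subfield`.
#' @return named numeric vector, one mean per subfield level (NA, with a
#'   warning, for subfields with no valid vertices).
#' @export
subfield_average <- function(map, labels) {
  vals <- map_values(map)
  labels <- factor(labels, levels = if (is.factor(labels)) levels(labels) else unique(labels))
  if (length(labels) != length(vals)) stop("labels must cover every vertex")
  out <- tapply(vals, labels, function(v) mean(v, na.rm = TRUE))
  out <- as.numeric(out)
  names(out) <- levels(labels)
  empty <- tapply(vals, labels, function(v) all(is.na(v)))
  if (any(empty, na.rm = TRUE) || anyNA(out)) {
    bad <- names(out)[is.na(out) | is.nan(out)]
    if (length(bad)) {
      warning("no valid vertices for subfield(s): ", paste(bad, collapse = ", "))
      out[is.nan(out)] <- NA_real_
    }
  }
  out
}
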