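#' Solve Laplace's equation along one hippocampal axis
#'
#' Solves the Dirichlet problem \eqn{\nabla^2 \psi = 0} on the masked domain
#' with \eqn{\psi = 0} on the axis source set, \eqn{\psi = 1} on the sink
#' set, and a no-flux (reflecting) condition on the remaining mask boundary.
#' The discretization is a 6-connected finite-difference Laplacian with
#' per-axis \eqn{1/h^2} weights; omitting out-of-mask neighbours from the
#' stencil realizes the no-flux condition. The default solver is a sparse
#' direct factorization; `method = "jacobi"` runs point relaxation to `tol`
#' and fails explicitly (reporting the residual) if `max_iter` is exhausted.
#'
#' @param domain a [make_voxel_domain()] object.
#' @param axis `"AP"`, `"PD"` or `"IO"`.
#' @param tol maximum allowed residual of the discrete Laplacian at interior
#'   voxels (default 1e-6).
#' @param max_iter iteration cap for the Jacobi solver.
#' @param method `"direct"` (sparse solve) or `"jacobi"`.
#' @return 3D array of \eqn{\psi \in [0, 1]} (NA outside the mask) with
#'   attribute `residual`.
#' @export
solve_laplace <- function(domain, axis = c("AP", "PD", "IO"), tol = 1e-6,
                          max_iter = 50000L, method = c("direct", "jacobi")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  stopifnot(inherits(domain, "voxel_domain"), tol > 0)
  mask <- domain$mask
  dims <- dim(mask)
  b <- domain$boundaries[[axis]]

  psi <- array(NA_real_, dims)
  psi[b$source] <- 0
  psi[b$sink] <- 1

  fixed <- array(FALSE, dims)
  fixed[c(b$source, b$sink)] <- TRUE
  free <- which(mask & !fixed)
  if (!length(free)) return(structure(psi, residual = 0))

  w_axis <- 1 / domain$voxel_size_mm^2
  strides <- c(1L, dims[1], dims[1] * dims[2])
  ai_free <- arrayInd(free, dims)

  # neighbour table: for each free voxel, up to 6 in-mask neighbours
  nb_list <- vector("list", 6L)
  wt_list <- vector("list", 6L)
  s <- 0L
  for (d in 1:3) {
    for (sg in c(-1L, 1L)) {
      s <- s + 1L
      ok <- ai_free[, d] + sg >= 1L & ai_free[, d] + sg <= dims[d]
      nb <- rep(NA_integer_, length(free))
      nb[ok] <- free[ok] + sg * strides[d]
      nb[!is.na(nb) & !mask[ifelse(is.na(nb), 1L, nb)]] <- NA_integer_
      nb_list[[s]] <- nb
      wt_list[[s]] <- ifelse(is.na(nb), 0, w_axis[d])
    }
  }
  diag_w <- Reduce(`+`, wt_list)

  pos <- integer(prod(dims))          # linear index -> free-row index
  pos[free] <- seq_along(free)

  if (method == "direct") {
    ii <- jj <- integer(0); xx <- numeric(0)
    rhs <- numeric(length(free))
    for (s in 1:6) {
      nb <- nb_list[[s]]; wt <- wt_list[[s]]
      has <- !is.na(nb)
      is_free_nb <- has & pos[ifelse(has, nb, 1L)] > 0
      is_fixed_nb <- has & !is_free_nb
      ii <- c(ii, which(is_free_nb))
      jj <- c(jj, pos[nb[is_free_nb]])
      xx <- c(xx, -wt[is_free_nb])
      if (any(is_fixed_nb)) {
        rhs[is_fixed_nb] <- rhs[is_fixed_nb] +
          wt[is_fixed_nb] * psi[nb[is_fixed_nb]]
      }
    }
    A <- Matrix::sparseMatrix(i = c(seq_along(free), ii),
                              j = c(seq_along(free), jj),
                              x = c(diag_w, xx),
                              dims = c(length(free), length(free)))
    sol <- as.vector(Matrix::solve(A, rhs))
    psi[free] <- sol
  } else {
    x <- rep(0.5, length(free))
    val <- function(v) ifelse(is.na(v), 0, psi[ifelse(is.na(v), 1L, v)])
    for (it in seq_len(max_iter)) {
      acc <- numeric(length(free))
      for (s in 1:6) {
        nb <- nb_list[[s]]; wt <- wt_list[[s]]
        has <- !is.na(nb)
        isf <- has & pos[ifelse(has, nb, 1L)] > 0
        acc[isf] <- acc[isf] + wt[isf] * x[pos[nb[isf]]]
        isx <- has & !isf
        acc[isx] <- acc[isx] + wt[isx] * psi[nb[isx]]
      }
      xn <- acc / diag_w
      if (it %% 20 == 0 || it == max_iter) {
        psi[free] <- xn
        res <- .laplace_residual(psi, free, nb_list, wt_list, diag_w)
        if (res < tol) break
        if (it == max_iter) {
          stop(sprintf("Jacobi solver did not converge in %d iterations (residual %.3g > tol %.3g)",
                       max_iter, res, tol))
        }
      }
      x <- xn
    }
    psi[free] <- xn
  }

  res <- .laplace_residual(psi, free, nb_list, wt_list, diag_w)
  if (method == "direct" && res > tol) {
    stop(sprintf("direct solve residual %.3g exceeds tol %.3g", res, tol))
  }
  # maximum principle (guards discretization errors)
  rng <- range(psi[free])
  if (rng[1] < -1e-10 || rng[2] > 1 + 1e-10) {
    stop("solved field violates the maximum principle")
  }
  psi[free] <- pmin(pmax(psi[free], 0), 1)
  structure(psi, residual = res)
}

.laplace_residual <- function(psi, free, nb_list, wt_list, diag_w) {
  acc <- numeric(length(free))
  for (s in 1:6) {
    nb <- nb_list[[s]]; wt <- wt_list[[s]]
    has <- !is.na(nb)
    acc[has] <- acc[has] + wt[has] * psi[nb[has]]
  }
  max(abs(acc - diag_w * psi[free]))
}

#' Solve all three axis coordinate fields
#'
#' @inheritParams solve_laplace
#' @param ... passed to [solve_laplace()].
#' @return a `laplace_coords`: list with `psi_AP`, `psi_PD`, `psi_IO` arrays
#'   and the originating `domain`.
#' @export
laplace_coordinates <- function(domain, ...) {
  out <- list(psi_AP = solve_laplace(domain, "AP", ...),
              psi_PD = solve_laplace(domain, "PD", ...),
              psi_IO = solve_laplace(domain, "IO", ...),
              domain = domain)
  class(out) <- "laplace_coords"
  out
}

#' Unit gradient vector fields of the Laplace coordinates
#'
#' Differentiates each coordinate field with central differences (one-sided
#' at mask edges), divides by the voxel size so vectors live in physical
#' (mm) space, and unit-normalizes. Voxels whose raw gradient magnitude is
#' below `min_norm` are flagged invalid rather than zero-normalized.
#'
#' @param coords a [laplace_coordinates()] object (or a single psi array, in
#'   which case `domain` must be supplied).
#' @param domain the voxel domain (taken from `coords` when available).
#' @param min_norm gradient magnitudes below this are invalid.
#' @return an `axis_fields`: for each axis a 4D array (dims x 3) `G_AP`,
#'   `G_PD`, `G_IO` of unit vectors (NA where invalid) plus a logical
#'   `valid` array per axis.
#' @export
gradient_fields <- function(coords, domain = NULL, min_norm = 1e-12) {
  if (inherits(coords, "laplace_coords")) {
    domain <- coords$domain
    fields <- list(AP = coords$psi_AP, PD = coords$psi_PD, IO = coords$psi_IO)
  } else {
    if (is.null(domain)) stop("`domain` required when `coords` is a bare array")
    fields <- list(AP = coords)
  }
  out <- list()
  for (ax in names(fields)) {
    g <- .masked_gradient(fields[[ax]], domain$mask, domain$voxel_size_mm)
    nrm <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
    valid <- domain$mask & is.finite(nrm) & nrm > min_norm
    if (!any(valid)) warning("all gradients are flat for axis ", ax)
    for (d in 1:3) {
      comp <- g[, , , d]
      comp[valid] <- comp[valid] / nrm[valid]
      comp[!valid] <- NA_real_
      g[, , , d] <- comp
    }
    out[[paste0("G_", ax)]] <- g
    out[[paste0("valid_", ax)]] <- valid
  }
  out$domain <- domain
  class(out) <- "axis_fields"
  out
}

# Central differences inside the mask, one-sided at mask edges; mm units.
.masked_gradient <- function(psi, mask, voxel_size_mm) {
  dims <- dim(psi)
  g <- array(NA_real_, c(dims, 3))
  lin <- which(mask)
  ai <- arrayInd(lin, dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (d in 1:3) {
    up_ok <- ai[, d] + 1L <= dims[d]
    up <- ifelse(up_ok, lin + strides[d], NA_integer_)
    up[!is.na(up) & !mask[ifelse(is.na(up), 1L, up)]] <- NA_integer_
    dn_ok <- ai[, d] - 1L >= 1L
    dn <- ifelse(dn_ok, lin - strides[d], NA_integer_)
    dn[!is.na(dn) & !mask[ifelse(is.na(dn), 1L, dn)]] <- NA_integer_

    val <- rep(NA_real_, length(lin))
    both <- !is.na(up) & !is.na(dn)
    val[both] <- (psi[up[both]] - psi[dn[both]]) / (2 * voxel_size_mm[d])
    fwd <- !is.na(up) & is.na(dn)
    val[fwd] <- (psi[up[fwd]] - psi[lin[fwd]]) / voxel_size_mm[d]
    bwd <- is.na(up) & !is.na(dn)
    val[bwd] <- (psi[lin[bwd]] - psi[dn[bwd]]) / voxel_size_mm[d]
    val[is.na(up) & is.na(dn)] <- 0
    comp <- array(NA_real_, dims)
    comp[lin] <- val
    g[, , , d] <- comp
  }
  g
}
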