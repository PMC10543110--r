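# Shared fixtures and independent oracles.

# Compact three-shell scheme for fast fits in unit tests.
test_scheme <- function(n_dir = 30, n_b0 = 6) make_scheme(c(1000, 2000, 3000), n_dir, n_b0)

# Brute-force Watson-NODDI forward model by equal-weight quadrature over a
# Fibonacci sphere lattice: the independent oracle for noddi_forward(). The
# intra-cellular term averages the stick kernel under the Watson weights;
# the extra-cellular term exponentiates the brute-force Watson-averaged
# zeppelin tensor.
oracle_noddi_forward <- function(params, scheme, n_points = 10000) {
  pts <- hippmap:::fibonacci_sphere(n_points)
  w <- exp(params$kappa * as.vector(pts %*% params$mu)^2)
  w <- w / sum(w)
  b <- scheme$bvals
  ct <- scheme$bvecs %*% t(pts)                       # n_meas x n_points
  e_ic <- as.vector(exp(-b * params$d_par * ct^2) %*% w)
  tissue <- params$f_ic + params$f_ec
  nu_ic <- if (tissue > 0) params$f_ic / tissue else 0
  d_perp <- params$d_par * (1 - nu_ic)
  Dbar <- d_perp * diag(3) +
    (params$d_par - d_perp) * crossprod(pts * sqrt(w))
  e_ec <- exp(-b * rowSums((scheme$bvecs %*% Dbar) * scheme$bvecs))
  params$f_iso * exp(-b * params$d_iso) + params$f_ec * e_ec + params$f_ic * e_ic
}

# Dense Jacobi relaxation for the masked Laplace problem; the independent
# oracle for solve_laplace(). Plain array sweeps, no shared code.
oracle_jacobi_laplace <- function(mask, source, sink, tol = 1e-10,
                                  max_iter = 200000) {
  dims <- dim(mask)
  psi <- array(0, dims)
  psi[sink] <- 1
  fixed <- array(FALSE, dims)
  fixed[c(source, sink)] <- TRUE
  free <- which(mask & !fixed)
  ai <- arrayInd(free, dims)
  strides <- c(1, dims[1], dims[1] * dims[2])
  nbs <- list(); wts <- list()
  kk <- 0
  for (d in 1:3) for (s in c(-1, 1)) {
    kk <- kk + 1
    ok <- ai[, d] + s >= 1 & ai[, d] + s <= dims[d]
    nb <- ifelse(ok, free + s * strides[d], NA)
    nb[!is.na(nb) & !mask[ifelse(is.na(nb), 1, nb)]] <- NA
    nbs[[kk]] <- nb
    wts[[kk]] <- !is.na(nb)
  }
  deg <- Reduce(`+`, wts)
  for (it in seq_len(max_iter)) {
    acc <- numeric(length(free))
    for (kk in 1:6) {
      has <- wts[[kk]]
      acc[has] <- acc[has] + psi[nbs[[kk]][has]]
    }
    new <- acc / deg
    delta <- max(abs(new - psi[free]))
    psi[free] <- new
    if (delta < tol) break
  }
  psi[!mask] <- NA
  psi
}

# An L-shaped custom domain with AP boundaries on the two far faces.
make_l_domain <- function() {
  dims <- c(12, 12, 8)
  mask <- array(FALSE, dims)
  mask[1:12, 1:5, ] <- TRUE
  mask[1:5, 1:12, ] <- TRUE
  lin <- which(mask)
  ai <- arrayInd(lin, dims)
  src <- lin[ai[, 1] == 1 & ai[, 2] <= 5]
  snk <- lin[ai[, 2] == 12]
  voxel_domain(mask, list(AP = list(source = src, sink = snk)))
}

# Uniform ground-truth parameter fields over a whole domain.
uniform_truth <- function(domain, f_iso = 0.1, f_ic = 0.6, odi = 0.3,
                          mu = c(0, 0, 1)) {
  dims <- dim(domain$mask)
  lin <- which(domain$mask)
  arr <- function(v) { a <- array(NA_real_, dims); a[lin] <- v; a }
  mu_arr <- array(NA_real_, c(dims, 3))
  for (d in 1:3) { a <- array(NA_real_, dims); a[lin] <- mu[d]; mu_arr[, , , d] <- a }
  structure(list(f_iso = arr(f_iso), f_ic = arr(f_ic), odi = arr(odi),
                 kappa = arr(kappa_from_odi(odi)), mu = mu_arr,
                 domain = domain),
            class = "voxel_params")
}
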