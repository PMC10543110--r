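# Synthetic inputs for every pipeline stage: voxel-domain ground truth,
# multi-shell diffusion signals from the Watson-NODDI forward model, smooth
# unfolded multi-subject stacks with planted parcels, and subfield metric
# tables. All generators are pure functions of (arguments, seed).

# Intrinsic PD coordinate in [0, 1] for masked voxels.
.pd_fraction <- function(domain, lin = which(domain$mask)) {
  ai <- arrayInd(lin, dim(domain$mask))
  if (domain$geometry == "slab") {
    (ai[, 2] - 0.5) / domain$shape_intrinsic[2]
  } else {
    ctr <- domain$embed$centre_voxel
    x <- ai[, 1] - 0.5 - ctr[1]
    y <- ai[, 2] - 0.5 - ctr[2]
    atan2(y, x) / pi
  }
}

#' Ground-truth NODDI parameter fields on a voxel domain
#'
#' Assigns per-voxel NODDI parameters with subfield-like banding along the
#' PD axis: each of five PD bands gets distinct mean neurite density and
#' dispersion (mirroring the kind of contrast seen between hippocampal
#' subfields), plus optional Gaussian jitter. The true orientation `mu` at
#' each voxel follows one of the domain's axis fields when `axes` is
#' supplied (per-band assignment, emulating tangential vs radial circuitry),
#' otherwise a fixed direction.
#'
#' @param domain a [make_voxel_domain()] object.
#' @param axes optional [gradient_fields()] result on the same domain.
#' @param band_axes length-5 character vector assigning each PD band an axis
#'   (`"AP"`, `"PD"`, `"IO"`); used only when `axes` is given.
#' @param f_iso isotropic fraction (scalar, shared).
#' @param jitter_sd SD of per-voxel Gaussian jitter on f_ic and odi.
#' @param seed integer seed for the jitter.
#' @return a `voxel_params`: arrays `f_iso`, `f_ic`, `odi`, `kappa` and the
#'   orientation field `mu` (dims x 3), plus the domain.
#' @export
make_ground_truth_params <- function(domain, axes = NULL,
                                     band_axes = c("AP", "PD", "IO", "AP", "PD"),
                                     f_iso = 0.08, jitter_sd = 0,
                                     seed = 1L) {
  stopifnot(inherits(domain, "voxel_domain"))
  dims <- dim(domain$mask)
  lin <- which(domain$mask)
  pd <- .pd_fraction(domain, lin)
  band <- pmin(pmax(findInterval(pd, seq(0, 1, length.out = 6),
                                 rightmost.closed = TRUE), 1L), 5L)
  # band-wise (f_ic, odi) means: Sub, CA1, CA2, CA3, DG/CA4-like contrast
  f_ic_band <- c(0.58, 0.38, 0.50, 0.56, 0.45)
  odi_band <- c(0.42, 0.58, 0.47, 0.38, 0.36)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f_ic <- pmin(pmax(f_ic_band[band] + stats::rnorm(length(lin), 0, jitter_sd), 0.05), 0.85)
  odi <- pmin(pmax(odi_band[band] + stats::rnorm(length(lin), 0, jitter_sd), 0.03), 0.95)

  arr <- function(v) { a <- array(NA_real_, dims); a[lin] <- v; a }
  mu <- array(NA_real_, c(dims, 3))
  if (is.null(axes)) {
    mu_v <- matrix(rep(c(0, 0, 1), each = length(lin)), ncol = 3)
  } else {
    mu_v <- matrix(NA_real_, length(lin), 3)
    for (b in 1:5) {
      sel <- band == b
      G <- axes[[paste0("G_", band_axes[b])]]
      for (d in 1:3) mu_v[sel, d] <- G[, , , d][lin[sel]]
    }
    bad <- !is.finite(rowSums(mu_v))
    mu_v[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  }
  for (d in 1:3) { a <- array(NA_real_, dims); a[lin] <- mu_v[, d]; mu[, , , d] <- a }

  structure(list(f_iso = arr(rep(f_iso, length(lin))), f_ic = arr(f_ic),
                 odi = arr(odi), kappa = arr(kappa_from_odi(odi)),
                 mu = mu, domain = domain, band = arr(band)),
            class = "voxel_params")
}

# save/restore the global RNG state so generators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate multi-shell diffusion signals from the NODDI forward model
#'
#' Generates a 4D signal volume: the noiseless signal at each masked voxel
#' equals [noddi_forward()] for that voxel's ground-truth parameters (b = 0
#' signal normalized to 1), and optional noise is added at scale
#' `mean(b0) / snr = 1 / snr`.
#'
#' @param params a [make_ground_truth_params()] `voxel_params` object.
#' @param scheme an [acq_scheme()] with at least one b = 0 volume.
#' @param snr positive signal-to-noise ratio at b = 0, or `NULL` for
#'   noiseless signals.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian perturbation).
#' @param seed integer seed for the noise.
#' @param n_gl Watson quadrature order for the forward model.
#' @return 4D array (volume dims x n_volumes); NA outside the mask.
#' @export
simulate_dwi <- function(params, scheme, snr = NULL,
                         noise_model = c("gaussian", "rician"), seed = 1L,
                         n_gl = 64) {
  stopifnot(inherits(params, "voxel_params"), inherits(scheme, "acq_scheme"))
  noise_model <- match.arg(noise_model)
  if (!is.null(snr) && (!is.finite(snr) || snr <= 0)) stop("`snr` must be positive")
  dims <- dim(params$domain$mask)
  lin <- which(params$domain$mask)
  n_meas <- length(scheme$bvals)
  sig <- matrix(NA_real_, length(lin), n_meas)
  mu_mat <- cbind(params$mu[, , , 1][lin], params$mu[, , , 2][lin], params$mu[, , , 3][lin])
  for (i in seq_along(lin)) {
    p <- noddi_params(f_iso = params$f_iso[lin[i]], f_ic = params$f_ic[lin[i]],
                      kappa = params$kappa[lin[i]], mu = mu_mat[i, ])
    sig[i, ] <- noddi_forward(p, scheme, n_gl = n_gl)
  }
  if (!is.null(snr)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sd <- 1 / snr
    if (noise_model == "gaussian") {
      sig <- sig + matrix(stats::rnorm(length(sig), 0, sd), nrow(sig))
    } else {
      n1 <- matrix(stats::rnorm(length(sig), 0, sd), nrow(sig))
      n2 <- matrix(stats::rnorm(length(sig), 0, sd), nrow(sig))
      sig <- sqrt((sig + n1)^2 + n2^2)
    }
  }
  out <- array(NA_real_, c(dims, n_meas))
  for (m in seq_len(n_meas)) {
    a <- array(NA_real_, dims); a[lin] <- sig[, m]
    out[, , , m] <- a
  }
  out
}

#' Smooth periodic Gaussian noise fields on the unfolded grid
#'
#' White noise convolved with a periodic (torus-wrapped) Gaussian kernel via
#' FFT and rescaled to unit marginal variance, matching the periodic-domain
#' assumption of the torus spin test.
#'
#' @param grid_shape integer pair (rows, cols).
#' @param smoothness_mm Gaussian kernel SD in vertex units (1 mm spacing).
#' @param n number of independent fields.
#' @param seed integer seed.
#' @return matrix (prod(grid_shape) x n), column-major vertex order.
#' @export
smooth_grid_noise <- function(grid_shape, smoothness_mm = 2, n = 1, seed = 1L) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  # periodic Gaussian kernel, unit-sum, then unit-variance output scaling
  dr <- pmin(0:(rows - 1), rows - 0:(rows - 1))
  dc <- pmin(0:(cols - 1), cols - 0:(cols - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * smoothness_mm^2))
  k <- k / sum(k)
  Kf <- stats::fft(k)
  gain <- sqrt(sum(k^2))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(0, rows * cols, n)
  for (i in seq_len(n)) {
    w <- matrix(stats::rnorm(rows * cols), rows, cols)
    sm <- Re(stats::fft(stats::fft(w) * Kf, inverse = TRUE)) / (rows * cols)
    out[, i] <- as.vector(sm) / gain
  }
  out
}

#' Synthetic multi-subject unfolded dataset with planted parcels
#'
#' Emulates the vertices x subject-metrics stack that feeds OPNNMF: the grid
#' is partitioned into `true_rank` contiguous parcels, every subject-metric
#' column loads non-negatively on each parcel, and smooth periodic Gaussian
#' noise is added. Ground-truth labels are returned so parcellation recovery
#' can be scored.
#'
#' @param grid_shape integer pair (rows, cols); default 64 x 32 = 2048
#'   vertices, close to the 2004-vertex real surfaces it stands in for.
#' @param n_subjects number of subjects.
#' @param true_rank number of planted parcels (k).
#' @param effect_size scale of the parcel loadings relative to unit-variance
#'   noise; 0 gives pure smooth noise.
#' @param smoothness_mm noise smoothness (vertex units).
#' @param n_metrics,metric_names metrics per subject.
#' @param noise_sd SD of the smooth noise component.
#' @param seed integer seed.
#' @return an `unfolded_dataset`: `maps` (V x n_subjects*n_metrics matrix),
#'   `columns` (subject/metric metadata), `true_parcels`, `true_rank`,
#'   `grid_shape`, `hemisphere`.
#' @export
make_unfolded_dataset <- function(grid_shape = c(64, 32), n_subjects = 10,
                                  true_rank = 4, effect_size = 1,
                                  smoothness_mm = 2, n_metrics = 3,
                                  metric_names = paste0("metric", seq_len(n_metrics)),
                                  noise_sd = 0.2, seed = 1L) {
  V <- prod(grid_shape)
  n_cols <- n_subjects * n_metrics
  if (true_rank > min(V, n_cols)) {
    stop("`true_rank` must not exceed min(grid cells, n_subjects x n_metrics)")
  }
  # contiguous parcels: near-equal bands of the PD (column) axis, falling
  # back to linear-index bands when there are fewer columns than parcels
  cols_idx <- rep(seq_len(grid_shape[2]), each = grid_shape[1])
  if (grid_shape[2] >= true_rank) {
    parcels <- as.integer(cut(cols_idx, true_rank, labels = FALSE))
  } else {
    parcels <- as.integer(cut(seq_len(V), true_rank, labels = FALSE))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  loadings <- matrix(abs(stats::rnorm(true_rank * n_cols, mean = 1, sd = 0.3)),
                     true_rank, n_cols) * effect_size
  indic <- matrix(0, V, true_rank)
  indic[cbind(seq_len(V), parcels)] <- 1
  noise <- smooth_grid_noise(grid_shape, smoothness_mm, n = n_cols,
                             seed = seed + 1L) * noise_sd
  maps <- indic %*% loadings + noise
  columns <- data.frame(subject = rep(sprintf("sub%03d", seq_len(n_subjects)),
                                      each = n_metrics),
                        metric = rep(metric_names, times = n_subjects),
                        stringsAsFactors = FALSE)
  structure(list(maps = maps, columns = columns, true_parcels = parcels,
                 true_rank = as.integer(true_rank),
                 grid_shape = as.integer(grid_shape),
                 metric_names = metric_names, hemisphere = "L"),
            class = "unfolded_dataset")
}

#' @export
print.unfolded_dataset <- function(x, ...) {
  cat(sprintf("Unfolded dataset: %d vertices (%d x %d) x %d subject-metrics, %d planted parcels\n",
              nrow(x$maps), x$grid_shape[1], x$grid_shape[2], ncol(x$maps),
              x$true_rank))
  invisible(x)
}

#' Pair of smooth unfolded maps with a target Spearman correlation
#'
#' Mixes two independent smooth latent Gaussian fields so the population
#' Spearman correlation of the pair equals `rho_target` (using the exact
#' Gaussian rank-correlation relation
#' \eqn{\rho_s = (6/\pi)\,\mathrm{asin}(\rho_P/2)} to pick the Pearson
#' mixing weight).
#'
#' @param grid_shape integer pair (rows, cols).
#' @param rho_target target Spearman correlation, |rho| < 1.
#' @param smoothness_mm latent field smoothness.
#' @param seed integer seed.
#' @return list of two [unfolded_map()]s, `map_a` and `map_b`.
#' @export
make_correlated_map_pair <- function(grid_shape = c(64, 32), rho_target = 0,
                                     smoothness_mm = 2, seed = 1L) {
  if (!is.finite(rho_target) || abs(rho_target) >= 1) stop("|rho_target| must be < 1")
  rho_p <- 2 * sin(pi * rho_target / 6)
  L <- smooth_grid_noise(grid_shape, smoothness_mm, n = 2, seed = seed)
  a <- L[, 1]
  b <- rho_p * L[, 1] + sqrt(1 - rho_p^2) * L[, 2]
  list(map_a = unfolded_map(a, grid_shape, metric = "map_a"),
       map_b = unfolded_map(b, grid_shape, metric = "map_b"))
}

#' Synthetic subject x subfield microstructure table
#'
#' Draws subfield-averaged (ODI, NDI, T1w/T2w) triples for each
#' subject-hemisphere-subfield combination from per-subfield Gaussian
#' distributions — the fixture for the subfield-separability classifier.
#'
#' @param n_subjects number of subjects (each contributes both hemispheres).
#' @param class_means 5 x 3 matrix of per-subfield means (rows in the order
#'   Sub, CA1, CA2, CA3, DG/CA4; columns odi, ndi, t1wt2w). The default
#'   mirrors the banding of [make_ground_truth_params()].
#' @param class_cov 3 x 3 positive semi-definite covariance shared across
#'   subfields (the zero matrix gives rows exactly at their class means).
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `hemisphere`, `subfield`,
#'   `odi`, `ndi`, `t1wt2w`.
#' @export
make_subfield_table <- function(n_subjects = 100,
                                class_means = NULL, class_cov = NULL,
                                seed = 1L) {
  if (is.null(class_means)) {
    class_means <- rbind(Sub = c(0.42, 0.58, 1.65),
                         CA1 = c(0.58, 0.38, 1.35),
                         CA2 = c(0.47, 0.50, 1.50),
                         CA3 = c(0.38, 0.56, 1.60),
                         "DG/CA4" = c(0.36, 0.45, 1.45))
    colnames(class_means) <- c("odi", "ndi", "t1wt2w")
  }
  class_means <- as.matrix(class_means)
  if (nrow(class_means) != 5 || ncol(class_means) != 3) {
    stop("`class_means` must be a 5 x 3 matrix (subfields x odi/ndi/t1wt2w)")
  }
  if (is.null(class_cov)) class_cov <- diag(c(0.035, 0.035, 0.08)^2)
  class_cov <- as.matrix(class_cov)
  ev <- eigen(class_cov, symmetric = TRUE)
  if (any(ev$values < -1e-12)) stop("`class_cov` is not positive semi-definite")
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- expand.grid(subfield = SUBFIELDS, hemisphere = c("L", "R"),
                      subject = sprintf("sub%03d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  cls <- match(grid$subfield, SUBFIELDS)
  Z <- matrix(stats::rnorm(nrow(grid) * 3), ncol = 3)
  draws <- class_means[cls, , drop = FALSE] + Z %*% t(A)
  out <- data.frame(subject = grid$subject, hemisphere = grid$hemisphere,
                    subfield = factor(grid$subfield, levels = SUBFIELDS),
                    odi = draws[, 1], ndi = draws[, 2], t1wt2w = draws[, 3],
                    stringsAsFactors = FALSE)
  out[order(out$subject, out$hemisphere, as.integer(out$subfield)), ,
      drop = FALSE]
}
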