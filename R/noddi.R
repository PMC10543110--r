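#' NODDI compartment parameters
#'
#' Parameter set for the three-compartment Watson-NODDI model: an isotropic
#' CSF compartment (fraction `f_iso`, diffusivity `d_iso`), intra-cellular
#' sticks (fraction `f_ic`, the neurite density index) and an extra-cellular
#' zeppelin (fraction `f_ec = 1 - f_iso - f_ic`), with the stick and zeppelin
#' linked orientationally by a Watson distribution with mean orientation `mu`
#' and concentration `kappa`. Diffusivities default to the grey-matter
#' optimized axial value `d_par = 1.1e-3` mm^2/s and `d_iso = 3.0e-3` mm^2/s;
#' the zeppelin radial diffusivity follows the tortuosity rule
#' `d_perp = d_par * (1 - nu_ic)` with `nu_ic = f_ic / (f_ic + f_ec)`.
#'
#' Exactly one of `kappa` or `odi` must be given (they are linked by
#' [odi_from_kappa()]). `mu` and `-mu` are equivalent (antipodal symmetry).
#'
#' @param f_iso isotropic (CSF) volume fraction in \[0, 1\].
#' @param f_ic intra-cellular volume fraction (NDI) in \[0, 1\];
#'   `f_iso + f_ic <= 1`.
#' @param kappa Watson concentration (> 0), or `NULL` if `odi` given.
#' @param odi orientation dispersion index in (0, 1\], or `NULL`.
#' @param mu length-3 mean orientation; normalized internally.
#' @param d_par,d_iso axial and isotropic diffusivities in mm^2/s.
#' @return an object of class `noddi_params`.
#' @export
#' @examples
#' noddi_params(f_iso = 0.1, f_ic = 0.6, odi = 0.3, mu = c(0, 0, 1))
noddi_params <- function(f_iso, f_ic, kappa = NULL, odi = NULL, mu = c(0, 0, 1),
                         d_par = 1.1e-3, d_iso = 3.0e-3) {
  if (is.null(kappa) == is.null(odi)) stop("give exactly one of `kappa` or `odi`")
  if (is.null(kappa)) kappa <- kappa_from_odi(odi)
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be positive")
  if (f_iso < 0 || f_ic < 0 || f_iso > 1 || f_ic > 1 || f_iso + f_ic > 1 + 1e-9) {
    stop("fractions must lie in [0, 1] with f_iso + f_ic <= 1")
  }
  nmu <- sqrt(sum(mu^2))
  if (length(mu) != 3 || nmu == 0 || any(!is.finite(mu))) {
    stop("`mu` must be a non-zero 3-vector")
  }
  f_ec <- max(1 - f_iso - f_ic, 0)
  structure(list(
    f_iso = f_iso, f_ic = f_ic, f_ec = f_ec,
    kappa = kappa, odi = odi_from_kappa(kappa),
    mu = mu / nmu, d_par = d_par, d_iso = d_iso
  ), class = "noddi_params")
}

#' @export
print.noddi_params <- function(x, ...) {
  cat(sprintf(
    "NODDI parameters: f_iso=%.3f f_ic=%.3f f_ec=%.3f odi=%.3f (kappa=%.2f)\n  mu=(%.3f, %.3f, %.3f)\n",
    x$f_iso, x$f_ic, x$f_ec, x$odi, x$kappa, x$mu[1], x$mu[2], x$mu[3]))
  invisible(x)
}

# Tortuosity-model radial diffusivity of the extra-cellular zeppelin.
.d_perp <- function(params) {
  tissue <- params$f_ic + params$f_ec
  nu_ic <- if (tissue > 0) params$f_ic / tissue else 0
  params$d_par * (1 - nu_ic)
}

#' Watson-NODDI forward model
#'
#' Normalized diffusion signal of the three-compartment model:
#' `E = f_iso * E_iso + f_ec * E_ec + f_ic * E_ic` with
#' `E_iso = exp(-b d_iso)`; `E_ic` the Watson-ODF spherical average of the
#' stick signal `exp(-b d_par (g.n)^2)`; and `E_ec` the signal of the
#' Watson-averaged zeppelin, `exp(-b g' D g)` with
#' `D = d_perp I + (d_par - d_perp) <n n'>` under the Watson distribution.
#' `E(b = 0) = 1` exactly, and the model is antipodally symmetric in `mu`.
#'
#' @param params a [noddi_params()] object.
#' @param scheme an [acq_scheme()].
#' @param n_gl number of Gauss-Legendre nodes for the Watson integrals.
#' @return numeric vector of normalized signals, one per scheme volume.
#' @export
noddi_forward <- function(params, scheme, n_gl = 64) {
  stopifnot(inherits(params, "noddi_params"), inherits(scheme, "acq_scheme"))
  b <- scheme$bvals
  ct <- as.vector(scheme$bvecs %*% params$mu)
  ct[b == 0] <- 0

  e_iso <- exp(-b * params$d_iso)
  e_ic <- .watson_kernel_attenuation(params$kappa, b * params$d_par, ct, n_gl = n_gl)

  dp <- .d_perp(params)
  tau1 <- .watson_tau1(params$kappa, n_gl = n_gl)
  # g' <D> g = d_perp + (d_par - d_perp) * (tau1 ct^2 + (1 - tau1)/2 (1 - ct^2))
  proj <- tau1 * ct^2 + 0.5 * (1 - tau1) * (1 - ct^2)
  e_ec <- exp(-b * (dp + (params$d_par - dp) * proj))

  params$f_iso * e_iso + params$f_ec * e_ec + params$f_ic * e_ic
}

# ---- fitting -------------------------------------------------------------

# theta = (qlogis(f_iso), qlogis(nu_ic), log kappa, polar, azimuth)
.theta_to_params <- function(theta, d_par, d_iso) {
  f_iso <- stats::plogis(theta[1])
  nu <- stats::plogis(theta[2])
  kappa <- exp(theta[3])
  mu <- c(sin(theta[4]) * cos(theta[5]), sin(theta[4]) * sin(theta[5]), cos(theta[4]))
  f_ic <- (1 - f_iso) * nu
  noddi_params(f_iso = f_iso, f_ic = f_ic, kappa = kappa, mu = mu,
               d_par = d_par, d_iso = d_iso)
}

.mu_to_angles <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  c(acos(max(min(mu[3], 1), -1)), atan2(mu[2], mu[1]))
}

#' Fit the Watson-NODDI model to one voxel
#'
#' Bounded nonlinear least squares over `(f_iso, f_ic, kappa, mu)` with the
#' diffusivities held fixed at their grey-matter values. Fractions are fitted
#' through a logistic transform and `kappa` through a log transform; the
#' optimizer is initialized from a coarse grid over `(f_iso, nu_ic, odi)`
#' with `mu` taken from the principal DTI eigenvector of the b = 1000 shell
#' (falling back to a signal-weighted dyadic if DTI is unavailable). The fit
#' is fully deterministic.
#'
#' @param signals numeric vector of measured signals (one per scheme volume);
#'   normalized internally by the mean b = 0 signal.
#' @param scheme an [acq_scheme()]; at least one b = 0 volume. A warning is
#'   emitted if fewer than two non-zero shells are present.
#' @param options list of fit options: `method` ("bfgs" or "nm"), `maxit`,
#'   `reltol`, `n_gl` (Watson quadrature order), `init_grid` (logical),
#'   `d_par`, `d_iso`.
#' @return a `noddi_fit`: the fitted [noddi_params()] plus `residual_norm`,
#'   `converged` and `flag` ("ok" or "bad_signal").
#' @export
fit_noddi <- function(signals, scheme, options = list()) {
  stopifnot(inherits(scheme, "acq_scheme"))
  opt <- utils::modifyList(list(
    method = "bfgs", maxit = 400L, reltol = 1e-12, n_gl = 64L,
    init_grid = TRUE, d_par = 1.1e-3, d_iso = 3.0e-3
  ), options)

  b0 <- scheme$bvals == 0
  if (!any(b0)) stop("scheme has no b = 0 volume")
  if (length(unique(scheme$bvals[!b0])) < 2) {
    warning("fewer than two non-zero shells: NODDI fit may be poorly conditioned")
  }
  if (any(!is.finite(signals)) || all(signals == 0)) {
    return(structure(list(params = NULL, residual_norm = NA_real_,
                          converged = FALSE, flag = "bad_signal"),
                     class = "noddi_fit"))
  }
  s <- signals / mean(signals[b0])

  # lean forward evaluation: same model as noddi_forward() without the
  # per-call container construction (the optimizer calls this thousands of
  # times per voxel)
  b <- scheme$bvals
  bvecs <- scheme$bvecs
  e_iso <- exp(-b * opt$d_iso)
  bd_par <- b * opt$d_par
  gl1 <- .gauss_legendre(opt$n_gl)
  gl01 <- .gauss_legendre(opt$n_gl, 0, 1)
  obj <- function(theta) {
    f_iso <- stats::plogis(theta[1])
    nu <- stats::plogis(theta[2])
    kappa <- exp(theta[3])
    st_ <- sin(theta[4])
    mu <- c(st_ * cos(theta[5]), st_ * sin(theta[5]), cos(theta[4]))
    f_ic <- (1 - f_iso) * nu
    f_ec <- (1 - f_iso) * (1 - nu)
    ct <- bvecs %*% mu
    e_ic <- .watson_kernel_attenuation(kappa, bd_par, ct, gl = gl1)
    dp <- opt$d_par * (1 - nu)
    tau1 <- .watson_tau1(kappa, gl = gl01)
    proj <- tau1 * ct^2 + 0.5 * (1 - tau1) * (1 - ct^2)
    e_ec <- exp(-b * (dp + (opt$d_par - dp) * proj))
    E <- f_iso * e_iso + f_ec * e_ec + f_ic * e_ic
    sum((E - s)^2)
  }

  mu0 <- .init_orientation(s, scheme)
  ang <- .mu_to_angles(mu0)

  if (isTRUE(opt$init_grid)) {
    grid <- expand.grid(f_iso = c(0.05, 0.4, 0.8),
                        nu = c(0.25, 0.55, 0.8),
                        odi = c(0.1, 0.3, 0.6))
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      obj(c(stats::qlogis(grid$f_iso[i]), stats::qlogis(grid$nu[i]),
            log(kappa_from_odi(grid$odi[i])), ang))
    }, numeric(1))
    best <- grid[which.min(vals), ]
    theta0 <- c(stats::qlogis(best$f_iso), stats::qlogis(best$nu),
                log(kappa_from_odi(best$odi)), ang)
  } else {
    theta0 <- c(stats::qlogis(0.2), stats::qlogis(0.5), log(kappa_from_odi(0.3)), ang)
  }

  method <- if (identical(opt$method, "nm")) "Nelder-Mead" else "BFGS"
  fit <- stats::optim(theta0, obj, method = method,
                      control = list(maxit = opt$maxit, reltol = opt$reltol))
  if (method == "BFGS") {  # polish: BFGS occasionally stalls on the angles
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 200L, reltol = opt$reltol))
    if (fit2$value < fit$value) fit <- fit2
  }

  params <- .theta_to_params(fit$par, opt$d_par, opt$d_iso)
  structure(list(params = params, residual_norm = sqrt(fit$value),
                 converged = fit$convergence == 0, flag = "ok"),
            class = "noddi_fit")
}

# Orientation seed: DTI principal eigenvector when a b=1000 shell exists,
# otherwise the leading eigenvector of the attenuation-weighted dyadic sum.
.init_orientation <- function(s, scheme) {
  has_dti <- sum(abs(scheme$bvals - 1000) < 100) >= 6
  if (has_dti) {
    e1 <- tryCatch(fit_dti(s, scheme)$e1, error = function(e) NULL)
    if (!is.null(e1)) return(e1)
  }
  nz <- scheme$bvals > 0
  w <- pmax(1 - s[nz], 0)
  dyad <- crossprod(scheme$bvecs[nz, , drop = FALSE] * sqrt(w))
  eigen(dyad, symmetric = TRUE)$vectors[, 1]
}

#' @export
print.noddi_fit <- function(x, ...) {
  if (identical(x$flag, "bad_signal")) {
    cat("NODDI fit: flagged (bad signal), not fitted\n")
  } else {
    cat(sprintf("NODDI fit (residual %.3g, %s):\n", x$residual_norm,
                if (x$converged) "converged" else "not converged"))
    print(x$params)
  }
  invisible(x)
}

#' Fit NODDI voxel-wise over a masked volume
#'
#' @param signals matrix (n_voxels x n_volumes) of signals.
#' @param scheme an [acq_scheme()].
#' @param options passed to [fit_noddi()].
#' @return data.frame with one row per voxel: `f_iso`, `f_ic`, `f_ec`, `odi`,
#'   `kappa`, `mu_x`, `mu_y`, `mu_z`, `residual_norm`, `ok`.
#' @export
fit_noddi_map <- function(signals, scheme, options = list()) {
  signals <- as.matrix(signals)
  out <- lapply(seq_len(nrow(signals)), function(i) {
    f <- fit_noddi(signals[i, ], scheme, options)
    if (identical(f$flag, "bad_signal")) {
      data.frame(f_iso = NA_real_, f_ic = NA_real_, f_ec = NA_real_,
                 odi = NA_real_, kappa = NA_real_, mu_x = NA_real_,
                 mu_y = NA_real_, mu_z = NA_real_,
                 residual_norm = NA_real_, ok = FALSE)
    } else {
      p <- f$params
      data.frame(f_iso = p$f_iso, f_ic = p$f_ic, f_ec = p$f_ec,
                 odi = p$odi, kappa = p$kappa,
                 mu_x = p$mu[1], mu_y = p$mu[2], mu_z = p$mu[3],
                 residual_norm = f$residual_norm, ok = TRUE)
    }
  })
  do.call(rbind, out)
}
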