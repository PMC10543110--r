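#' Convert Watson concentration to orientation dispersion index
#'
#' The orientation dispersion index maps the Watson concentration parameter
#' \eqn{\kappa} to a bounded scale, \eqn{ODI = (2/\pi)\arctan(1/\kappa)}.
#' Large \eqn{\kappa} (tightly aligned neurites) gives ODI near 0; \eqn{\kappa
#' \to 0} (isotropic dispersion) gives ODI near 1.
#'
#' @param kappa positive Watson concentration parameter(s).
#' @return ODI value(s) in (0, 1).
#' @seealso [kappa_from_odi()]
#' @export
#' @examples
#' odi_from_kappa(1)   # 0.5
odi_from_kappa <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("`kappa` must be positive and finite")
  }
  (2 / pi) * atan(1 / kappa)
}

#' Convert orientation dispersion index to Watson concentration
#'
#' Exact inverse of [odi_from_kappa()]: \eqn{\kappa = 1/\tan(\pi\,ODI/2)}.
#'
#' @param odi dispersion index value(s) in (0, 1].
#' @return Watson concentration \eqn{\kappa} (non-negative; 0 when `odi == 1`).
#' @export
kappa_from_odi <- function(odi) {
  if (!is.numeric(odi) || any(!is.finite(odi)) || any(odi <= 0) || any(odi > 1)) {
    stop("`odi` must lie in (0, 1]")
  }
  1 / tan(pi * odi / 2)
}

# Cached Gauss-Legendre nodes (pracma) keyed by (n, a, b).
.hippmap_env <- new.env(parent = emptyenv())

.gauss_legendre <- function(n, a = -1, b = 1) {
  key <- paste0("gl_", n, "_", a, "_", b)
  got <- .hippmap_env[[key]]
  if (is.null(got)) {
    got <- pracma::gaussLegendre(n, a, b)
    .hippmap_env[[key]] <- got
  }
  got
}

# Exponentially scaled modified Bessel function e^{-x} I0(x), x >= 0.
# Abramowitz & Stegun 9.8.1 / 9.8.2 polynomial approximations (|rel err| <
# 2e-7), vectorized; ~7x faster than besselI(expon.scaled = TRUE) and well
# inside the accuracy needed by the Watson quadrature.
.i0_scaled <- function(x) {
  out <- x                                # keep dim attributes
  small <- x <= 3.75
  if (any(small)) {
    t2 <- (x[small] / 3.75)^2
    p <- 1 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
         t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))))
    out[small] <- p * exp(-x[small])
  }
  if (any(!small)) {
    xt <- x[!small]
    t1 <- 3.75 / xt
    p <- 0.39894228 + t1 * (0.01328592 + t1 * (0.00225319 + t1 * (-0.00157565 +
         t1 * (0.00916281 + t1 * (-0.02057706 + t1 * (0.02635537 +
         t1 * (-0.01647633 + t1 * 0.00392377)))))))
    out[!small] <- p / sqrt(xt)
  }
  out
}

# Sphere integral I(a, b, 0) = \int_{S^2} exp(a n1^2 + b n2^2) dOmega, scaled
# by exp(-scale), reduced to a 1D integral over the zero-eigenvalue axis:
#   I = 2*pi * int_{-1}^{1} exp(((a+b)/2)(1-u^2)) I0(((a-b)/2)(1-u^2)) du.
# Combining the exponential with the scaled Bessel gives exponent
# max(a,b)*(1-u^2) - scale, which is <= 0 whenever scale >= max(a, b), so the
# computation never overflows. `a` and `b` may be vectors (one integral each).
.sphere_exp_integral <- function(a, b, scale, n_gl = 64, gl = NULL) {
  if (is.null(gl)) gl <- .gauss_legendre(n_gl)
  s2 <- 1 - gl$x^2                       # (1 - u^2) at the nodes
  hi <- pmax(a, b)
  half_diff <- abs(a - b) / 2
  # rows: integrals, cols: nodes
  expo <- outer(hi, s2) - scale
  bess <- .i0_scaled(outer(half_diff, s2))
  2 * pi * as.vector((exp(expo) * bess) %*% gl$w)
}

# Watson-weighted attenuation of an axially symmetric exponential kernel:
#   A(kappa, q, ct) = E_W[ exp(-q (g.n)^2) ],  n ~ Watson(mu, kappa),
# with ct = cos(angle between g and mu) and q = b * d >= 0. The exponent
# kappa (mu.n)^2 - q (g.n)^2 is a rank-2 quadratic form whose in-plane 2x2
# block has trace kappa - q and determinant -kappa*q*(1-ct^2); its eigenvalues
# feed the 1D sphere-integral reduction above. Vectorized over (q, ct).
.watson_kernel_attenuation <- function(kappa, q, ct, n_gl = 64, gl = NULL) {
  stopifnot(length(q) == length(ct))
  tr <- kappa - q
  disc <- sqrt(pmax(tr^2 + 4 * kappa * q * (1 - ct^2), 0))
  # last row carries the normalizing integral I(kappa, 0, 0): sharing one
  # quadrature for numerator and denominator also cancels quadrature error
  l1 <- c((tr + disc) / 2, kappa)
  l2 <- c((tr - disc) / 2, 0)
  v <- .sphere_exp_integral(l1, l2, scale = kappa, n_gl = n_gl, gl = gl)
  n <- length(q)
  pmin(v[seq_len(n)] / v[n + 1L], 1)
}

# First orientation moment of the Watson distribution along mu:
#   tau1 = E[(mu.n)^2] = int_0^1 t^2 e^{kappa t^2} dt / int_0^1 e^{kappa t^2} dt.
# tau1 -> 1/3 as kappa -> 0 and -> 1 as kappa -> Inf.
.watson_tau1 <- function(kappa, n_gl = 64, gl = NULL) {
  if (is.null(gl)) gl <- .gauss_legendre(n_gl, 0, 1)
  e <- exp(kappa * (gl$x^2 - 1))         # scaled by exp(-kappa)
  sum(gl$w * gl$x^2 * e) / sum(gl$w * e)
}
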