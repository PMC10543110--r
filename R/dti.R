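#' Fit the diffusion tensor on the b = 1000 shell
#'
#' Ordinary (unweighted) log-linear least squares for the six unique tensor
#' elements plus \eqn{\ln S_0}, using only the b = 0 and b = 1000 s/mm^2
#' volumes, the typical single-shell DTI regime. Eigenvalues are sorted
#' descending; negative eigenvalues are clamped to zero and the voxel
#' flagged. FA follows the standard definition
#' \deqn{FA = \sqrt{3/2}\,\frac{\|\lambda - \bar\lambda\|}{\|\lambda\|}}
#' and MD is the eigenvalue mean.
#'
#' @param signals numeric vector of signals (one per scheme volume).
#' @param scheme an [acq_scheme()] containing at least 6 unique directions at
#'   the target shell.
#' @param b_shell shell to use (default 1000 s/mm^2).
#' @param b_tol tolerance for shell membership.
#' @return a `dti_fit`: tensor `D` (3x3, mm^2/s), `lambda` (sorted
#'   eigenvalues), `FA`, `MD`, principal eigenvector `e1`, `S0`, and
#'   `clamped` flag.
#' @export
fit_dti <- function(signals, scheme, b_shell = 1000, b_tol = 50) {
  stopifnot(inherits(scheme, "acq_scheme"))
  sel0 <- scheme$bvals == 0
  sel1 <- abs(scheme$bvals - b_shell) <= b_tol & scheme$bvals > 0
  g <- scheme$bvecs[sel1, , drop = FALSE]
  if (nrow(unique(round(g, 6))) < 6) {
    stop("need at least 6 unique directions at b = ", b_shell)
  }
  s <- c(mean(signals[sel0]), signals[sel1])
  if (any(s <= 0)) stop("non-positive signals: cannot take log for DTI fit")
  b <- c(0, scheme$bvals[sel1])
  g <- rbind(c(0, 0, 0), g)
  # model: log S = log S0 - b g' D g
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  beta <- qr.solve(X, log(s))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE)
  lam <- ev$values
  clamped <- any(lam < 0)
  lam <- pmax(lam, 0)
  md <- mean(lam)
  denom <- sqrt(sum(lam^2))
  fa <- if (denom == 0) 0 else sqrt(1.5) * sqrt(sum((lam - md)^2)) / denom
  structure(list(D = D, lambda = lam, FA = fa, MD = md,
                 e1 = ev$vectors[, 1], S0 = exp(beta[1]), clamped = clamped),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("DTI fit: FA=%.3f MD=%.3g mm^2/s  lambda=(%.3g, %.3g, %.3g)%s\n",
              x$FA, x$MD, x$lambda[1], x$lambda[2], x$lambda[3],
              if (x$clamped) "  [negative eigenvalue clamped]" else ""))
  invisible(x)
}

#' Fit DTI voxel-wise over a signal matrix
#'
#' @param signals matrix (n_voxels x n_volumes).
#' @inheritParams fit_dti
#' @return data.frame with per-voxel `FA`, `MD`, `e1_x/y/z`, `clamped`, `ok`.
#' @export
fit_dti_map <- function(signals, scheme, b_shell = 1000, b_tol = 50) {
  signals <- as.matrix(signals)
  out <- lapply(seq_len(nrow(signals)), function(i) {
    si <- signals[i, ]
    if (any(!is.finite(si)) || all(si == 0)) {
      return(data.frame(FA = NA_real_, MD = NA_real_, e1_x = NA_real_,
                        e1_y = NA_real_, e1_z = NA_real_,
                        clamped = NA, ok = FALSE))
    }
    f <- fit_dti(si, scheme, b_shell, b_tol)
    data.frame(FA = f$FA, MD = f$MD, e1_x = f$e1[1], e1_y = f$e1[2],
               e1_z = f$e1[3], clamped = f$clamped, ok = TRUE)
  })
  do.call(rbind, out)
}
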