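#' Build a diffusion acquisition scheme
#'
#' Bundles b-values (s/mm^2) with unit gradient directions. Directions of
#' b = 0 entries are ignored (stored as zeros).
#'
#' @param bvals numeric vector of b-values in s/mm^2, all >= 0, at least one 0.
#' @param bvecs numeric matrix (n x 3) of gradient directions; rows with
#'   non-zero b must be unit-norm (renormalized if within 1e-3 of unit).
#' @return an object of class `acq_scheme`.
#' @export
acq_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3) {
    stop("`bvecs` must be a length(bvals) x 3 matrix")
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) stop("b-values must be finite and >= 0")
  if (!any(bvals == 0)) stop("scheme must contain at least one b = 0 volume")
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[nz] - 1) > 1e-3)) stop("non-zero-b directions must be unit vectors")
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  bvecs[!nz, ] <- 0
  dimnames(bvecs) <- NULL
  structure(list(bvals = bvals, bvecs = bvecs), class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  shells <- table(round(x$bvals))
  cat("Acquisition scheme:", length(x$bvals), "volumes\n")
  cat("  shells (b : n):", paste(names(shells), unname(shells), sep = " : ", collapse = ", "), "\n")
  invisible(x)
}

#' Multi-shell scheme with evenly spread directions
#'
#' Convenience generator for a scheme resembling a multi-shell
#' acquisition: `n_b0` b = 0 volumes followed by `n_dir` directions (a
#' deterministic Fibonacci-sphere spread) repeated on each shell.
#'
#' @param bvals_shell non-zero shell b-values (s/mm^2); default
#'   `c(1000, 2000, 3000)`.
#' @param n_dir number of diffusion-encoding directions per shell.
#' @param n_b0 number of b = 0 volumes.
#' @return an `acq_scheme`.
#' @export
make_scheme <- function(bvals_shell = c(1000, 2000, 3000), n_dir = 90, n_b0 = 18) {
  dirs <- fibonacci_hemisphere(n_dir)
  bvals <- c(rep(0, n_b0), rep(bvals_shell, each = n_dir))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs[rep(seq_len(n_dir), times = length(bvals_shell)), ])
  acq_scheme(bvals, bvecs)
}

#' Deterministic near-uniform directions on the upper hemisphere
#'
#' Fibonacci-lattice points mapped to the z >= 0 hemisphere; antipodally a
#' near-uniform sampling of orientation space.
#'
#' @param n number of directions.
#' @return an n x 3 matrix of unit vectors.
#' @export
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - i / n                         # (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  unname(cbind(r * cos(phi), r * sin(phi), z))
}

# Full-sphere Fibonacci lattice with equal quadrature weights (oracle use).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read / write FSL-style gradient tables
#'
#' `write_bvals_bvecs()` writes `<prefix>.bval` / `<prefix>.bvec` (directions
#' as three rows); `read_scheme()` reads the pair back into an [acq_scheme()].
#'
#' @param scheme an `acq_scheme`.
#' @param prefix file path prefix (without extension).
#' @return `read_scheme()` returns an `acq_scheme`; the writer returns the
#'   prefix invisibly.
#' @export
write_bvals_bvecs <- function(scheme, prefix) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_bvals_bvecs
#' @export
read_scheme <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- t(as.matrix(utils::read.table(paste0(prefix, ".bvec"))))
  acq_scheme(bvals, bvecs)
}
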