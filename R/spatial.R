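#' Spearman rank correlation between two unfolded maps
#'
#' Rank correlation with average ranks for ties; vertices missing in either
#' map are pairwise-deleted. A constant map makes the correlation undefined:
#' `NA` is returned with a warning.
#'
#' @param map_a,map_b [unfolded_map()]s or numeric vectors on the same
#'   vertex set.
#' @return Spearman's rho in \[-1, 1\], or NA when undefined.
#' @export
spearman_rho <- function(map_a, map_b) {
  a <- map_values(map_a); b <- map_values(map_b)
  if (length(a) != length(b)) stop("maps have different vertex counts")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing values")
  ra <- rank(a[ok]); rb <- rank(b[ok])
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    warning("constant map: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(ra, rb)
}

#' Torus transform group permutations of the unfolded grid
#'
#' Spatial-autocorrelation-preserving permutations of a rows x cols vertex
#' grid under periodic boundary conditions: each permutation is a cyclic 2D
#' shift by a uniformly random offset, optionally composed with a 180-degree
#' rotation (fair coin) — the isometries of the rectangular torus that
#' preserve neighbour structure. The identity transform is excluded and
#' resampled. Deterministic given the seed.
#'
#' @param grid_shape integer pair (rows, cols).
#' @param n_perm number of permutations; must not exceed the number of
#'   distinct non-identity transforms (`2 * rows * cols - 1`).
#' @param seed integer seed.
#' @param rotations include the 180-degree rotation coin flip (default TRUE).
#' @return integer matrix (V x n_perm); column p holds indices such that
#'   `map[perm[, p]]` is the transformed map.
#' @export
torus_permutations <- function(grid_shape, n_perm, seed = 1L, rotations = TRUE) {
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  n_distinct <- rows * cols * (if (rotations) 2L else 1L) - 1L
  if (n_perm > n_distinct) {
    stop("n_perm exceeds the ", n_distinct, " distinct non-identity transforms")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(0L, rows * cols, n_perm)
  for (p in seq_len(n_perm)) {
    repeat {
      dr <- sample.int(rows, 1) - 1L
      dc <- sample.int(cols, 1) - 1L
      rot <- if (rotations) stats::runif(1) < 0.5 else FALSE
      if (dr != 0L || dc != 0L || rot) break
    }
    out[, p] <- torus_transform(grid_shape, dr, dc, rot)
  }
  out
}

#' Single torus transform of the unfolded grid
#'
#' Index vector of one element of the spin-test transform group: cyclic
#' shift by (`dr`, `dc`) with optional 180-degree rotation applied first.
#'
#' @param grid_shape integer pair (rows, cols).
#' @param dr,dc non-negative integer shifts along rows / columns.
#' @param rotate apply the 180-degree rotation.
#' @return integer vector of length `prod(grid_shape)`: `map[idx]` is the
#'   transformed map.
#' @export
torus_transform <- function(grid_shape, dr = 0L, dc = 0L, rotate = FALSE) {
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  r <- rep(seq_len(rows), cols)
  c <- rep(seq_len(cols), each = rows)
  if (rotate) { r <- rows + 1L - r; c <- cols + 1L - c }
  r <- ((r - 1L - as.integer(dr)) %% rows) + 1L
  c <- ((c - 1L - as.integer(dc)) %% cols) + 1L
  (c - 1L) * rows + r
}

#' Torus spin test for the correlation of two unfolded maps
#'
#' Tests the Spearman correlation between two maps against a null that
#' preserves each map's spatial autocorrelation: map A is rearranged by
#' random torus transforms ([torus_permutations()]) while map B stays fixed,
#' and the two-sided p-value is
#' \eqn{p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(1 + n_{perm})}.
#'
#' @param map_a,map_b [unfolded_map()]s on the same grid (map_a is the one
#'   permuted).
#' @param n_perm number of permutations (default 2500).
#' @param seed integer seed.
#' @param grid_shape required when the maps are bare numeric vectors.
#' @return a `spin_test` result: `rho_observed`, `null_rhos`, `p_value`,
#'   `n_perm`.
#' @export
spin_test <- function(map_a, map_b, n_perm = 2500, seed = 1L,
                      grid_shape = NULL) {
  if (is.null(grid_shape)) {
    if (!inherits(map_a, "unfolded_map")) stop("`grid_shape` required for bare vectors")
    grid_shape <- map_a$grid_shape
  }
  a <- map_values(map_a); b <- map_values(map_b)
  obs <- spearman_rho(a, b)
  perms <- torus_permutations(grid_shape, n_perm, seed = seed)
  if (anyNA(a) || anyNA(b)) {
    null_rhos <- vapply(seq_len(n_perm), function(p) {
      suppressWarnings(spearman_rho(a[perms[, p]], b))
    }, numeric(1))
  } else {
    # ranks of a permuted map are the permuted ranks: one ranking suffices
    ra <- rank(a); rb <- rank(b)
    za <- (ra - mean(ra)) / stats::sd(ra)
    zb <- (rb - mean(rb)) / stats::sd(rb)
    null_rhos <- as.vector(crossprod(matrix(za[perms], nrow(perms)), zb)) /
      (length(a) - 1)
  }
  p <- (1 + sum(abs(null_rhos) >= abs(obs), na.rm = TRUE)) / (1 + n_perm)
  structure(list(rho_observed = obs, null_rhos = null_rhos, p_value = p,
                 n_perm = as.integer(n_perm)),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("Torus spin test: rho = %.3f, p = %.4g (%d permutations)\n",
              x$rho_observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up adjusted q-values with monotonicity enforcement.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @param alpha FDR level for the rejection flags.
#' @return list with `q_values` and logical `rejected`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' Correlation matrix report across a set of averaged maps
#'
#' Computes the Spearman correlation for every unordered pair of maps, a
#' torus spin-test p-value per pair, and Benjamini-Hochberg q-values across
#' all pairs jointly. Each pair's permutation seed is derived from the
#' alphabetically sorted pair of metric names, so the report is invariant to
#' the input order.
#'
#' @param maps named list of [unfolded_map()]s on the same grid (names
#'   default to each map's `metric`).
#' @param n_perm permutations per pair (default 2500).
#' @param seed root seed.
#' @param spin if FALSE, skip the spin test: p/q columns are NA.
#' @return a `correlation_report`: data.frame `pairs` (metric_a, metric_b,
#'   rho, p, q, rejected) plus square matrices `rho_matrix` and `q_matrix`.
#' @export
all_pairs_report <- function(maps, n_perm = 2500, seed = 1L, spin = TRUE) {
  if (length(maps) < 2) stop("need at least 2 maps")
  nm <- names(maps)
  if (is.null(nm)) nm <- vapply(maps, function(m) m$metric, character(1))
  if (anyDuplicated(nm)) stop("map names must be unique")
  names(maps) <- nm
  cmb <- utils::combn(sort(nm), 2)
  res <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    pair_seed <- (seed + sum(utf8ToInt(paste(a, b))) * 1009L) %% .Machine$integer.max
    if (spin) {
      st <- spin_test(maps[[a]], maps[[b]], n_perm = n_perm, seed = pair_seed)
      data.frame(metric_a = a, metric_b = b, rho = st$rho_observed,
                 p = st$p_value, stringsAsFactors = FALSE)
    } else {
      data.frame(metric_a = a, metric_b = b,
                 rho = suppressWarnings(spearman_rho(maps[[a]], maps[[b]])),
                 p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, res)
  if (spin) {
    bh <- fdr_bh(pairs$p)
    pairs$q <- bh$q_values
    pairs$rejected <- bh$rejected
  } else {
    pairs$q <- NA_real_
    pairs$rejected <- NA
  }
  k <- length(nm)
  rho_m <- q_m <- matrix(NA_real_, k, k, dimnames = list(sort(nm), sort(nm)))
  diag(rho_m) <- 1
  for (i in seq_len(nrow(pairs))) {
    rho_m[pairs$metric_a[i], pairs$metric_b[i]] <- pairs$rho[i]
    rho_m[pairs$metric_b[i], pairs$metric_a[i]] <- pairs$rho[i]
    q_m[pairs$metric_a[i], pairs$metric_b[i]] <- pairs$q[i]
    q_m[pairs$metric_b[i], pairs$metric_a[i]] <- pairs$q[i]
  }
  structure(list(pairs = pairs, rho_matrix = rho_m, q_matrix = q_m,
                 n_perm = if (spin) as.integer(n_perm) else NA_integer_),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report:", nrow(x$pairs), "map pairs",
      if (!is.na(x$n_perm)) sprintf("(spin test, %d permutations)", x$n_perm)
      else "(spin test skipped)", "\n")
  print(utils::head(x$pairs, 10))
  if (nrow(x$pairs) > 10) cat("...\n")
  invisible(x)
}

# Lag-1 Moran-type spatial statistic with periodic neighbours (used by the
# property tests: torus transforms must leave it unchanged).
torus_moran <- function(values, grid_shape) {
  m <- matrix(map_values(values), grid_shape[1], grid_shape[2])
  z <- m - mean(m)
  nb <- m[c(2:nrow(m), 1), ] + m[c(nrow(m), 1:(nrow(m) - 1)), ] +
    m[, c(2:ncol(m), 1)] + m[, c(ncol(m), 1:(ncol(m) - 1))]
  zc <- nb - 4 * mean(m)
  sum(z * zc) / (4 * sum(z^2))
}
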