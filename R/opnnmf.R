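#' Normalize a raw metric stack for OPNNMF
#'
#' Applies the two-step normalization used before factorizing the vertices x
#' subject-metrics matrix: each metric's values are z-scored within each
#' hemisphere (jointly across its vertices and subjects), and the whole
#' z-scored collection is then shifted by its global minimum so the matrix
#' is non-negative with minimum exactly 0.
#'
#' @param raw an `unfolded_dataset`, or a numeric matrix (vertices x
#'   columns) with `columns` metadata supplied.
#' @param columns data.frame with `metric` (and optionally `subject`,
#'   `hemisphere`) per column of the matrix; ignored when `raw` is an
#'   `unfolded_dataset`.
#' @param hemisphere single hemisphere tag when the metadata carries none.
#' @return a `metric_stack`: non-negative matrix `X` (vertices x
#'   subject-metrics), `columns` metadata, `shift` (the subtracted minimum
#'   per hemisphere), `grid_shape` when known.
#' @export
normalize_metrics <- function(raw, columns = NULL, hemisphere = "L") {
  if (inherits(raw, "unfolded_dataset")) {
    X <- raw$maps
    columns <- raw$columns
    if (is.null(columns$hemisphere)) columns$hemisphere <- raw$hemisphere
    grid_shape <- raw$grid_shape
  } else {
    X <- as.matrix(raw)
    if (is.null(columns)) stop("`columns` metadata required for a bare matrix")
    grid_shape <- attr(raw, "grid_shape")
  }
  if (is.null(columns$hemisphere)) columns$hemisphere <- hemisphere
  if (nrow(columns) != ncol(X)) stop("column metadata does not match the matrix")
  if (anyNA(X) || any(!is.finite(X))) stop("metric stack contains non-finite values")

  Z <- X
  shift <- c()
  for (h in unique(columns$hemisphere)) {
    hsel <- columns$hemisphere == h
    for (m in unique(columns$metric[hsel])) {
      sel <- hsel & columns$metric == m
      v <- X[, sel, drop = FALSE]
      s <- stats::sd(as.vector(v))
      if (!is.finite(s) || s == 0) stop("zero-variance metric: ", m)
      Z[, sel] <- (v - mean(v)) / s
    }
    mn <- min(Z[, hsel])
    Z[, hsel] <- Z[, hsel] - mn
    shift[h] <- mn
  }
  structure(list(X = Z, columns = columns, shift = shift,
                 grid_shape = grid_shape),
            class = "metric_stack")
}

#' @export
print.metric_stack <- function(x, ...) {
  cat(sprintf("Metric stack: %d vertices x %d subject-metrics (min %.3g, max %.3g)\n",
              nrow(x$X), ncol(x$X), min(x$X), max(x$X)))
  invisible(x)
}

.stack_matrix <- function(x) {
  if (inherits(x, "metric_stack")) x$X
  else if (inherits(x, "unfolded_dataset")) x$maps
  else as.matrix(x)
}

#' Non-negative double SVD initialization
#'
#' Deterministic non-negative initialization of the component matrix from
#' the rank-k truncated SVD: for each singular pair the positive and
#' negative parts are compared and the dominant side kept, scaled by the
#' singular value (the standard NNDSVD construction). No randomness; zero
#' entries are preserved.
#'
#' @param X non-negative matrix (vertices x columns).
#' @param k number of components, `k <= min(dim(X))`.
#' @return V x k non-negative matrix `C0`.
#' @export
nndsvd_init <- function(X, k) {
  X <- .stack_matrix(X)
  if (k > min(dim(X))) stop("k exceeds min(dim(X))")
  sv <- svd(X, nu = k, nv = k)
  C0 <- matrix(0, nrow(X), k)
  # leading pair of a non-negative matrix is sign-fixable to non-negative
  u1 <- sv$u[, 1]
  if (sum(u1) < 0) u1 <- -u1
  C0[, 1] <- sqrt(sv$d[1]) * pmax(u1, 0)
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        if (nup > 0) C0[, j] <- sqrt(sv$d[j] * nup * nvp) * up / nup
      } else {
        if (nun > 0) C0[, j] <- sqrt(sv$d[j] * nun * nvn) * un / nun
      }
    }
  }
  C0
}

#' Orthogonal projective NMF
#'
#' Factorizes a non-negative vertices x subject-metrics matrix as
#' \eqn{X \approx C C^T X} by minimizing the squared Frobenius norm
#' \eqn{\|X - CC^TX\|^2} subject to \eqn{C \ge 0} and (softly)
#' \eqn{C^TC = I}, using the multiplicative update
#' \deqn{C \leftarrow C \odot (XX^TC) \oslash (C\,C^TXX^TC)}
#' from NNDSVD initialization. Iteration stops when the relative change of
#' the objective falls below `tol` or at `max_iter`. At exit the columns of
#' `C` are rescaled to unit norm, `W = C^TX`, and each vertex receives a
#' winner-take-all label.
#'
#' @param X non-negative matrix, [normalize_metrics()] stack, or
#'   `unfolded_dataset`.
#' @param k number of components.
#' @param max_iter iteration cap (default 10000).
#' @param tol relative-objective-change tolerance (default 1e-5).
#' @param eps denominator floor guarding against division by zero; the
#'   initial C is also floored at `eps` so the multiplicative update is not
#'   frozen at exact zeros.
#' @param init optional V x k non-negative starting matrix (defaults to
#'   [nndsvd_init()]).
#' @return an `opnnmf_fit`: `C` (V x k, unit-norm columns), `W` (k x
#'   columns), `labels`, `objective` trace, `recon_error`
#'   (\eqn{\|X-CC^TX\|_F}), `orth_error` (\eqn{\|C^TC - I\|_F}), `iterations`,
#'   `converged`.
#' @export
opnnmf_fit <- function(X, k, max_iter = 10000L, tol = 1e-5, eps = 1e-12,
                       init = NULL) {
  Xm <- .stack_matrix(X)
  if (any(Xm < 0)) stop("X must be non-negative")
  if (any(!is.finite(Xm))) stop("X contains non-finite values")
  C <- if (is.null(init)) nndsvd_init(Xm, k) else as.matrix(init)
  if (ncol(C) != k || nrow(C) != nrow(Xm)) stop("bad init dimensions")
  C <- pmax(C, eps)

  XXt <- tcrossprod(Xm)                   # V x V
  x2 <- sum(Xm^2)
  objective <- numeric(0)
  obj_of <- function(C) {
    XXtC <- XXt %*% C
    x2 - 2 * sum(C * XXtC) + sum(crossprod(C) * crossprod(C, XXtC))
  }
  prev <- obj_of(C)
  objective <- prev
  converged <- FALSE
  it <- 0L
  reseeded <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    XXtC <- XXt %*% C
    denom <- C %*% crossprod(C, XXtC)
    C <- C * XXtC / pmax(denom, eps)
    if (any(!is.finite(C))) stop("non-finite values during OPNNMF iteration ", it)
    # keep the iterate on a stable scale: without this the update's overall
    # scale oscillates; the spectral normalization leaves the fixed-point
    # direction unchanged
    C <- pmax(C, eps)
    C <- C / norm(C, "2")
    cur <- obj_of(C)
    objective <- c(objective, cur)
    if (abs(prev - cur) <= tol * abs(prev)) {
      # dead-component guard: re-seed an all-zero column once from the
      # vertex with the largest residual, then continue
      dead <- colSums(C) <= k * eps * nrow(C)
      if (any(dead) && !reseeded) {
        resid <- rowSums((Xm - C %*% crossprod(C, Xm))^2)
        for (j in which(dead)) {
          C[, j] <- eps
          C[which.max(resid), j] <- 1
        }
        reseeded <- TRUE
        prev <- obj_of(C)
        next
      }
      converged <- TRUE
      break
    }
    prev <- cur
  }
  # recon_error is the converged objective: the update drives C toward an
  # orthonormal fixed point, where this coincides with ||X - CC'X||_F of the
  # returned unit-column C; when iteration stops short of orthonormality the
  # objective value is the faithful error of the fitted projection
  recon <- sqrt(max(objective[length(objective)], 0))
  labels <- winner_take_all(C)
  nrm <- sqrt(colSums(C^2))
  nrm[nrm == 0] <- 1
  C <- sweep(C, 2, nrm, "/")
  W <- crossprod(C, Xm)
  structure(list(C = C, W = W, k = as.integer(k),
                 labels = labels,
                 objective = objective,
                 recon_error = recon,
                 orth_error = norm(crossprod(C) - diag(k), "F"),
                 iterations = it, converged = converged),
            class = "opnnmf_fit")
}

#' @export
print.opnnmf_fit <- function(x, ...) {
  cat(sprintf("OPNNMF fit: k = %d, %d iterations (%s), recon error %.4g, ||C'C - I|| = %.3g\n",
              x$k, x$iterations, if (x$converged) "converged" else "max_iter reached",
              x$recon_error, x$orth_error))
  invisible(x)
}

#' Winner-take-all vertex labels from a component matrix
#'
#' Each vertex gets the index of its largest component weight; exact ties go
#' to the lowest component index. All-zero rows get a missing label.
#'
#' @param C V x k non-negative component matrix.
#' @return integer vector of labels in 1..k (NA for all-zero rows).
#' @export
winner_take_all <- function(C) {
  C <- as.matrix(C)
  if (!nrow(C) || !ncol(C)) stop("empty component matrix")
  lab <- max.col(C, ties.method = "first")
  lab[rowSums(C != 0) == 0] <- NA_integer_
  lab
}

#' Row-wise z-scoring of the OPNNMF weight matrix
#'
#' @param W k x columns weight matrix; every row must have positive SD.
#' @return matrix of the same shape with each row standardized.
#' @export
zscore_weights <- function(W) {
  W <- as.matrix(W)
  s <- apply(W, 1, stats::sd)
  if (any(!is.finite(s)) || any(s == 0)) stop("constant weight row: cannot z-score")
  (W - rowMeans(W)) / s
}

#' OPNNMF reconstruction error and its gradient over k
#'
#' `reconstruction_error()` is the Frobenius norm \eqn{\|X - CC^TX\|_F};
#' `error_gradient()` differences a vector of errors across a k-sweep.
#'
#' @param X data matrix (or stack).
#' @param C component matrix.
#' @return scalar error / vector of consecutive differences.
#' @export
reconstruction_error <- function(X, C) {
  Xm <- .stack_matrix(X)
  C <- as.matrix(C)
  norm(Xm - C %*% crossprod(C, Xm), "F")
}

#' @param errors numeric vector of reconstruction errors ordered by k.
#' @rdname reconstruction_error
#' @export
error_gradient <- function(errors) diff(errors)

#' Split-half stability coefficient between two component matrices
#'
#' The similarity structure of a decomposition is the V x V cosine matrix
#' \eqn{S = \hat C \hat C^T} with row-normalized \eqn{\hat C}; stability
#' between two halves is the Pearson correlation between matched rows of
#' their similarity matrices (1 = perfect correspondence of vertex
#' relationships, -1 = instability).
#'
#' @param C1,C2 V x k component matrices from the two data halves.
#' @return list with `mean`, `sd` and the `per_vertex` correlation vector.
#' @export
stability_coefficient <- function(C1, C2) {
  r <- .stability_rows(as.matrix(C1), as.matrix(C2))
  list(mean = mean(r, na.rm = TRUE), sd = stats::sd(r, na.rm = TRUE),
       per_vertex = r)
}

.row_normalize <- function(C) {
  n <- sqrt(rowSums(C^2))
  n[n == 0] <- 1
  C / n
}

.stability_rows <- function(C1, C2) {
  if (nrow(C1) != nrow(C2)) stop("component matrices have different vertex counts")
  S1 <- tcrossprod(.row_normalize(C1))
  S2 <- tcrossprod(.row_normalize(C2))
  z <- function(S) {
    mu <- rowMeans(S)
    sd <- sqrt(rowSums((S - mu)^2))
    (S - mu) / ifelse(sd == 0, 1, sd)
  }
  rowSums(z(S1) * z(S2))
}

#' Split-half stability and reconstruction-error analysis over k
#'
#' For each k in `k_range` and each of `n_splits` random subject splits,
#' subjects are divided into two equal halves (both hemispheres and all
#' metrics of a subject travel together; the remainder of an odd count is
#' dropped with a warning), OPNNMF is fitted to each half's columns, and
#' the [stability_coefficient()] between the halves is recorded. The
#' reconstruction error of the full-stack fit and its gradient across k are
#' reported alongside.
#'
#' @param stack a [normalize_metrics()] `metric_stack` (or
#'   `unfolded_dataset`), with subject metadata.
#' @param k_range integer vector of component counts (default 2:12).
#' @param n_splits number of random splits (default 6).
#' @param seed integer seed for the splits.
#' @param max_iter,tol passed to [opnnmf_fit()].
#' @return a `stability_report` data.frame: per k the mean and SD of the
#'   stability coefficient (across vertices and splits), the full-data
#'   reconstruction error, and its gradient.
#' @export
stability_analysis <- function(stack, k_range = 2:12, n_splits = 6, seed = 1L,
                               max_iter = 10000L, tol = 1e-5) {
  X <- .stack_matrix(stack)
  columns <- if (inherits(stack, "metric_stack")) stack$columns
             else if (inherits(stack, "unfolded_dataset")) stack$columns
             else stop("stack must carry subject metadata")
  subjects <- unique(columns$subject)
  if (length(subjects) < 4) stop("need at least 4 subjects to split")
  half <- length(subjects) %/% 2
  if (length(subjects) %% 2 == 1) {
    warning("odd subject count: one subject dropped from each split")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) {
    perm <- sample(subjects)
    list(a = perm[seq_len(half)], b = perm[half + seq_len(half)])
  })
  rows <- lapply(k_range, function(k) {
    stab <- unlist(lapply(splits, function(sp) {
      Ca <- opnnmf_fit(X[, columns$subject %in% sp$a, drop = FALSE], k,
                       max_iter = max_iter, tol = tol)$C
      Cb <- opnnmf_fit(X[, columns$subject %in% sp$b, drop = FALSE], k,
                       max_iter = max_iter, tol = tol)$C
      .stability_rows(Ca, Cb)
    }))
    full <- opnnmf_fit(X, k, max_iter = max_iter, tol = tol)
    data.frame(k = k, stability_mean = mean(stab, na.rm = TRUE),
               stability_sd = stats::sd(stab, na.rm = TRUE),
               recon_error = full$recon_error)
  })
  out <- do.call(rbind, rows)
  out$error_gradient <- c(NA, error_gradient(out$recon_error))
  attr(out, "n_splits") <- as.integer(n_splits)
  class(out) <- c("stability_report", "data.frame")
  out
}

#' Greedy cross-decomposition component matching
#'
#' Reorders the components of `fit_b` to maximize spatial overlap with
#' `fit_a` (greedy maximal overlap of winner-take-all labels) — cosmetic
#' alignment for comparing decompositions across hemispheres.
#'
#' @param fit_a,fit_b `opnnmf_fit` objects with equal k and vertex counts.
#' @return `fit_b` with columns of `C`, rows of `W` and labels reordered.
#' @export
match_components <- function(fit_a, fit_b) {
  stopifnot(fit_a$k == fit_b$k)
  k <- fit_a$k
  overlap <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- sum(fit_a$labels == i & fit_b$labels == j, na.rm = TRUE)
  }
  ord <- integer(k)
  used <- logical(k)
  for (i in order(-apply(overlap, 1, max))) {
    j <- order(-overlap[i, ])
    j <- j[!used[j]][1]
    ord[i] <- j
    used[j] <- TRUE
  }
  fit_b$C <- fit_b$C[, ord, drop = FALSE]
  fit_b$W <- fit_b$W[ord, , drop = FALSE]
  fit_b$labels <- match(fit_b$labels, ord)
  fit_b
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same vertex set
#' (1 = identical up to relabeling, ~0 = chance).
#'
#' @param a,b integer/factor label vectors of equal length (NA pairs
#'   dropped).
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  tab <- table(a[ok], b[ok])
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
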