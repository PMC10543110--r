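planted_stack <- function(effect = 10, seed = 3, n_subjects = 8) {
  ds <- make_unfolded_dataset(grid_shape = c(32, 16), n_subjects = n_subjects,
                              true_rank = 4, effect_size = effect, seed = seed)
  list(ds = ds, stack = normalize_metrics(ds))
}

test_that("metric normalization z-scores per metric and shifts to a zero minimum", {
  ds <- make_unfolded_dataset(c(16, 8), 5, 3, seed = 2)
  st <- normalize_metrics(ds)
  expect_equal(min(st$X), 0)
  expect_true(all(st$X >= 0))
  # undo the shift: each metric group must be a z-scored distribution
  Z <- st$X + st$shift[["L"]]
  for (m in unique(st$columns$metric)) {
    v <- Z[, st$columns$metric == m]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(as.vector(v)) - 1), 1e-9)
  }
  # affine rescaling of one raw metric leaves its normalized values unchanged
  ds2 <- ds
  sel <- ds2$columns$metric == ds2$metric_names[1]
  ds2$maps[, sel] <- 5 * ds2$maps[, sel] - 2
  st2 <- normalize_metrics(ds2)
  expect_equal(st2$X + st2$shift[["L"]], Z, tolerance = 1e-9)

  ds3 <- ds
  ds3$maps[, sel] <- 1
  expect_error(normalize_metrics(ds3), "zero-variance")
})

test_that("NNDSVD initialization is non-negative, deterministic, and exact at rank 1", {
  u <- abs(stats::rnorm(20)); v <- abs(stats::rnorm(7))
  X1 <- 3 * u %o% v
  C0 <- nndsvd_init(X1, 1)
  expect_true(all(C0 >= 0))
  cs <- C0[, 1] / u
  expect_lt(stats::sd(cs) / mean(cs), 1e-9)

  set.seed(4)
  X <- matrix(stats::runif(30 * 10), 30, 10)
  expect_identical(nndsvd_init(X, 4), nndsvd_init(X, 4))
  expect_true(all(nndsvd_init(X, 4) >= 0))
  expect_error(nndsvd_init(X, 11), "min")
})

test_that("OPNNMF recovers planted parcels with a non-increasing objective", {
  ps <- planted_stack()
  fit <- opnnmf_fit(ps$stack, 4)
  expect_lt(fit$recon_error / norm(ps$stack$X, "F"), 0.05)
  expect_gt(adjusted_rand_index(fit$labels, ps$ds$true_parcels), 0.9)
  expect_true(all(fit$C >= 0))

  # monotone objective on unit-norm random fixtures (objective is O(1))
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(stats::runif(40 * 12), 40, 12)
    X <- X / norm(X, "F")
    f <- opnnmf_fit(X, 3)
    expect_true(all(diff(f$objective) <= 1e-10))
  }
  expect_error(opnnmf_fit(matrix(c(-1, 1, 1, 1), 2), 1), "non-negative")
})

test_that("scaling the input leaves the fitted components unchanged", {
  ps <- planted_stack(seed = 6)
  f1 <- opnnmf_fit(ps$stack$X, 3)
  f2 <- opnnmf_fit(5 * ps$stack$X, 3)
  expect_lt(max(abs(f1$C - f2$C)), 1e-6)
  expect_identical(f1$labels, f2$labels)
})

test_that("winner-take-all labels follow the documented argmax and tie rules", {
  C <- rbind(c(0, 1, 0), c(0, 0, 1), c(0.2, 0.2, 0.1), c(0, 0, 0))
  lab <- winner_take_all(C)
  expect_identical(lab[1:3], c(2L, 3L, 1L))
  expect_true(is.na(lab[4]))
})

test_that("weight z-scoring standardizes rows and flags planted loadings", {
  ps <- planted_stack(seed = 8)
  fit <- opnnmf_fit(ps$stack, 4)
  Wz <- zscore_weights(fit$W)
  expect_lt(max(abs(rowMeans(Wz))), 1e-9)
  expect_lt(max(abs(apply(Wz, 1, stats::sd) - 1)), 1e-9)
  expect_error(zscore_weights(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")

  # a column loading strongly on one planted parcel gets positive z-scores
  # in the matching component row
  ds <- ps$ds
  boost <- which(ds$true_parcels == 1)
  X <- ps$stack$X
  X[boost, 1] <- X[boost, 1] + 10
  f2 <- opnnmf_fit(X, 4)
  comp <- f2$labels[boost[1]]
  expect_gt(zscore_weights(f2$W)[comp, 1], 0)
})

test_that("reconstruction error matches brute force and its k-gradient differences", {
  set.seed(5)
  X <- matrix(stats::runif(20 * 15), 20, 15)
  Q <- qr.Q(qr(X))                     # orthonormal basis of the column space
  expect_lt(reconstruction_error(X, Q), 1e-10)
  expect_equal(reconstruction_error(X, matrix(0, 20, 2)), norm(X, "F"))
  C <- abs(matrix(stats::rnorm(20 * 3), 20, 3))
  brute <- sqrt(sum((X - C %*% (t(C) %*% X))^2))
  expect_equal(reconstruction_error(X, C), brute, tolerance = 1e-12)
  expect_equal(error_gradient(c(10, 7, 6)), c(-3, -1))
})

test_that("reconstruction error decreases across the component sweep", {
  ps <- planted_stack(effect = 1, seed = 3)
  errs <- vapply(2:12, function(k) opnnmf_fit(ps$stack, k)$recon_error,
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("stability coefficient is one for identical splits and permutation-invariant", {
  ps <- planted_stack(seed = 10)
  C <- opnnmf_fit(ps$stack, 4)$C
  sc <- stability_coefficient(C, C)
  expect_equal(sc$mean, 1, tolerance = 1e-9)
  # permuting components leaves the similarity structure unchanged
  sc_perm <- stability_coefficient(C, C[, c(3, 1, 4, 2)])
  expect_equal(sc_perm$mean, 1, tolerance = 1e-9)
})

test_that("split-half stability separates planted structure from noise", {
  ps <- planted_stack(effect = 10, seed = 12)
  rep_s <- stability_analysis(ps$stack, k_range = c(4, 8), n_splits = 2,
                              seed = 1, max_iter = 3000)
  expect_gt(rep_s$stability_mean[rep_s$k == 4],
            rep_s$stability_mean[rep_s$k == 8])
  expect_gt(rep_s$stability_mean[rep_s$k == 4], 0.5)

  noise <- make_unfolded_dataset(c(32, 16), 8, 4, effect_size = 0, seed = 13)
  rep_n <- stability_analysis(normalize_metrics(noise), k_range = c(4, 8),
                              n_splits = 2, seed = 1, max_iter = 3000)
  expect_true(all(rep_n$stability_mean < 0.5))
  expect_true(all(rep_n$stability_mean < rep_s$stability_mean))

  odd <- make_unfolded_dataset(c(8, 8), n_subjects = 5, true_rank = 2, seed = 1)
  expect_warning(stability_analysis(normalize_metrics(odd), k_range = 2,
                                    n_splits = 1, max_iter = 200),
                 "odd subject count")
})
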