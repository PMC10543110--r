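test_that("Spearman correlation matches hand computation and handles degeneracy", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 5)
  # brute force: 1 - 6*sum(d^2)/(n(n^2-1)) on the (tie-free) ranks
  d2 <- sum((rank(a) - rank(b))^2)
  expect_equal(spearman_rho(a, b), 1 - 6 * d2 / (5 * 24))
  expect_equal(spearman_rho(a, a), 1)
  expect_equal(spearman_rho(a, -a^3), -1)
  expect_warning(out <- spearman_rho(a, rep(2, 5)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(c(1, 2, NA, NA, NA), c(1, NA, 2, 3, 4)), "at least 3")
})

test_that("torus transforms are bijections forming the expected group", {
  gs <- c(8, 6)
  perms <- torus_permutations(gs, 40, seed = 1)
  for (p in seq_len(ncol(perms))) {
    expect_identical(sort(perms[, p]), seq_len(48L))
  }
  # half-period shift composed with itself is the identity
  half <- torus_transform(gs, dr = 0, dc = 3)
  expect_identical(half[half], seq_len(48L))
  rot <- torus_transform(gs, rotate = TRUE)
  expect_identical(rot[rot], seq_len(48L))
  expect_error(torus_permutations(c(4, 4), 1000), "distinct")
})

test_that("torus transforms preserve periodic spatial autocorrelation", {
  gs <- c(16, 12)
  m <- smooth_grid_noise(gs, smoothness_mm = 2, seed = 8)[, 1]
  stat0 <- hippmap:::torus_moran(m, gs)
  perms <- torus_permutations(gs, 50, seed = 3)
  stats_perm <- apply(perms, 2, function(p) hippmap:::torus_moran(m[p], gs))
  expect_true(all(abs(stats_perm - stat0) < 1e-12))
})

test_that("spin test on a map against itself is maximally significant", {
  pr <- make_correlated_map_pair(c(16, 12), 0, seed = 5)
  st <- spin_test(pr$map_a, pr$map_a, n_perm = 199, seed = 7)
  expect_equal(st$rho_observed, 1)
  expect_equal(st$p_value, 1 / 200)
  expect_length(st$null_rhos, 199)
  # null distribution centred near zero for exchangeable smooth maps
  pr2 <- make_correlated_map_pair(c(32, 16), 0, seed = 6)
  st2 <- spin_test(pr2$map_a, pr2$map_b, n_perm = 500, seed = 8)
  expect_lt(abs(mean(st2$null_rhos)), 0.05)
})

test_that("null p-values are super-uniform (KS) under independent smooth maps", {
  ps <- vapply(1:400, function(i) {
    pr <- make_correlated_map_pair(c(16, 12), 0, seed = 5000 + i)
    spin_test(pr$map_a, pr$map_b, n_perm = 99, seed = 6000 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH correction equals hand-computed step-up values", {
  expect_equal(fdr_bh(0.03)$q_values, 0.03)
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q_values, rep(0.04, 4))
  expect_true(all(out$rejected))
  all1 <- fdr_bh(rep(1, 5))
  expect_true(all(all1$q_values == 1))
  expect_false(any(all1$rejected))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
})

test_that("the all-pairs report covers every pair and is order-invariant", {
  maps <- lapply(1:11, function(i) {
    unfolded_map(smooth_grid_noise(c(16, 12), 2, seed = 30 + i)[, 1],
                 c(16, 12), metric = paste0("m", sprintf("%02d", i)))
  })
  names(maps) <- vapply(maps, function(m) m$metric, character(1))
  rep1 <- all_pairs_report(maps, n_perm = 49, seed = 2)
  expect_equal(nrow(rep1$pairs), choose(11, 2))
  expect_true(all(rep1$pairs$q >= rep1$pairs$p))

  rep2 <- all_pairs_report(rev(maps), n_perm = 49, seed = 2)
  key <- function(r) paste(r$metric_a, r$metric_b)
  expect_equal(rep1$pairs$q[order(key(rep1$pairs))],
               rep2$pairs$q[order(key(rep2$pairs))])

  # a duplicated map shows up with rho = 1 and the smallest p
  maps_dup <- c(maps[1:3], list(dup = maps[[1]]))
  maps_dup$dup$metric <- "dup"
  rep3 <- all_pairs_report(maps_dup, n_perm = 49, seed = 2)
  dup_row <- rep3$pairs$metric_a == "dup" | rep3$pairs$metric_b == "dup"
  dup_row <- dup_row & (rep3$pairs$metric_a == "m01" | rep3$pairs$metric_b == "m01")
  expect_equal(rep3$pairs$rho[dup_row], 1)
  expect_equal(min(rep3$pairs$p), rep3$pairs$p[dup_row])
})

test_that("disabling the spin test leaves rho with empty p and q", {
  maps <- lapply(1:3, function(i) {
    unfolded_map(smooth_grid_noise(c(8, 8), 1, seed = i)[, 1], c(8, 8),
                 metric = paste0("m", i))
  })
  rep0 <- all_pairs_report(maps, spin = FALSE)
  expect_true(all(is.na(rep0$pairs$p)))
  expect_true(all(is.na(rep0$pairs$q)))
  expect_true(all(is.finite(rep0$pairs$rho)))
})
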