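test_that("simulated signals reproduce the forward model exactly when noiseless", {
  d <- make_voxel_domain(c(8, 8, 8), "slab")
  truth <- uniform_truth(d, f_iso = 0.1, f_ic = 0.6, odi = 0.3)
  sch <- test_scheme(n_dir = 10, n_b0 = 4)
  dwi <- simulate_dwi(truth, sch, snr = NULL)
  expected <- noddi_forward(noddi_params(0.1, 0.6, odi = 0.3, mu = c(0, 0, 1)), sch)
  expect_lt(max(abs(dwi[4, 4, 4, ] - expected)), 1e-12)
  expect_true(all(dwi[, , , 1][d$mask] == 1))   # b = 0 normalized to 1

  iso <- uniform_truth(d, f_iso = 1, f_ic = 1e-9, odi = 0.5)
  iso$f_ic[] <- 0; iso$kappa[] <- 1
  dwi_iso <- simulate_dwi(iso, sch)
  b1000 <- which(sch$bvals == 1000)
  expect_equal(unique(round(dwi_iso[, , , b1000[1]][d$mask], 10)),
               round(exp(-1000 * 3.0e-3), 10))
})

test_that("injected Gaussian noise has the prescribed scale", {
  d <- make_voxel_domain(c(8, 8, 8), "slab")     # 512 replicate voxels
  truth <- uniform_truth(d)
  sch <- acq_scheme(c(0, 0, 1000), rbind(0, 0, c(0, 0, 1)))
  dwi <- simulate_dwi(truth, sch, snr = 30, noise_model = "gaussian", seed = 2)
  b0_vals <- dwi[, , , 1][d$mask]
  expect_lt(abs(stats::sd(b0_vals) - 1 / 30) / (1 / 30), 0.1)
  expect_error(simulate_dwi(truth, sch, snr = -5), "positive")

  # rician magnitudes are non-negative by construction
  dwi_r <- simulate_dwi(truth, sch, snr = 10, noise_model = "rician", seed = 2)
  expect_true(all(dwi_r[, , , 1][d$mask] >= 0))
})

test_that("generators are pure functions of their seed", {
  d1 <- make_voxel_domain(c(10, 12, 8), "curved_shell")
  d2 <- make_voxel_domain(c(10, 12, 8), "curved_shell")
  expect_identical(d1$mask, d2$mask)

  ds1 <- make_unfolded_dataset(c(16, 8), 4, 3, seed = 9)
  ds2 <- make_unfolded_dataset(c(16, 8), 4, 3, seed = 9)
  expect_identical(ds1$maps, ds2$maps)

  pr1 <- make_correlated_map_pair(c(16, 8), 0.5, seed = 4)
  pr2 <- make_correlated_map_pair(c(16, 8), 0.5, seed = 4)
  expect_identical(pr1$map_a$values, pr2$map_a$values)

  t1 <- make_subfield_table(5, seed = 3)
  t2 <- make_subfield_table(5, seed = 3)
  expect_identical(t1, t2)
})

test_that("zero effect size gives pure smooth noise with vanishing group mean", {
  ds <- make_unfolded_dataset(c(16, 12), n_subjects = 60, true_rank = 3,
                              effect_size = 0, n_metrics = 1,
                              noise_sd = 1, seed = 21)
  expect_equal(sort(unique(ds$true_parcels)), 1:3)
  expect_true(all(is.finite(ds$maps)))
  mu <- rowMeans(ds$maps)
  se <- apply(ds$maps, 1, stats::sd) / sqrt(ncol(ds$maps))
  expect_gt(mean(abs(mu) < 3 * se), 0.95)
  expect_error(make_unfolded_dataset(c(4, 2), 1, 20, n_metrics = 1), "true_rank")
})

test_that("correlated map pairs hit their target Spearman correlation", {
  rhos <- vapply(1:100, function(s) {
    pr <- make_correlated_map_pair(c(64, 32), 0.9, smoothness_mm = 2, seed = s)
    spearman_rho(pr$map_a, pr$map_b)
  }, numeric(1))
  expect_true(all(rhos >= 0.8 & rhos <= 0.97))

  neg <- vapply(1:100, function(s) {
    pr <- make_correlated_map_pair(c(32, 16), -0.5, seed = 200 + s)
    spearman_rho(pr$map_a, pr$map_b)
  }, numeric(1))
  expect_gte(sum(neg < 0), 95)
  expect_error(make_correlated_map_pair(c(8, 8), 1.2), "rho_target")
})

test_that("subfield tables honour their class means and covariance", {
  t0 <- make_subfield_table(4, class_cov = matrix(0, 3, 3), seed = 1)
  sub_rows <- t0[t0$subfield == "Sub", ]
  expect_true(all(sub_rows$odi == sub_rows$odi[1]))
  expect_equal(nrow(t0), 4 * 2 * 5)        # subjects x hemispheres x subfields
  bad <- diag(c(1, -1, 1))
  expect_error(make_subfield_table(4, class_cov = bad), "positive semi-definite")
})
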