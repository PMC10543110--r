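test_that("ODI <-> kappa conversion follows the arctan formula and inverts", {
  expect_equal(odi_from_kappa(1), 0.5)
  expect_lt(odi_from_kappa(1e9), 1e-8)
  expect_equal(kappa_from_odi(odi_from_kappa(3.7)), 3.7, tolerance = 1e-10)
  expect_error(odi_from_kappa(0), "positive")
  expect_error(kappa_from_odi(1.2), "0, 1")
})

test_that("forward model respects normalization and single-compartment limits", {
  sch <- test_scheme()
  p_iso <- noddi_params(f_iso = 1, f_ic = 0, kappa = 1)
  E <- noddi_forward(p_iso, sch)
  expect_equal(unique(E[sch$bvals == 0]), 1)
  expect_equal(E[sch$bvals == 1000][1], exp(-1000 * 3.0e-3), tolerance = 1e-10)
  expect_equal(E[sch$bvals == 3000][1], exp(-3000 * 3.0e-3), tolerance = 1e-10)

  # near-parallel sticks show almost no attenuation perpendicular to mu
  p_stick <- noddi_params(f_iso = 0, f_ic = 1, kappa = 64, mu = c(0, 0, 1))
  perp <- acq_scheme(c(0, 2000, 2000), rbind(0, c(1, 0, 0), c(0, 1, 0)))
  E_perp <- noddi_forward(p_stick, perp)[2:3]
  expect_true(all(E_perp > 0.98))
})

test_that("forward model matches the brute-force spherical quadrature oracle", {
  sch <- acq_scheme(c(0, rep(c(1000, 2000, 3000), each = 4)),
                    rbind(0, matrix(rep(t(fibonacci_hemisphere(4)), 3),
                                    ncol = 3, byrow = TRUE)))
  cases <- expand.grid(f_ic = c(0.2, 0.6), odi = c(0.1, 0.4, 0.8),
                       f_iso = c(0.05, 0.3))
  for (i in seq_len(nrow(cases))) {
    p <- noddi_params(f_iso = cases$f_iso[i], f_ic = cases$f_ic[i],
                      odi = cases$odi[i], mu = c(0.3, -0.4, sqrt(0.75)))
    expect_lt(max(abs(noddi_forward(p, sch) - oracle_noddi_forward(p, sch))),
              1e-3)
  }
})

test_that("forward model is antipodally symmetric, bounded, and monotone in b", {
  p <- noddi_params(f_iso = 0.15, f_ic = 0.5, odi = 0.35, mu = c(0.6, 0.64, 0.48))
  sch <- test_scheme(n_dir = 12)
  pm <- noddi_params(f_iso = 0.15, f_ic = 0.5, odi = 0.35, mu = -c(0.6, 0.64, 0.48))
  expect_identical(noddi_forward(p, sch), noddi_forward(pm, sch))

  E <- noddi_forward(p, sch)
  expect_true(all(E > 0 & E <= 1))

  g <- c(0.2, -0.5, sqrt(1 - 0.04 - 0.25))
  bs <- seq(0, 3000, by = 250)
  ramp <- acq_scheme(bs, rbind(0, matrix(g, length(bs) - 1, 3, byrow = TRUE)))
  expect_true(all(diff(noddi_forward(p, ramp)) <= 1e-12))
})

test_that("noddi_params validates fractions and orientation", {
  expect_error(noddi_params(0.5, 0.7, kappa = 1), "fractions")
  expect_error(noddi_params(0.1, 0.5, kappa = 1, mu = c(0, 0, 0)), "non-zero")
  expect_error(noddi_params(0.1, 0.5), "exactly one")
  p <- noddi_params(0.2, 0.5, odi = 0.4, mu = c(0, 0, 2))
  expect_equal(p$f_iso + p$f_ic + p$f_ec, 1, tolerance = 1e-9)
  expect_equal(sum(p$mu^2), 1, tolerance = 1e-12)
})

test_that("noiseless fits recover the generating parameters", {
  sch <- test_scheme()
  truth <- noddi_params(f_iso = 0.1, f_ic = 0.6, odi = 0.3, mu = c(0, 0, 1))
  fit <- fit_noddi(noddi_forward(truth, sch), sch)
  expect_lt(abs(fit$params$f_ic - 0.6), 0.02)
  expect_lt(abs(fit$params$odi - 0.3), 0.02)
  ang <- acos(min(abs(sum(fit$params$mu * truth$mu)), 1)) * 180 / pi
  expect_lt(ang, 3)

  # pure isotropic signal
  iso <- noddi_params(f_iso = 1, f_ic = 0, kappa = 1)
  fit_iso <- fit_noddi(noddi_forward(iso, sch), sch)
  expect_gt(fit_iso$params$f_iso, 0.95)
})

test_that("degenerate signals are flagged, not fitted, and fits are deterministic", {
  sch <- test_scheme(n_dir = 12)
  bad <- fit_noddi(rep(0, length(sch$bvals)), sch)
  expect_identical(bad$flag, "bad_signal")
  expect_false(bad$converged)

  sig <- noddi_forward(noddi_params(0.1, 0.5, odi = 0.4), sch) # no noise needed
  f1 <- fit_noddi(sig, sch)
  f2 <- fit_noddi(sig, sch)
  expect_identical(f1$params, f2$params)

  one_shell <- acq_scheme(c(0, rep(1000, 12)), rbind(0, fibonacci_hemisphere(12)))
  expect_warning(fit_noddi(noddi_forward(noddi_params(0.1, 0.5, odi = 0.4), one_shell),
                           one_shell, options = list(maxit = 5L)),
                 "shells")
})

test_that("DTI recovers isotropic and anisotropic generating tensors", {
  sch <- test_scheme(n_dir = 15)
  iso_sig <- exp(-sch$bvals * 1e-3)
  f <- fit_dti(iso_sig, sch)
  expect_equal(f$FA, 0, tolerance = 1e-9)
  expect_equal(f$MD, 1e-3, tolerance = 1e-9)

  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 1, 1, 0, 2), 3)))
  D <- R %*% diag(c(1.7e-3, 0.3e-3, 0.3e-3)) %*% t(R)
  sig <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
  f2 <- fit_dti(sig, sch)
  expect_lt(max(abs(f2$D - D)), 1e-9)
  expect_gt(abs(sum(f2$e1 * R[, 1])), 1 - 1e-6)
  expect_equal(f2$MD, sum(diag(f2$D)) / 3, tolerance = 1e-12)
})

test_that("DTI refuses under-determined direction sets", {
  sch <- acq_scheme(c(0, rep(1000, 5)), rbind(0, fibonacci_hemisphere(5)))
  expect_error(fit_dti(exp(-sch$bvals * 1e-3), sch), "6 unique directions")
})
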