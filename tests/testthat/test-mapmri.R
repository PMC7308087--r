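sch <- test_scheme()

test_that("index set size and parameter validation", {
  expect_equal(nrow(map_index_set(6)), 50)
  expect_equal(nrow(map_index_set(4)), 22)
  expect_equal(nrow(map_index_set(0)), 1)
  expect_error(fit_map_basis(rep(1, 276), sch, radial_order = 7), "even")
  small <- test_scheme(dirs = 10, n_b0 = 2)  # 32 measurements < 50 coef
  expect_error(fit_map_basis(rep(1, 32), small, radial_order = 6),
               "rank error")
  one_shell <- make_acquisition_scheme(1000, 30, 3, 10, 43, seed = 1)
  expect_error(fit_map_basis(rep(1, 33), one_shell), "2 non-zero shells")
})

test_that("single Gaussian voxels are fitted exactly", {
  cmp <- list(gaussian_compartment(1, diag(c(1.7, 0.4, 0.3)) * 1e-3))
  sig <- simulate_voxel_signal(sch, cmp)
  fit <- fit_map_basis(sig, sch, radial_order = 2)
  expect_lt(fit$fit_residual, 1e-6)
  expect_equal(fit$e0, 1, tolerance = 1e-6)
  # held-out prediction of a 2-compartment mixture at order 6 within 2%
  mix <- list(gaussian_compartment(0.6, diag(c(1.5, 0.5, 0.4)) * 1e-3),
              gaussian_compartment(0.4, 1.0e-3))
  sig2 <- simulate_voxel_signal(sch, mix)
  fit2 <- fit_map_basis(sig2, sch)
  held <- make_acquisition_scheme(c(1500, 2500), 40, 0, 10, 43, seed = 99)
  truth <- simulate_voxel_signal(held, mix)
  pred <- map_predict(fit2, held$q_magnitudes * held$bvecs)
  expect_lt(max(abs(pred - truth)), 0.02)
})

test_that("analytic RTOP equals q-space quadrature of the fitted signal", {
  for (s in c(1, 4, 9)) {
    cmp <- random_mixture(seed = 400 + s)
    fit <- fit_map_basis(simulate_voxel_signal(sch, cmp), sch)
    expect_equal(rtop_from_fit(fit), quadrature_rtop_fitted(fit, 1),
                 tolerance = 1e-3)
  }
})

test_that("free water gives normalized RTOP 1 and the closed-form value", {
  sig <- simulate_voxel_signal(sch, list(gaussian_compartment(1, 3.0e-3)))
  m <- compute_rtop_map(sig, sch)
  expect_equal(m$normalized_rtop, 1, tolerance = 0.02)
  expect_equal(m$rtop, (4 * pi * sch$tau * 3.0e-3)^(-1.5), tolerance = 0.02)
  # pure analytic estimate is also exact here (Gaussian is in the basis)
  expect_equal(rtop_from_fit(m$fit), (4 * pi * sch$tau * 3.0e-3)^(-1.5),
               tolerance = 1e-4)
})

test_that("oracle recovery within 5% on 20 random mixtures at order 6", {
  errs <- vapply(1:20, function(s) {
    cmp <- random_mixture(seed = 100 + s)
    m <- compute_rtop_map(simulate_voxel_signal(sch, cmp), sch)
    (m$normalized_rtop -
       normalize_rtop(rtop_oracle(cmp, sch$tau), 3.0e-3, sch$tau)) /
      normalize_rtop(rtop_oracle(cmp, sch$tau), 3.0e-3, sch$tau)
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("shrinking diffusivities strictly increases estimated RTOP", {
  base <- diag(c(1.4, 0.9, 0.7)) * 1e-3
  vals <- vapply(c(1, 0.8, 0.6), function(f) {
    sig <- simulate_voxel_signal(sch, list(gaussian_compartment(1, base * f)))
    compute_rtop_map(sig, sch)$rtop
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("recovery error decreases with radial order 2 -> 4 -> 6", {
  mean_err <- vapply(c(2, 4, 6), function(ord) {
    mean(vapply(1:20, function(s) {
      cmp <- random_mixture(seed = 100 + s)
      m <- compute_rtop_map(simulate_voxel_signal(sch, cmp), sch,
                            radial_order = ord)
      abs(m$rtop - rtop_oracle(cmp, sch$tau)) / rtop_oracle(cmp, sch$tau)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("rotation invariance of the analytic RTOP", {
  cmp <- list(gaussian_compartment(0.6, diag(c(1.6, 0.5, 0.4)) * 1e-3),
              gaussian_compartment(0.4, diag(c(0.9, 0.8, 0.6)) * 1e-3))
  r <- rtopmap:::random_rotation()
  sig <- simulate_voxel_signal(sch, cmp)
  # rotate gradients and tensors together
  sch_rot <- sch
  sch_rot$bvecs <- sch$bvecs %*% t(r)
  cmp_rot <- lapply(cmp, function(cp)
    gaussian_compartment(cp$volume_fraction,
                         r %*% cp$diffusion_tensor %*% t(r)))
  sig_rot <- simulate_voxel_signal(sch_rot, cmp_rot)
  expect_equal(sig, sig_rot, tolerance = 1e-10)
  r1 <- rtop_from_fit(fit_map_basis(sig, sch))
  r2 <- rtop_from_fit(fit_map_basis(sig_rot, sch_rot))
  expect_equal(r1, r2, tolerance = 1e-6 * abs(r1))
})

test_that("median normalized RTOP is stable under Rician noise at SNR 30", {
  n_vox <- 16
  clean <- vapply(seq_len(n_vox), function(s) {
    cmp <- random_gm_mixture(seed = 500 + s)
    compute_rtop_map(simulate_voxel_signal(sch, cmp), sch)$normalized_rtop
  }, numeric(1))
  noisy <- vapply(seq_len(n_vox), function(s) {
    cmp <- random_gm_mixture(seed = 500 + s)
    compute_rtop_map(simulate_voxel_signal(sch, cmp, snr = 30, seed = s),
                     sch)$normalized_rtop
  }, numeric(1))
  expect_lt(abs(median(noisy) - median(clean)) / median(clean), 0.10)
})

test_that("normalization ratios and input validation", {
  tau <- 0.04
  expect_equal(normalize_rtop((4 * pi * tau * 3e-3)^(-1.5), 3e-3, tau), 1)
  # D = D_free / 4 isotropic -> ratio 4^(3/2) = 8
  r <- (4 * pi * tau * 0.75e-3)^(-1.5)
  expect_equal(normalize_rtop(r, 3e-3, tau), 8, tolerance = 1e-12)
  expect_error(normalize_rtop(1, -1, tau), "free_diffusivity")
  expect_error(normalize_rtop(1, 3e-3, 0), "tau")
})
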