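sch <- test_scheme(dirs = 30, n_b0 = 3)

test_that("noiseless attenuation follows the Gaussian mixture closed form", {
  iso <- list(gaussian_compartment(1, 3.0e-3))
  e <- simulate_voxel_signal(sch, iso)
  expect_equal(unique(round(e[sch$bvals == 1000], 10)), round(exp(-3), 10))
  expect_equal(e[sch$bvals == 0], rep(1, 3))

  mix <- list(gaussian_compartment(0.5, 3.0e-3),
              gaussian_compartment(0.5, 0.5e-3))
  e2 <- simulate_voxel_signal(sch, mix)
  expect_equal(unique(round(e2[sch$bvals == 1000], 6)),
               round(0.5 * exp(-3) + 0.5 * exp(-0.5), 6))

  # positivity, bounds, and monotone decay in b for a fixed direction
  for (s in 1:5) {
    cmp <- random_mixture(seed = s)
    ev <- simulate_voxel_signal(sch, cmp)
    expect_true(all(ev > 0 & ev <= 1 + 1e-12))
    d <- sch$bvecs[sch$bvals == 3000, ][1, ]
    bs <- c(0, 500, 1500, 2500, 3500)
    prof <- vapply(bs, function(b) sum(vapply(cmp, function(cp)
      cp$volume_fraction * exp(-b * (t(d) %*% cp$diffusion_tensor %*% d)),
      numeric(1))), numeric(1))
    expect_true(all(diff(prof) < 0))
  }
})

test_that("compartment validation rejects bad tensors and fractions", {
  expect_error(gaussian_compartment(0.5, matrix(1:9, 3, 3)), "symmetric")
  bad <- diag(c(1, 1, -1)) * 1e-3
  expect_error(gaussian_compartment(0.5, bad), "positive-definite")
  expect_error(simulate_voxel_signal(sch, list(gaussian_compartment(0.5, 1e-3))),
               "sum to 1")
  expect_error(simulate_voxel_signal(sch, list(gaussian_compartment(1, 1e-3)),
                                     snr = -2), "snr")
})

test_that("Rician noise is reproducible and matches the analytic mean", {
  cmp <- list(gaussian_compartment(1, 1.0e-3))
  a <- simulate_voxel_signal(sch, cmp, snr = 20, seed = 11)
  b <- simulate_voxel_signal(sch, cmp, snr = 20, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_voxel_signal(sch, cmp, snr = 20,
                                                  seed = 12)))
  # Monte-Carlo mean vs Rician first moment at one measurement
  nu <- exp(-2)  # b = 2000 along any direction (isotropic)
  sigma <- 1 / 20
  idx <- which(sch$bvals == 2000)[1]
  reps <- vapply(seq_len(10000), function(s)
    simulate_voxel_signal(sch, cmp, snr = 20, seed = s)[idx], numeric(1))
  expect_equal(mean(reps), rician_mean_oracle(nu, sigma), tolerance = 0.01)
})

test_that("rtop_oracle: closed form, scaling law, quadrature equivalence", {
  tau <- 0.0397
  iso <- list(gaussian_compartment(1, 3.0e-3))
  expect_equal(rtop_oracle(iso, tau), (4 * pi * tau * 3.0e-3)^(-1.5),
               tolerance = 1e-12)
  # halving det(D) multiplies RTOP by sqrt(2)
  d1 <- list(gaussian_compartment(1, diag(c(2, 1, 1)) * 1e-3))
  d2 <- list(gaussian_compartment(1, diag(c(1, 1, 1)) * 1e-3))
  expect_equal(rtop_oracle(d2, tau) / rtop_oracle(d1, tau), sqrt(2),
               tolerance = 1e-12)
  # strictly decreasing in a compartment's eigenvalues
  r_small <- rtop_oracle(list(gaussian_compartment(1, 0.8e-3)), tau)
  r_big <- rtop_oracle(list(gaussian_compartment(1, 1.0e-3)), tau)
  expect_gt(r_small, r_big)
  # matches brute-force quadrature of E(q) within 0.5% on random mixtures
  for (s in 1:20) {
    cmp <- random_mixture(seed = 300 + s)
    expect_equal(quadrature_rtop_truth(cmp, tau), rtop_oracle(cmp, tau),
                 tolerance = 5e-3)
  }
})

test_that("generators are reproducible under a fixed seed", {
  expect_identical(make_surface_phantom(seed = 3),
                   make_surface_phantom(seed = 3))
  expect_identical(make_rest_phantom(seed = 4)$data,
                   make_rest_phantom(seed = 4)$data)
  expect_identical(make_brain_behavior(seed = 5),
                   make_brain_behavior(seed = 5))
  a <- make_surface_phantom(noise_sd = 0.2, seed = 1)
  b <- make_surface_phantom(noise_sd = 0.2, seed = 2)
  expect_identical(a$left$labels, b$left$labels)
  expect_false(identical(a$left$planted_field, b$left$planted_field))
})

test_that("rest phantom realizes the planted coupling (and its null)", {
  rp <- make_rest_phantom(coupling = 0.6, seed = 2)
  flat <- matrix(rp$data, ncol = dim(rp$data)[4])
  for (k in names(rp$seed_masks)) {
    tser <- colMeans(flat[as.vector(rp$target_masks[[k]]), ])
    r_own <- cor(tser, rp$seed_series[, k])
    others <- setdiff(colnames(rp$seed_series), k)
    r_oth <- vapply(others, function(o) cor(tser, rp$seed_series[, o]),
                    numeric(1))
    expect_gt(r_own, max(abs(r_oth)) + 0.2)
  }
  # null coupling: |r| below 3/sqrt(T)
  rp0 <- make_rest_phantom(coupling = 0, seed = 3)
  flat0 <- matrix(rp0$data, ncol = dim(rp0$data)[4])
  t_len <- dim(rp0$data)[4]
  for (k in names(rp0$seed_masks)) {
    tser <- colMeans(flat0[as.vector(rp0$target_masks[[k]]), ])
    expect_lt(abs(cor(tser, rp0$seed_series[, k])), 3 / sqrt(t_len))
  }
  expect_error(make_rest_phantom(coupling = 1.2), "coupling")
})

test_that("brain-behavior phantom plants the canonical structure", {
  bb <- make_brain_behavior(400, 0.6, 0, seed = 9)
  f <- fit_cca(bb$brain, bb$behavior)
  expect_equal(f$canonical_correlations[1], 0.6, tolerance = 0.1)
  # independence under a zero planted correlation
  bb0 <- make_brain_behavior(400, 0, 0, seed = 10)
  x <- as.matrix(bb0$brain[, -1]); y <- as.matrix(bb0$behavior[, -1])
  expect_lt(max(abs(cor(x, y))), 4 / sqrt(400))
  expect_equal(ncol(x), 6)
  expect_equal(ncol(y), 11)
  # missing cells: ~6 of 413 at the study's missing rate
  bbm <- make_brain_behavior(413, 0.32, 0.015, seed = 1)
  expect_equal(length(bbm$missing_subjects), 6)
})
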