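test_that("motion screening thresholds and hand-computed FD", {
  zeros <- matrix(0, 50, 6)
  ms <- motion_screen(zeros)
  expect_true(ms$include)
  expect_equal(ms$total_displacement, 0)
  expect_equal(ms$mean_fd, 0)
  # single 3 mm spike excludes on total displacement
  spike <- zeros; spike[25, 1] <- 3
  expect_false(motion_screen(spike)$include)
  expect_equal(motion_screen(spike)$total_displacement, 3)
  # 5-frame drift vs hand computation (rotations on a 50 mm sphere)
  m <- rbind(c(0, 0, 0, 0, 0, 0),
             c(0.1, 0, 0, 0.001, 0, 0),
             c(0.1, 0.05, 0, 0.001, 0.002, 0),
             c(0.2, 0.05, -0.05, 0.001, 0.002, -0.001),
             c(0.2, 0.05, -0.05, 0.001, 0.002, -0.001))
  fd_hand <- c(0,
               0.1 + 50 * 0.001,
               0.05 + 50 * 0.002,
               0.1 + 0.05 + 50 * 0.001,
               0)
  expect_equal(motion_screen(m)$fd, fd_hand, tolerance = 1e-9)
  expect_error(motion_screen(m[, 1:5]), "frames x 6")
})

test_that("band-pass keeps the passband and kills the stopband", {
  tr <- 0.72
  t_len <- 400
  tt <- (0:(t_len - 1)) * tr
  mk_run <- function(freq) {
    d <- array(0, c(3, 3, 3, t_len))
    for (i in 1:27) d[((i - 1) %% 3) + 1, ((i - 1) %/% 3 %% 3) + 1,
                      ((i - 1) %/% 9) + 1, ] <- sin(2 * pi * freq * tt)
    list(data = d, tr = tr)
  }
  inband <- preprocess_rest(mk_run(0.05), fwhm_mm = 0)
  amp_in <- max(abs(inband$data[2, 2, 2, 50:350]))
  expect_gt(amp_in, 0.95)
  stop <- preprocess_rest(mk_run(0.2), fwhm_mm = 0)
  amp_out <- max(abs(stop$data[2, 2, 2, 50:350]))
  expect_lt(amp_out, 0.1)
  expect_error(preprocess_rest(mk_run(0.05), band_hz = c(0.01, 2)),
               "Nyquist")
})

test_that("spatial smoothing recovers the requested FWHM", {
  d <- array(0, c(31, 31, 31, 1))
  d[16, 16, 16, 1] <- 1
  run <- list(data = d, tr = 1)
  sm <- rtopmap:::gaussian_smooth_volume(d[, , , 1],
                                         rtopmap:::fwhm_to_sigma(6, 2))
  prof <- sm[, 16, 16]
  # fit a Gaussian to the impulse response and convert back to FWHM (mm)
  xs <- (1:31 - 16) * 2
  fit <- lm(log(prof[prof > 1e-12]) ~ I(xs[prof > 1e-12]^2))
  sigma_mm <- sqrt(-1 / (2 * unname(coef(fit)[2])))
  expect_equal(2 * sqrt(2 * log(2)) * sigma_mm, 6, tolerance = 0.5 / 6)
})

test_that("seed regression: exact beta, null beta, nuisance invariance", {
  rp <- make_rest_phantom(coupling = 0.5, seed = 6)
  pp <- preprocess_rest(rp, fwhm_mm = 0)
  bm <- seed_connectivity(pp, rp$seed_masks$dAI)
  # target zone of the matching seed has the largest mean beta
  means <- vapply(rp$target_masks, function(m) mean(bm$beta[m]), numeric(1))
  expect_equal(names(which.max(means)), "dAI")
  # voxel equal to the seed mean (no global/no motion contribution):
  # construct a tiny run by hand
  t_len <- 120
  set.seed(8)
  seedser <- rnorm(t_len)
  d <- array(rnorm(8 * t_len, sd = 0.1), c(2, 2, 2, t_len))
  d[1, 1, 1, ] <- seedser
  d[2, 2, 2, ] <- seedser           # echo voxel
  run <- list(data = d, tr = 1, motion_params = matrix(rnorm(t_len * 6,
                                                             sd = 1e-3),
                                                       t_len, 6),
              brain_mask = array(TRUE, c(2, 2, 2)))
  seedm <- array(FALSE, c(2, 2, 2)); seedm[1, 1, 1] <- TRUE
  b <- seed_connectivity(run, seedm, include_global = FALSE)
  expect_equal(b$beta[2, 2, 2], 1, tolerance = 1e-9)
  # independent voxel: |beta| < 3 SE
  expect_lt(abs(b$beta[2, 1, 1]), 3 * b$se[2, 1, 1])
  # rescaling nuisance regressors leaves the seed beta unchanged
  run2 <- run; run2$motion_params <- run$motion_params * 1000
  b2 <- seed_connectivity(run2, seedm, include_global = FALSE)
  expect_equal(b2$beta, b$beta, tolerance = 1e-9)
  # collinear design errors with the column name
  run3 <- run
  run3$data[] <- rep(seedser, each = 8)  # every voxel = seed -> global collinear
  expect_error(seed_connectivity(run3, seedm), "collinear|global")
})

test_that("group one-sample map: FDR calibration, saturation, BH hand check", {
  # all-null maps: average false-discovery proportion <= alpha
  set.seed(3)
  fdp <- vapply(1:400, function(r) {
    maps <- lapply(1:20, function(i) array(rnorm(200), c(200, 1, 1)))
    g <- group_onesample(maps, alpha = 0.05)
    sum(g$significant) / max(1, sum(g$significant))  # 0 when none
  }, numeric(1))
  # with no true effects every discovery is false: FDP = 1{any discovery};
  # BH controls E[FDP] <= alpha
  expect_lte(mean(fdp), 0.05 + 0.02)
  # constant positive betas -> everything significant
  maps_c <- lapply(1:10, function(i) array(1 + rnorm(50, sd = 0.01),
                                           c(50, 1, 1)))
  gc <- group_onesample(maps_c, alpha = 0.01)
  expect_true(all(gc$significant))
  # BH matches the brute-force step-up definition on a fixed p-set
  ps <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.42)
  adj <- p.adjust(ps, "BH")
  k <- max(which(sort(ps) <= seq_along(ps) / length(ps) * 0.05))
  expect_equal(sum(adj <= 0.05), k)
  expect_equal(k, 2)
  # zero-variance voxels get p = 1 and a flag
  maps_z <- lapply(1:5, function(i) array(c(0, rnorm(9)), c(10, 1, 1)))
  gz <- group_onesample(maps_z)
  expect_true(gz$zero_variance[1, 1, 1])
  expect_equal(gz$p[1, 1, 1], 1)
})

test_that("differential subdivisions recover planted zones disjointly", {
  subjects <- lapply(1:10, function(s) {
    rp <- make_rest_phantom(seed = 40 + s)
    pp <- preprocess_rest(rp, fwhm_mm = 0)
    lapply(rp$seed_masks, function(m) seed_connectivity(pp, m)$beta)
  })
  ref <- make_rest_phantom(seed = 41)
  by_seed <- lapply(names(ref$seed_masks), function(k)
    lapply(subjects, function(s) s[[k]]))
  names(by_seed) <- names(ref$seed_masks)
  masks <- differential_subdivisions(by_seed, ref$target_mask, alpha = 0.01)
  # pairwise disjoint
  expect_lte(max(as.vector(masks$vAI) + as.vector(masks$dAI) +
                   as.vector(masks$PI)), 1)
  for (k in names(masks))
    expect_gte(dice_coefficient(masks[[k]], ref$target_masks[[k]]), 0.8)
  # identical maps for two seeds -> both empty
  same <- by_seed
  same$dAI <- same$vAI
  masks2 <- differential_subdivisions(same, ref$target_mask)
  expect_equal(sum(masks2$vAI), 0)
  expect_equal(sum(masks2$dAI), 0)
  # misaligned grids error
  bad <- by_seed
  bad$PI[[1]] <- array(0, c(2, 2, 2))
  expect_error(differential_subdivisions(bad, ref$target_mask),
               "misaligned")
})

test_that("recovered subdivision masks reproduce a planted RTOP ordering", {
  # end-to-end mirror: RTOP field over the grid with planted zone means,
  # averaged inside recovered masks, keeps the planted ordering
  subjects <- lapply(1:8, function(s) {
    rp <- make_rest_phantom(seed = 60 + s)
    pp <- preprocess_rest(rp, fwhm_mm = 0)
    lapply(rp$seed_masks, function(m) seed_connectivity(pp, m)$beta)
  })
  ref <- make_rest_phantom(seed = 61)
  by_seed <- lapply(names(ref$seed_masks), function(k)
    lapply(subjects, function(s) s[[k]]))
  names(by_seed) <- names(ref$seed_masks)
  masks <- differential_subdivisions(by_seed, ref$target_mask)
  rtop_field <- array(0, dim(ref$target_mask))
  planted <- c(vAI = 1.8, dAI = 2.3, PI = 2.9)
  for (k in names(planted)) rtop_field[ref$target_masks[[k]]] <- planted[k]
  got <- vapply(names(planted), function(k) mean(rtop_field[masks[[k]]]),
                numeric(1))
  expect_true(got["vAI"] < got["dAI"] && got["dAI"] < got["PI"])
})
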