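flat_sheet <- function(n = 300) make_surface_phantom(n, c(1, 0, 0), seed = 1)$left

test_that("mesh gradient is exact for linear fields and zero for constants", {
  h <- flat_sheet()
  gx <- mesh_gradient(h$mesh, h$mesh$vertices[, 1])
  expect_lt(max(abs(gx$gradients[gx$valid, 1] - 1)), 1e-9)
  expect_lt(max(abs(gx$gradients[gx$valid, 2:3])), 1e-9)
  gc <- mesh_gradient(h$mesh, rep(3.5, nrow(h$mesh$vertices)))
  expect_lt(max(abs(gc$gradients)), 1e-12)
  # gradients are tangent to the surface
  dots <- rowSums(gx$gradients * gx$vertex_normals)
  expect_lt(max(abs(dots)), 1e-6 * max(sqrt(rowSums(gx$gradients^2))))
})

test_that("gradient operator is linear", {
  h <- flat_sheet()
  f <- sin(h$mesh$vertices[, 1] / 10)
  g <- cos(h$mesh$vertices[, 2] / 7)
  ga <- mesh_gradient(h$mesh, 2 * f + 3 * g)$gradients
  gb <- 2 * mesh_gradient(h$mesh, f)$gradients +
    3 * mesh_gradient(h$mesh, g)$gradients
  expect_equal(ga, gb, tolerance = 1e-10)
})

test_that("curved-sheet gradient matches refinement estimate within 2%", {
  # curved sheet: z = bump(x, y); analytic tangential gradient via finer mesh
  mk <- function(nx) {
    m <- rtopmap:::grid_sheet(nx, nx, 40, 40)
    m$vertices[, 3] <- 3 * sin(m$vertices[, 1] / 8) * cos(m$vertices[, 2] / 9)
    m
  }
  f_of <- function(m) sin(m$vertices[, 1] / 6) + 0.5 * cos(m$vertices[, 2] / 5)
  coarse <- mk(25); fine <- mk(49)  # nested grid positions
  gc <- mesh_gradient(coarse, f_of(coarse))
  gf <- mesh_gradient(fine, f_of(fine))
  # compare magnitudes at matching interior locations (vertex subset)
  pick <- which(gc$valid)
  nearest_idx <- function(v, m) which.min(colSums((t(m$vertices) - v)^2))
  idx_f <- vapply(pick, function(i) nearest_idx(coarse$vertices[i, ], fine),
                  integer(1))
  ok <- gf$valid[idx_f]
  mg_c <- sqrt(rowSums(gc$gradients[pick[ok], ]^2))
  mg_f <- sqrt(rowSums(gf$gradients[idx_f[ok], ]^2))
  expect_lt(median(abs(mg_c - mg_f) / mg_f), 0.02)
})

test_that("main_direction: parallel fields, degeneracy, planted recovery", {
  h <- flat_sheet()
  gf <- mesh_gradient(h$mesh, h$planted_field)
  md <- main_direction(gf, rep(TRUE, nrow(h$mesh$vertices)))
  expect_lt(rtopmap:::angle_between(md, h$planted_gradient_direction),
            5 * pi / 180)
  # all parallel -> exact
  gpar <- gf
  gpar$gradients <- matrix(rep(c(0, 1, 0), nrow(h$mesh$vertices)),
                           ncol = 3, byrow = TRUE)
  gpar$valid <- rep(TRUE, nrow(h$mesh$vertices))
  expect_equal(main_direction(gpar, rep(TRUE, nrow(h$mesh$vertices))),
               c(0, 1, 0))
  # two equal opposite clusters cancel
  n <- nrow(h$mesh$vertices)
  gopp <- gpar
  gopp$gradients[seq(1, n, 2), ] <- matrix(rep(c(0, -1, 0), length(seq(1, n, 2))),
                                           ncol = 3, byrow = TRUE)
  half <- seq_len(2 * floor(n / 2))  # even count -> exact cancellation
  expect_error(main_direction(gopp, half), "degenerate|valid vertices")
  expect_error(main_direction(gf, logical(n)), "empty region")
})

test_that("oblique planted gradient recovered within 5 degrees per subdivision", {
  ph <- make_surface_phantom(400, c(1, 2, 0), noise_sd = 0.05, seed = 4)
  for (h in c("left", "right")) {
    hp <- ph[[h]]
    gf <- mesh_gradient(hp$mesh, hp$planted_field)
    for (sub in c("vAI", "dAI", "PI")) {
      md <- main_direction(gf, hp$labels == sub)
      expect_lt(rtopmap:::angle_between(md, hp$planted_gradient_direction),
                5 * pi / 180)
    }
  }
})

test_that("directional statistics: degenerate, vMF coverage, SEM scaling", {
  u0 <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  ds0 <- directional_stats(u0, n_boot = 200)
  expect_equal(ds0$dispersion, 0)
  expect_equal(ds0$ci_halfwidth, 0)
  expect_error(directional_stats(rbind(u0, c(0, 0, 0))), "zero-length")

  # coverage: planted vMF mean inside the bootstrap CI at a rate consistent
  # with >= 93% (binomial check over 200 replicates)
  mu <- c(1, 1, 1) / sqrt(3)
  set.seed(99)
  hits <- vapply(1:200, function(r) {
    d <- rvmf(413, mu, kappa = 50)
    ds <- directional_stats(d, n_boot = 1000, seed = r)
    rtopmap:::angle_between(ds$mean_direction, mu) <= ds$ci_halfwidth
  }, logical(1))
  expect_gt(pbinom(sum(hits), length(hits), 0.93), 0.01)

  # SEM halves (within 15%) when N quadruples at fixed concentration
  set.seed(5)
  sems <- vapply(c(200, 800), function(n) {
    mean(vapply(1:40, function(r)
      directional_stats(rvmf(n, mu, 50), n_boot = 50, seed = r)$sem,
      numeric(1)))
  }, numeric(1))
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.15)
})

test_that("Rayleigh test: maximal concentration, bound, type-I calibration", {
  ident <- matrix(rep(c(1, 0, 0), 413), ncol = 3, byrow = TRUE)
  rt <- rayleigh_test(ident)
  expect_equal(rt$statistic, 3 * 413)
  expect_equal(rt$df, 3)
  expect_lt(rt$p, 1e-10)
  set.seed(1)
  for (r in 1:20) {
    s <- rayleigh_test(rtopmap:::random_unit_vectors(50))$statistic
    expect_lte(s, 3 * 50)
  }
  # p-values uniform under uniformity (1000 replicates)
  set.seed(2)
  ps <- vapply(1:1000, function(r)
    rayleigh_test(rtopmap:::random_unit_vectors(413))$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  rej <- mean(ps < 0.05)
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("isocontours: straight line on a ramp, edge property, refinement", {
  h <- flat_sheet()
  ic <- isocontours(h$mesh, h$mesh$vertices[, 1], 30)
  expect_true(all(abs(c(ic$x1, ic$x2) - 30) < 1e-9))
  expect_equal(as.numeric(contour_lengths(ic)), 30, tolerance = 1e-9)
  expect_equal(length(unique(ic$polyline)), 1)  # one straight polyline
  expect_warning(isocontours(h$mesh, h$mesh$vertices[, 1], 1000),
                 "outside")
  # each segment endpoint lies on a mesh edge (barycentric on two vertices)
  # and contour length is stable under refinement on a smooth field
  mkf <- function(nx) {
    m <- rtopmap:::grid_sheet(nx, nx, 40, 40)
    list(m = m, f = sin(m$vertices[, 1] / 9) + cos(m$vertices[, 2] / 7))
  }
  a <- mkf(30); b <- mkf(60)
  la <- as.numeric(contour_lengths(isocontours(a$m, a$f, 0.4)))
  lb <- as.numeric(contour_lengths(isocontours(b$m, b$f, 0.4)))
  expect_equal(la, lb, tolerance = 0.02)
})
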