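test_that("missing-value exclusion mirrors the cohort bookkeeping", {
  bb <- make_brain_behavior(413, 0.32, 0.015, seed = 1)
  cc <- exclude_missing(bb$behavior, bb$brain)
  expect_equal(nrow(cc$brain), 407)
  expect_setequal(cc$excluded$subject, bb$missing_subjects)
  # no missing -> identity
  bb0 <- make_brain_behavior(100, 0.3, 0, seed = 2)
  cc0 <- exclude_missing(bb0$behavior, bb0$brain)
  expect_equal(nrow(cc0$brain), 100)
  expect_equal(nrow(cc0$excluded), 0)
  # unmatched ids are logged
  beh <- bb0$behavior
  beh$subject[1] <- "sub-xxxx"
  cc1 <- exclude_missing(beh, bb0$brain)
  expect_true(any(grepl("unmatched", cc1$excluded$reason)))
  # under-determination guard
  tiny <- make_brain_behavior(30, 0, 0.45, seed = 3)
  expect_error(exclude_missing(tiny$behavior, tiny$brain), "complete")
})

test_that("CCA: deterministic linear maps, affine invariance, degeneracy", {
  set.seed(4)
  x <- matrix(rnorm(200 * 6), 200, 6)
  y <- x %*% matrix(rnorm(6 * 11), 6, 11)  # rank-6 noiseless map
  f <- fit_cca(x, y)
  expect_equal(f$canonical_correlations, rep(1, 6), tolerance = 1e-8)
  # invariance under invertible linear transforms of either block
  A <- matrix(rnorm(36), 6) + diag(6)
  B <- matrix(rnorm(121), 11) + diag(11)
  set.seed(5)
  y2 <- y + matrix(rnorm(length(y)), nrow(y))
  f1 <- fit_cca(x, y2)
  f2 <- fit_cca(x %*% A, y2 %*% B)
  expect_equal(f1$canonical_correlations, f2$canonical_correlations,
               tolerance = 1e-8)
  # degenerate column errors name the column
  xbad <- x; xbad[, 3] <- 7
  colnames(xbad) <- paste0("c", 1:6)
  expect_error(fit_cca(xbad, y2), "c3")
})

test_that("canonical correlations agree with the reference implementation", {
  set.seed(21)
  x <- matrix(rnorm(150 * 6), 150, 6)
  y <- matrix(rnorm(150 * 11), 150, 11) + 0.4 * x[, 1]
  f <- fit_cca(x, y)
  ref <- cancor(scale(x), scale(y), xcenter = FALSE, ycenter = FALSE)
  expect_equal(f$canonical_correlations, ref$cor[1:6], tolerance = 1e-10)
})

test_that("variate correlation equals the first canonical correlation", {
  bb <- make_brain_behavior(300, 0.5, 0, seed = 6)
  f <- fit_cca(bb$brain, bb$behavior)
  vc <- variate_correlation(f)
  expect_equal(vc$r, f$canonical_correlations[1], tolerance = 1e-10)
  expect_gte(vc$r, 0)  # sign convention
  # unit-variance variates, non-increasing correlations in [0, 1]
  expect_equal(apply(f$brain_variates, 2, sd), rep(1, 6), tolerance = 1e-8)
  expect_true(all(diff(f$canonical_correlations) <= 1e-8))
  expect_true(all(f$canonical_correlations >= 0 &
                    f$canonical_correlations <= 1))
})

test_that("column sign flips leave canonical correlations unchanged", {
  bb <- make_brain_behavior(200, 0.4, 0, seed = 7)
  f1 <- fit_cca(bb$brain, bb$behavior)
  br2 <- bb$brain; br2[[3]] <- -br2[[3]]
  be2 <- bb$behavior; be2[[5]] <- -be2[[5]]
  f2 <- fit_cca(br2, be2)
  expect_equal(f1$canonical_correlations, f2$canonical_correlations,
               tolerance = 1e-10)
  lp1 <- loo_predict(bb$brain, bb$behavior)
  lp2 <- loo_predict(br2, be2)
  expect_equal(abs(lp1$pearson_r), abs(lp2$pearson_r), tolerance = 1e-8)
})

test_that("Pillai p-values are uniform under independence", {
  set.seed(8)
  ps <- vapply(1:500, function(r) {
    x <- matrix(rnorm(400 * 6), 400, 6)
    y <- matrix(rnorm(400 * 11), 400, 11)
    fit_cca(x, y)$pillai_p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("effect-size conversion reproduces the printed (r, d) pairs", {
  expect_equal(round(cohens_d_from_r(0.19), 2), 0.39)
  expect_equal(round(cohens_d_from_r(0.31), 2), 0.65)
  expect_equal(round(cohens_d_from_r(0.17), 2), 0.35)
  expect_equal(cohens_d_from_r(0), 0)
  expect_error(cohens_d_from_r(1), "r")
})

test_that("leave-one-out prediction: noiseless, planted, and null regimes", {
  # deterministic linear phantom -> prediction r ~ 1
  set.seed(9)
  x <- matrix(rnorm(120 * 6), 120, 6)
  y <- x %*% matrix(rnorm(6 * 11), 6, 11)
  lp <- loo_predict(x, y)
  expect_gt(lp$pearson_r, 0.99)
  # planted r = 0.4 at n = 400: positive, attenuated
  bb <- make_brain_behavior(400, 0.4, 0, seed = 10)
  lpp <- loo_predict(bb$brain, bb$behavior)
  expect_gt(lpp$pearson_r, 0.2)
  expect_lt(lpp$pearson_r, 0.45)
  # null: prediction centred on zero (mean over replicates; a single draw
  # has sd ~0.09) and always attenuated relative to the in-sample fit
  r0 <- vapply(1:6, function(s) {
    bb0 <- make_brain_behavior(400, 0, 0, seed = s)
    lp0 <- loo_predict(bb0$brain, bb0$behavior)
    expect_lt(lp0$pearson_r,
              fit_cca(bb0$brain, bb0$behavior)$canonical_correlations[1])
    lp0$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.06)
})

test_that("LOO prediction attenuates the in-sample correlation on average", {
  gap <- vapply(1:20, function(s) {
    bb <- make_brain_behavior(120, 0.4, 0, seed = 100 + s)
    fit_cca(bb$brain, bb$behavior)$canonical_correlations[1] -
      loo_predict(bb$brain, bb$behavior)$pearson_r
  }, numeric(1))
  expect_gt(mean(gap), 0)
})
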