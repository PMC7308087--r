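# Seed-based resting-state connectivity and differentially connected target
# subdivisions.

#' Head-motion screening
#'
#' Total displacement is the maximum translation magnitude relative to the
#' reference (first) frame. Framewise displacement follows the 50 mm-sphere
#' convention: sum of absolute backward differences of the six parameters
#' with rotations (radians) converted to arc length on a 50 mm sphere. A run
#' is included when total displacement stays below
#' `total_displacement_max` and mean FD below `fd_max`.
#'
#' @param motion_params frames x 6 matrix: 3 translations (mm), 3 rotations
#'   (radians).
#' @param total_displacement_max maximum allowed displacement (mm).
#' @param fd_max maximum allowed mean framewise displacement (mm).
#' @param rotation_radius_mm sphere radius for rotation conversion.
#' @return list with include, total_displacement, mean_fd, fd (per frame).
#' @export
motion_screen <- function(motion_params, total_displacement_max = 2,
                          fd_max = 0.2, rotation_radius_mm = 50) {
  m <- as.matrix(motion_params)
  if (ncol(m) != 6 || !all(is.finite(m)))
    stop("motion_params must be a finite frames x 6 table")
  trans <- sweep(m[, 1:3, drop = FALSE], 2, m[1, 1:3])
  td <- max(sqrt(rowSums(trans^2)))
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(include = td < total_displacement_max && mean(fd) < fd_max,
       total_displacement = td, mean_fd = mean(fd), fd = fd)
}

# FWHM (mm) to Gaussian sigma in voxels.
fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

# Separable 1-D Gaussian convolution along each spatial axis (renormalized
# at the edges).
gaussian_smooth_volume <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  kern <- kern / sum(kern)
  sm_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- dp[1]
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (k in seq_along(kern)) {
      off <- k - half - 1L
      src <- seq_len(n) + off
      okk <- src >= 1 & src <= n
      out[okk, ] <- out[okk, ] + kern[k] * m[src[okk], ]
      norm[okk] <- norm[okk] + kern[k]
    }
    out <- out / norm
    ap <- array(out, dp)
    aperm(ap, order(perm))
  }
  for (ax in 1:3) vol <- sm_axis(vol, ax)
  vol
}

#' Spatial smoothing and temporal band-pass of a resting run
#'
#' Each frame is smoothed with an isotropic Gaussian kernel of `fwhm_mm`
#' (separable convolution); each voxel series is then band-pass filtered
#' with a zero-phase Butterworth filter (order 2 forward-backward, 4th-order
#' magnitude response) between `band_hz[1]` and `band_hz[2]`, leaving each
#' voxel approximately zero-mean.
#'
#' @param run a [make_rest_phantom()]-like list with `data` (4-D) and `tr`.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param band_hz length-2 pass band (Hz), inside (0, Nyquist).
#' @param voxel_mm voxel size (mm) for the FWHM conversion.
#' @return the run with filtered `data`.
#' @export
preprocess_rest <- function(run, fwhm_mm = 6, band_hz = c(0.008, 0.1),
                            voxel_mm = 2) {
  fs <- 1 / run$tr
  nyq <- fs / 2
  assert_that(band_hz[1] > 0 && band_hz[2] > band_hz[1] && band_hz[2] < nyq,
              "band edges must satisfy 0 < low < high < Nyquist (",
              round(nyq, 3), " Hz)")
  d <- run$data
  dims <- dim(d)
  t_len <- dims[4]
  if (fwhm_mm > 0) {
    sig <- fwhm_to_sigma(fwhm_mm, voxel_mm)
    for (t in seq_len(t_len))
      d[, , , t] <- gaussian_smooth_volume(d[, , , t], sig)
  }
  bf <- signal::butter(2, band_hz / nyq, type = "pass")
  flat <- matrix(d, ncol = t_len)
  flat <- t(apply(flat, 1, function(x)
    signal::filtfilt(bf, x - mean(x))))
  run$data <- array(flat, dims)
  run
}

#' Seed-based connectivity beta map
#'
#' Per voxel, ordinary least squares of the voxel time series on the mean
#' seed series with nuisance covariates: intercept, global mean series, and
#' the six motion parameters (all demeaned). Returns the coefficient of the
#' seed regressor.
#'
#' @param run list with `data` (4-D), `tr`, `motion_params`, `brain_mask`.
#' @param seed_mask logical array selecting the seed voxels.
#' @param include_global include the global-mean nuisance regressor.
#' @return `seed_beta_map`: list with `beta` (3-D array), `se` (3-D), and
#'   the design column names.
#' @export
seed_connectivity <- function(run, seed_mask, include_global = TRUE) {
  dims <- dim(run$data)
  t_len <- dims[4]
  flat <- matrix(run$data, ncol = t_len)
  sm <- as.vector(seed_mask)
  assert_that(any(sm), "empty seed mask")
  seed_series <- colMeans(flat[sm, , drop = FALSE])
  mask <- if (!is.null(run$brain_mask)) as.vector(run$brain_mask)
  else rep(TRUE, nrow(flat))
  global <- colMeans(flat[mask, , drop = FALSE])
  motion <- as.matrix(run$motion_params)

  dm <- cbind(seed = seed_series - mean(seed_series),
              if (include_global) global - mean(global),
              sweep(motion, 2, colMeans(motion)),
              intercept = 1)
  colnames(dm) <- c("seed", if (include_global) "global",
                    paste0("motion", 1:6), "intercept")
  qrd <- qr(dm)
  if (qrd$rank < ncol(dm)) {
    drop <- colnames(dm)[qrd$pivot[(qrd$rank + 1):ncol(dm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  coefs <- qr.coef(qrd, t(flat))
  resid <- t(flat) - dm %*% coefs
  sigma2 <- colSums(resid^2) / (t_len - ncol(dm))
  xtx_inv_11 <- chol2inv(qr.R(qrd))[1, 1]
  beta <- array(coefs["seed", ], dims[1:3])
  se <- array(sqrt(sigma2 * xtx_inv_11), dims[1:3])
  structure(list(beta = beta, se = se, columns = colnames(dm)),
            class = "seed_beta_map")
}

#' Group one-sample t-map with FDR thresholding
#'
#' Voxelwise one-sample t-test of the betas against zero across subjects,
#' Benjamini-Hochberg corrected over in-mask voxels; zero-variance voxels
#' get p = 1 and are flagged.
#'
#' @param beta_maps list of 3-D beta arrays (one per subject).
#' @param mask logical array of voxels to test (default all).
#' @param alpha corrected significance level.
#' @return list with t (array), p, p_fdr, significant (logical array),
#'   zero_variance (logical array).
#' @export
group_onesample <- function(beta_maps, mask = NULL, alpha = 0.01) {
  assert_that(length(beta_maps) >= 3, "need at least 3 subjects")
  dims <- dim(beta_maps[[1]])
  b <- vapply(beta_maps, as.vector, numeric(prod(dims)))
  if (is.null(mask)) mask <- array(TRUE, dims)
  mv <- as.vector(mask)
  n <- ncol(b)
  mu <- rowMeans(b)
  sdv <- sqrt(rowSums((b - mu)^2) / (n - 1))
  tv <- mu / (sdv / sqrt(n))
  zerovar <- sdv == 0
  pv <- 2 * stats::pt(abs(tv), df = n - 1, lower.tail = FALSE)
  pv[zerovar] <- 1
  p_fdr <- rep(NA_real_, length(pv))
  p_fdr[mv] <- stats::p.adjust(pv[mv], method = "BH")
  sig <- !is.na(p_fdr) & p_fdr < alpha
  list(t = array(tv, dims), p = array(pv, dims),
       p_fdr = array(p_fdr, dims),
       significant = array(sig, dims),
       zero_variance = array(zerovar, dims))
}

# Voxelwise paired one-sided t-test (a > b) across subjects.
paired_t_onesided <- function(maps_a, maps_b) {
  dims <- dim(maps_a[[1]])
  d <- vapply(seq_along(maps_a),
              function(i) as.vector(maps_a[[i]]) - as.vector(maps_b[[i]]),
              numeric(prod(dims)))
  n <- ncol(d)
  mu <- rowMeans(d)
  sdv <- sqrt(rowSums((d - mu)^2) / (n - 1))
  tv <- mu / (sdv / sqrt(n))
  pv <- stats::pt(tv, df = n - 1, lower.tail = FALSE)
  pv[sdv == 0] <- 1
  list(t = tv, p = pv)
}

#' Differentially connected target subdivisions
#'
#' For each seed s, voxels whose connectivity with s exceeds the
#' connectivity with both other seeds: one-sided paired t-tests (s > s')
#' across subjects, each FDR-corrected over in-mask voxels and thresholded
#' at `alpha`, combined with a logical AND, then intersected with
#' `target_mask`. The three resulting masks are pairwise disjoint by
#' construction (opposite strict one-sided tests cannot both reject).
#'
#' @param beta_maps_by_seed named list of 3 lists of per-subject 3-D beta
#'   arrays.
#' @param target_mask logical array (e.g. an anatomical target mask).
#' @param alpha FDR-corrected threshold.
#' @return named list of 3 logical arrays.
#' @export
differential_subdivisions <- function(beta_maps_by_seed, target_mask,
                                      alpha = 0.01) {
  assert_that(length(beta_maps_by_seed) == 3, "need exactly 3 seeds")
  dims <- dim(beta_maps_by_seed[[1]][[1]])
  for (s in beta_maps_by_seed) for (m in s)
    if (!identical(dim(m), dims)) stop("misaligned beta map grids")
  seeds <- names(beta_maps_by_seed) %||% paste0("seed", 1:3)
  names(beta_maps_by_seed) <- seeds
  mv <- as.vector(target_mask)
  out <- list()
  for (s in seeds) {
    others <- setdiff(seeds, s)
    keep <- rep(TRUE, prod(dims))
    for (o in others) {
      tt <- paired_t_onesided(beta_maps_by_seed[[s]], beta_maps_by_seed[[o]])
      p_fdr <- rep(NA_real_, length(tt$p))
      p_fdr[mv] <- stats::p.adjust(tt$p[mv], method = "BH")
      keep <- keep & !is.na(p_fdr) & p_fdr < alpha
    }
    out[[s]] <- array(keep & mv, dims)
  }
  # disjointness is structural; assert it anyway
  overlap <- (as.vector(out[[1]]) + as.vector(out[[2]]) +
                as.vector(out[[3]])) > 1
  stopifnot(!any(overlap))
  out
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays.
#' @return 2|A&B| / (|A|+|B|).
#' @export
dice_coefficient <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
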