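# q-space reconstruction with the anisotropic Hermite-function (MAP) basis.
#
# The normalized signal E(q) is expanded on products of 1-D Hermite functions
#   f_n(x) = H_n(x) exp(-x^2/2) / sqrt(2^n n!),   x_j = 2 pi u_j q_j,
# in the frame of a diffusion-tensor pre-fit, using only basis functions of
# even total order N1+N2+N3 <= radial_order (E(q) = E(-q) for real
# propagators). Each product basis function carries the parity sign
# (-1)^((N1+N2+N3)/2) so that a single Gaussian with matched scales is exactly
# the zeroth basis function. The fit is penalized least squares with the
# analytic q-space Laplacian energy as the smoothness penalty; RTOP follows
# in closed form from the coefficients.

#' Even-order index set of the MAP basis
#'
#' All (N1, N2, N3) with even total order at most `radial_order`. The count is
#' (N/2+1)(N/2+2)(2N+3)/6 (50 at order 6).
#'
#' @param radial_order even non-negative integer.
#' @return data.frame with columns n1, n2, n3.
#' @export
map_index_set <- function(radial_order) {
  assert_that(radial_order >= 0 && radial_order %% 2 == 0,
              "radial_order must be an even non-negative integer")
  idx <- expand.grid(n1 = 0:radial_order, n2 = 0:radial_order,
                     n3 = 0:radial_order)
  tot <- idx$n1 + idx$n2 + idx$n3
  idx <- idx[tot <= radial_order & tot %% 2 == 0, ]
  idx <- idx[order(idx$n1 + idx$n2 + idx$n3, idx$n1, idx$n2), ]
  rownames(idx) <- NULL
  idx
}

# Hermite functions f_0..f_nmax at points x: matrix length(x) x (nmax+1).
hermite_functions <- function(nmax, x) {
  out <- matrix(0, length(x), nmax + 1)
  h_prev <- rep(1, length(x))         # H_0
  out[, 1] <- h_prev
  if (nmax >= 1) {
    h <- 2 * x                         # H_1
    out[, 2] <- h / sqrt(2)
    if (nmax >= 2) for (n in 1:(nmax - 1)) {
      h_next <- 2 * x * h - 2 * n * h_prev
      h_prev <- h
      h <- h_next
      out[, n + 2] <- h / sqrt(2^(n + 1) * factorial(n + 1))
    }
  }
  out * exp(-x^2 / 2)
}

# 1-D moment tables S_k[n, m] = integral x^k f_n(x) f_m(x) dx for k = 0, 2, 4,
# by fine trapezoidal quadrature (integrands are polynomials times exp(-x^2);
# the grid makes these exact to ~1e-12). Cached per nmax.
.map_cache <- new.env(parent = emptyenv())
hermite_moment_tables <- function(nmax) {
  key <- as.character(nmax)
  if (!is.null(.map_cache[[key]])) return(.map_cache[[key]])
  x <- seq(-12, 12, length.out = 6001)
  dx <- x[2] - x[1]
  fv <- hermite_functions(nmax, x)
  tab <- lapply(c(0, 2, 4), function(k) {
    w <- x^k
    crossprod(fv, fv * (w * dx))
  })
  names(tab) <- c("S0", "S2", "S4")
  .map_cache[[key]] <- tab
  tab
}

# Analytic Laplacian penalty matrix U for scales u (length 3):
# U_ab = integral (Lap E_a)(Lap E_b) d^3 q for the signal basis functions.
map_laplacian_penalty <- function(idx, u) {
  nmax <- max(idx$n1, idx$n2, idx$n3)
  tabs <- hermite_moment_tables(nmax)
  two_np1 <- function(n) 2 * n + 1
  # B[n,m] = int f_n'' f_m dx; C[n,m] = int f_n'' f_m'' dx
  # using f_n''(x) = (x^2 - (2n+1)) f_n(x).
  nn <- 0:nmax
  B <- tabs$S2 - outer(two_np1(nn), rep(1, nmax + 1)) * tabs$S0
  C <- tabs$S4 - outer(two_np1(nn), rep(1, nmax + 1)) * tabs$S2 -
    outer(rep(1, nmax + 1), two_np1(nn)) * tabs$S2 +
    outer(two_np1(nn), two_np1(nn)) * tabs$S0
  A <- tabs$S0

  n_coef <- nrow(idx)
  nmat <- as.matrix(idx)          # n_coef x 3
  sgn <- (-1)^(rowSums(nmat) / 2)
  w <- (2 * pi * u)^2             # per-axis Laplacian scale factors
  U <- matrix(0, n_coef, n_coef)
  for (a in seq_len(n_coef)) {
    na <- nmat[a, ]
    for (b in a:n_coef) {
      nb <- nmat[b, ]
      acc <- 0
      for (j in 1:3) for (l in 1:3) {
        term <- w[j] * w[l]
        for (k in 1:3) {
          term <- term * (
            if (j == l && k == j) C[na[k] + 1, nb[k] + 1]
            else if (k == j && j != l) B[na[k] + 1, nb[k] + 1]
            else if (k == l && j != l) B[nb[k] + 1, na[k] + 1]
            else A[na[k] + 1, nb[k] + 1])
        }
        acc <- acc + term
      }
      U[a, b] <- U[b, a] <- sgn[a] * sgn[b] * acc
    }
  }
  U / ((2 * pi)^3 * prod(u))
}

# Design matrix at q-vectors (rows, 1/mm) already rotated into the tensor
# frame, for scales u.
map_design_matrix <- function(idx, q_rot, u) {
  nmax <- max(idx$n1, idx$n2, idx$n3)
  fx <- hermite_functions(nmax, 2 * pi * u[1] * q_rot[, 1])
  fy <- hermite_functions(nmax, 2 * pi * u[2] * q_rot[, 2])
  fz <- hermite_functions(nmax, 2 * pi * u[3] * q_rot[, 3])
  sgn <- (-1)^((idx$n1 + idx$n2 + idx$n3) / 2)
  M <- fx[, idx$n1 + 1, drop = FALSE] *
    fy[, idx$n2 + 1, drop = FALSE] *
    fz[, idx$n3 + 1, drop = FALSE]
  sweep(M, 2, sgn, `*`)
}

# Log-linear diffusion tensor pre-fit; returns eigenvalues (clamped to a
# physiological range) and rotation. Falls back to isotropic scales when the
# fit is degenerate.
tensor_prefit <- function(signal, scheme,
                          lambda_range = c(0.1e-3, 3.0e-3)) {
  sel <- scheme$bvals > 0
  g <- scheme$bvecs[sel, , drop = FALSE]
  b <- scheme$bvals[sel]
  y <- -log(pmax(signal[sel], 1e-8))
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 6))
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  if (anyNA(D)) {
    md <- stats::median(y / b)
    return(list(eigenvalues = rep(clamp(md, lambda_range), 3),
                rotation = diag(3), degenerate = TRUE))
  }
  ed <- eigen(D, symmetric = TRUE)
  lam <- clamp(ed$values, lambda_range)
  rot <- ed$vectors
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  list(eigenvalues = lam, rotation = rot, degenerate = FALSE)
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Fit the MAP signal basis to multi-shell measurements
#'
#' Per voxel: a diffusion-tensor pre-fit supplies the anisotropic scale
#' factors u_j = sqrt(2 tau lambda_j) and the frame rotation; the even-order
#' Hermite product basis is then fit to the normalized signal by penalized
#' least squares with the analytic q-space Laplacian energy as penalty. The
#' regularization weight is chosen by generalized cross-validation over a
#' log-spaced grid, or fixed if a number is supplied.
#'
#' @param signals numeric vector (one voxel) or matrix voxels x measurements,
#'   normalized so that the b0 signal is 1.
#' @param scheme an [make_acquisition_scheme()] scheme (>= 2 shells).
#' @param radial_order even integer >= 0 (default 6, 50 coefficients).
#' @param regularization `"gcv"` or a non-negative numeric weight.
#' @return `map_basis_fit`: coefficients (voxels x n_coef), per-voxel scale
#'   factors (mm), rotations, fit residual rms, predicted E(0), the index set
#'   and `tau`.
#' @export
fit_map_basis <- function(signals, scheme, radial_order = 6,
                          regularization = "gcv") {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  assert_that(radial_order >= 0 && radial_order %% 2 == 0,
              "radial_order must be even (got ", radial_order, ")")
  n_shell <- length(unique(scheme$bvals[scheme$bvals > 0]))
  assert_that(n_shell >= 2, "need at least 2 non-zero shells, got ", n_shell)
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  idx <- map_index_set(radial_order)
  n_coef <- nrow(idx)
  n_meas <- length(scheme$bvals)
  if (n_meas < n_coef)
    stop("rank error: ", n_meas, " measurements cannot determine ", n_coef,
         " coefficients at radial order ", radial_order,
         "; need at least ", n_coef, " measurements")

  qvec <- scheme$q_magnitudes * scheme$bvecs
  n_vox <- nrow(signals)
  coefs <- matrix(NA_real_, n_vox, n_coef)
  scales <- matrix(NA_real_, n_vox, 3)
  rotations <- vector("list", n_vox)
  resid_rms <- numeric(n_vox)
  e0 <- numeric(n_vox)
  lambda_used <- numeric(n_vox)

  lam_grid <- 10^seq(-10, 0, length.out = 12)
  for (v in seq_len(n_vox)) {
    y <- signals[v, ]
    pf <- tensor_prefit(y, scheme)
    u <- sqrt(2 * scheme$tau * pf$eigenvalues)
    q_rot <- qvec %*% pf$rotation    # components in the tensor frame
    M <- map_design_matrix(idx, q_rot, u)
    U <- map_laplacian_penalty(idx, u)
    MtM <- crossprod(M)
    Mty <- crossprod(M, y)
    # scale penalty so the grid is comparable across voxels
    u_scale <- sum(diag(MtM)) / max(sum(diag(U)), 1e-300)
    Us <- U * u_scale
    if (is.numeric(regularization)) {
      lam <- regularization
      cf <- solve(MtM + lam * Us, Mty)
    } else {
      best <- Inf; cf <- NULL; lam <- 0
      for (l in lam_grid) {
        A <- tryCatch(solve(MtM + l * Us), error = function(e) NULL)
        if (is.null(A)) next
        cf_l <- A %*% Mty
        r <- y - as.vector(M %*% cf_l)
        tr_h <- sum((M %*% A) * M)
        gcv <- n_meas * sum(r^2) / (n_meas - tr_h)^2
        if (gcv < best) { best <- gcv; cf <- cf_l; lam <- l }
      }
      if (is.null(cf)) stop("penalized normal equations singular for voxel ", v)
    }
    coefs[v, ] <- cf
    scales[v, ] <- u
    rotations[[v]] <- pf$rotation
    resid_rms[v] <- sqrt(mean((y - as.vector(M %*% cf))^2))
    e0[v] <- map_e0(cf, idx)
    lambda_used[v] <- lam
  }
  structure(list(coefficients = coefs, scales = scales, rotations = rotations,
                 fit_residual = resid_rms, e0 = e0,
                 regularization_weight = lambda_used,
                 index_set = idx, radial_order = radial_order,
                 tau = scheme$tau),
            class = "map_basis_fit")
}

# Predicted E(0) from coefficients: f_n(0) = (-1)^(n/2) sqrt(n!)/(2^(n/2) (n/2)!)
# for even n, 0 for odd; the axis signs multiply to (-1)^(M/2), which cancels
# the basis parity sign, so the E(0) weights are simply positive.
map_e0 <- function(cf, idx) {
  w <- axis_zero_weight(idx$n1) * axis_zero_weight(idx$n2) *
    axis_zero_weight(idx$n3)
  sum(cf * w)
}

axis_zero_weight <- function(n) {
  ifelse(n %% 2 == 0, sqrt(factorial(n)) / (2^(n / 2) * factorial(n / 2)), 0)
}

#' Predict the fitted signal at arbitrary q-vectors
#'
#' @param fit a [fit_map_basis()] result.
#' @param qvec matrix of q-vectors (rows, 1/mm) in scanner coordinates.
#' @param voxel voxel index.
#' @return predicted attenuations.
#' @export
map_predict <- function(fit, qvec, voxel = 1) {
  q_rot <- qvec %*% fit$rotations[[voxel]]
  M <- map_design_matrix(fit$index_set, q_rot, fit$scales[voxel, ])
  as.vector(M %*% fit$coefficients[voxel, ])
}

#' Analytic RTOP from a MAP basis fit
#'
#' RTOP = integral of the fitted E(q) over q-space, which for the Hermite
#' product basis is a signed (parity-weighted) sum over the all-even-index
#' coefficients divided by the scale volume:
#' RTOP = sum_a c_a (-1)^(Ma/2) prod_j sqrt(Nj!)/(2^(Nj/2) (Nj/2)!) /
#'        ((2 pi)^(3/2) u1 u2 u3).
#'
#' @param fit a [fit_map_basis()] result.
#' @return numeric vector, RTOP per voxel (mm^-3).
#' @export
rtop_from_fit <- function(fit) {
  idx <- fit$index_set
  all_even <- idx$n1 %% 2 == 0 & idx$n2 %% 2 == 0 & idx$n3 %% 2 == 0
  w <- axis_zero_weight(idx$n1) * axis_zero_weight(idx$n2) *
    axis_zero_weight(idx$n3)
  sgn <- (-1)^((idx$n1 + idx$n2 + idx$n3) / 2)
  wt <- ifelse(all_even, sgn * w, 0)
  num <- as.vector(fit$coefficients %*% wt)
  num * (2 * pi)^(3 / 2) / ((2 * pi)^3 * apply(fit$scales, 1, prod))
}

#' Normalize RTOP against free diffusion
#'
#' The normalized index is the ratio of tissue RTOP to the RTOP of freely
#' diffusing water at the same diffusion time:
#' normalized = rtop * (4 pi tau D_free)^(3/2). Equals 1 for free water.
#'
#' @param rtop RTOP values (mm^-3).
#' @param free_diffusivity free-water diffusivity (mm^2/s), default 3.0e-3
#'   (water at body temperature).
#' @param tau diffusion time (s).
#' @return unitless normalized RTOP.
#' @examples
#' normalize_rtop((4 * pi * 0.04 * 3e-3)^(-1.5), 3e-3, 0.04)  # 1
#' @export
normalize_rtop <- function(rtop, free_diffusivity = 3.0e-3, tau) {
  assert_that(free_diffusivity > 0, "free_diffusivity must be > 0")
  assert_that(tau > 0, "tau must be > 0")
  rtop * (4 * pi * tau * free_diffusivity)^(3 / 2)
}

erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Rician bias correction via smoothed-signal inversion
#'
#' Magnitude MRI noise is Rician, which inflates weak signals toward the
#' noise floor and biases RTOP. Per voxel this routine (i) fits the MAP basis
#' to the raw signal, which averages the noise over all measurements, (ii)
#' estimates the noise level sigma from the robust spread (1.4826 mad) of the
#' fit residuals, and (iii) replaces each measurement by the asymptotic
#' inversion of the Rician mean applied to the smoothed prediction,
#' sqrt(max(pred^2 - sigma^2, 0)), renormalized to the corrected b0. The
#' inversion acts on smoothed values, so it does not amplify per-measurement
#' noise; it is essentially unbiased wherever the local SNR exceeds about 2
#' and is a no-op on noiseless data (sigma below `sigma_min`).
#'
#' @param signals voxel x measurement matrix (or vector), b0-normalized.
#' @param scheme the acquisition scheme.
#' @param radial_order,regularization passed to the preliminary fit.
#' @param sigma_min noise level (relative to b0 = 1) below which the data are
#'   treated as noiseless.
#' @return list with `signals` (corrected matrix), `sigma` (per voxel) and
#'   `corrected` (logical per voxel).
#' @export
rician_correct <- function(signals, scheme, radial_order = 6,
                           regularization = "gcv", sigma_min = 1e-4) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  fit <- fit_map_basis(signals, scheme, radial_order, regularization)
  qvec <- scheme$q_magnitudes * scheme$bvecs
  b0 <- scheme$bvals == 0
  out <- signals
  sigma <- numeric(nrow(signals))
  corrected <- logical(nrow(signals))
  for (v in seq_len(nrow(signals))) {
    pred <- map_predict(fit, qvec, v)
    sigma[v] <- 1.4826 * stats::mad(signals[v, ] - pred, center = 0)
    if (!is.finite(sigma[v]) || sigma[v] < sigma_min) next
    corr <- sqrt(pmax(pred^2 - sigma[v]^2, 0))
    s0 <- mean(corr[b0])
    if (s0 > 0) {
      out[v, ] <- corr / s0
      corrected[v] <- TRUE
    }
  }
  list(signals = out, sigma = sigma, corrected = corrected,
       preliminary_fit = fit)
}

# Radial tail integral_Q^inf q^2 exp(-4 pi^2 tau D q^2) dq (closed form).
radial_gaussian_tail <- function(D, tau, q_max) {
  a <- 4 * pi^2 * tau * D
  sqrt(pi) / (4 * a^1.5) * erfc(sqrt(a) * q_max) +
    q_max / (2 * a) * exp(-a * q_max^2)
}

#' Unsampled q-space tail of the RTOP integral
#'
#' RTOP is the integral of E(q) over all of q-space, but measurements only
#' constrain the ball |q| <= q_max set by the largest b-value; for voxels
#' containing slowly diffusing pools a substantial share of the integral lies
#' outside that ball, where the fitted basis decays too quickly. The tail is
#' therefore estimated by per-direction radial extrapolation: along each of
#' `n_dirs` directions the fitted signal is sampled at four equally spaced
#' b-values (0 to b_max), the unique biexponential through those samples is
#' recovered with Prony's method (exact for any two-compartment profile, a
#' close bound otherwise), its diffusivities are clamped to a physiological
#' range, and the analytic radial Gaussian tail of each exponential is
#' accumulated over the sphere. Complete monotonicity of the directional
#' signal requires the biexponential weights to be non-negative and sum to at
#' most E(0); directions violating this, or whose Prony roots are complex or
#' out of range, fall back to terminal-slope mono-exponential extrapolation.
#' The default diffusivity floor (0.1e-3 mm^2/s) is the slowest apparent
#' diffusivity plausible in tissue at body temperature and bounds the tail
#' amplification under noise.
#'
#' @param fit a [fit_map_basis()] result.
#' @param scheme the acquisition scheme used for the fit.
#' @param n_dirs number of directions of the spherical quadrature rule.
#' @param d_range admissible diffusivity range for extrapolation (mm^2/s).
#' @return numeric vector: tail contribution to RTOP (mm^-3) per voxel.
#' @export
rtop_tail_estimate <- function(fit, scheme, n_dirs = 256,
                               d_range = c(0.1e-3, 3.5e-3)) {
  tau <- fit$tau
  b_max <- max(scheme$bvals)
  q_max <- max(scheme$q_magnitudes)
  db <- b_max / 3
  bs <- seq(0, b_max, length.out = 4)
  qs <- sqrt(bs / tau) / (2 * pi)
  dirs <- fibonacci_sphere(n_dirs)
  # all sample points for one voxel: 4 radii x n_dirs
  qpts <- dirs[rep(seq_len(n_dirs), each = 4), ] * rep(qs, times = n_dirs)
  n_vox <- nrow(fit$coefficients)
  tails <- numeric(n_vox)
  for (v in seq_len(n_vox)) {
    e_all <- matrix(map_predict(fit, qpts, v), nrow = 4)
    e_all[1, ] <- fit$e0[v]
    tot <- 0
    for (d in seq_len(n_dirs)) {
      e <- e_all[, d]
      td <- NA_real_
      det2 <- e[1] * e[3] - e[2]^2
      if (is.finite(det2) && abs(det2) > 1e-14) {
        # Prony: rho^2 + c2 rho + c1 = 0 with [e1 e2; e2 e3] c = -[e3; e4]
        c1 <- (-e[3] * e[3] + e[2] * e[4]) / det2
        c2 <- (-e[1] * e[4] + e[2] * e[3]) / det2
        disc <- c2^2 - 4 * c1
        if (is.finite(disc) && disc >= 0) {
          rho <- (-c2 + c(1, -1) * sqrt(disc)) / 2
          if (all(rho > 1e-8 & rho < 1)) {
            D <- clamp(-log(rho) / db, d_range)
            A <- rbind(rep(1, 2), rho, rho^2, rho^3)
            w <- qr.coef(qr(A), e)
            if (all(is.finite(w)) && all(w > -1e-3) && sum(w) < 1.05)
              td <- sum(pmax(w, 0) * radial_gaussian_tail(D, tau, q_max))
          }
        }
      }
      if (!is.finite(td)) {
        # terminal-slope mono-exponential fallback
        if (e[3] > 0 && e[4] > 0 && e[4] < e[3]) {
          D <- clamp(log(e[3] / e[4]) / db, d_range)
          td <- e[4] * exp(b_max * D) * radial_gaussian_tail(D, tau, q_max)
        } else td <- 0
      }
      tot <- tot + max(td, 0)
    }
    tails[v] <- tot * 4 * pi / n_dirs
  }
  tails
}

# Integral of the fitted signal over the sampled ball |q| <= q_max, by
# Gauss-Legendre radial quadrature times a Fibonacci spherical rule.
map_inball_integral <- function(fit, voxel, q_max, n_radial = 32,
                                n_dirs = 256) {
  gl <- gauss_legendre(n_radial, 0, q_max)
  dirs <- fibonacci_sphere(n_dirs)
  qpts <- dirs[rep(seq_len(n_dirs), times = n_radial), ] *
    rep(gl$x, each = n_dirs)
  ev <- map_predict(fit, qpts, voxel)
  ev <- matrix(ev, nrow = n_dirs)
  sum(gl$w * gl$x^2 * colMeans(ev)) * 4 * pi
}

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix on [-1, 1].
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (b + a) / 2, w = (b - a) / 2 * w)
}

#' Per-voxel normalized RTOP map from multi-shell signals
#'
#' The package's RTOP estimator: MAP basis fit, then RTOP as the integral of
#' the fitted signal over the sampled q-ball plus the per-direction
#' biexponential extrapolation of the unsampled tail
#' ([rtop_tail_estimate()]), normalized against free water. With
#' `tail_correction = FALSE` the purely analytic basis-coefficient RTOP
#' ([rtop_from_fit()]) is used instead, which underestimates voxels with
#' slowly diffusing pools whose q-space support extends beyond the
#' acquisition. Voxels whose estimated RTOP is non-positive are flagged (not
#' silently clamped) so downstream region means can exclude them.
#'
#' @inheritParams fit_map_basis
#' @param free_diffusivity free-water diffusivity (mm^2/s).
#' @param tail_correction estimate the out-of-ball tail (default TRUE).
#' @param rician_correction moment-based Rician bias correction using the
#'   noise level estimated from the b0 repeats (needs >= 3 b0 measurements; a
#'   no-op on noiseless data).
#' @return `rtop_map`: list with `rtop` (mm^-3), `normalized_rtop`, `valid`
#'   flag per voxel, the fit, and `free_diffusivity`.
#' @export
compute_rtop_map <- function(signals, scheme, radial_order = 6,
                             regularization = "gcv",
                             free_diffusivity = 3.0e-3,
                             tail_correction = TRUE,
                             rician_correction = TRUE) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  fit <- NULL
  if (rician_correction) {
    rc <- rician_correct(signals, scheme, radial_order, regularization)
    if (any(rc$corrected)) signals <- rc$signals
    else fit <- rc$preliminary_fit   # clean data: reuse the fit
  }
  if (is.null(fit))
    fit <- fit_map_basis(signals, scheme, radial_order, regularization)
  if (tail_correction) {
    q_max <- max(scheme$q_magnitudes)
    tails <- rtop_tail_estimate(fit, scheme)
    inball <- vapply(seq_len(nrow(signals)), function(v)
      map_inball_integral(fit, v, q_max), numeric(1))
    rtop <- inball + tails
  } else {
    rtop <- rtop_from_fit(fit)
  }
  structure(list(rtop = rtop,
                 normalized_rtop = normalize_rtop(rtop, free_diffusivity,
                                                  scheme$tau),
                 valid = is.finite(rtop) & rtop > 0,
                 fit = fit, free_diffusivity = free_diffusivity,
                 tau = scheme$tau),
            class = "rtop_map")
}
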