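#' Gaussian diffusion compartment
#'
#' A single Gaussian compartment of a multi-compartment voxel: a volume
#' fraction and a symmetric positive-definite diffusion tensor (mm^2/s).
#' Mixtures of such compartments have a closed-form return-to-origin
#' probability, which makes them exact oracles for the basis-fit estimator.
#'
#' @param volume_fraction fraction in (0, 1].
#' @param diffusion_tensor 3x3 symmetric positive-definite matrix (mm^2/s), or
#'   a single number for an isotropic tensor.
#' @return object of class `gaussian_compartment`.
#' @examples
#' gaussian_compartment(1, 3.0e-3)        # free water at body temperature
#' gaussian_compartment(0.5, diag(c(1.7, 0.3, 0.3)) * 1e-3)
#' @export
gaussian_compartment <- function(volume_fraction, diffusion_tensor) {
  if (length(diffusion_tensor) == 1)
    diffusion_tensor <- diag(3) * diffusion_tensor
  diffusion_tensor <- as.matrix(diffusion_tensor)
  assert_that(volume_fraction > 0 && volume_fraction <= 1,
              "volume_fraction must be in (0, 1]")
  assert_that(all(dim(diffusion_tensor) == c(3, 3)),
              "diffusion_tensor must be 3x3")
  assert_that(max(abs(diffusion_tensor - t(diffusion_tensor))) < 1e-12,
              "diffusion_tensor must be symmetric")
  ev <- eigen(diffusion_tensor, symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ev > 0), "diffusion_tensor must be positive-definite")
  structure(list(volume_fraction = volume_fraction,
                 diffusion_tensor = diffusion_tensor),
            class = "gaussian_compartment")
}

check_compartments <- function(compartments) {
  if (inherits(compartments, "gaussian_compartment"))
    compartments <- list(compartments)
  assert_that(length(compartments) >= 1, "need at least one compartment")
  fr <- vapply(compartments, function(c) c$volume_fraction, numeric(1))
  assert_that(abs(sum(fr) - 1) < 1e-9, "volume fractions must sum to 1")
  compartments
}

#' Simulate the diffusion signal attenuation of a multi-compartment voxel
#'
#' Noiseless attenuation is the Gaussian mixture
#' E(b, g) = sum_i f_i exp(-b g' D_i g), so E = 1 at b = 0. With `snr` given,
#' Rician noise is applied (magnitude-MRI convention): the noiseless value is
#' perturbed by two independent Gaussian channels of standard deviation
#' 1/snr (SNR defined on the b0 signal) and the magnitude is returned.
#'
#' @param scheme an [make_acquisition_scheme()] object.
#' @param compartments list of [gaussian_compartment()] (fractions sum to 1).
#' @param snr b0 signal-to-noise ratio, or `NULL` for a noiseless signal.
#' @param seed integer seed for the noise draw.
#' @return numeric vector of attenuations, one per scheme measurement.
#' @examples
#' sch <- make_acquisition_scheme(1000, 12, 1, 10, 43, seed = 1)
#' sig <- simulate_voxel_signal(sch, list(gaussian_compartment(1, 3e-3)))
#' all.equal(unique(round(sig[-1], 6)), round(exp(-3), 6))
#' @export
simulate_voxel_signal <- function(scheme, compartments, snr = NULL, seed = 1L) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  compartments <- check_compartments(compartments)
  assert_that(is.null(snr) || snr > 0, "snr must be NULL or > 0")

  g <- scheme$bvecs
  b <- scheme$bvals
  e <- numeric(length(b))
  for (cp in compartments) {
    quad <- rowSums((g %*% cp$diffusion_tensor) * g)  # g' D g
    e <- e + cp$volume_fraction * exp(-b * quad)
  }
  if (is.null(snr)) return(e)
  sigma <- 1 / snr
  with_seed(seed, {
    n1 <- stats::rnorm(length(e), sd = sigma)
    n2 <- stats::rnorm(length(e), sd = sigma)
    sqrt((e + n1)^2 + n2^2)
  })
}

#' Closed-form RTOP of a Gaussian-mixture voxel
#'
#' For a mixture of Gaussian compartments the return-to-origin probability at
#' diffusion time tau is sum_i f_i (4 pi tau)^(-3/2) det(D_i)^(-1/2) (mm^-3).
#' Serves as the exact oracle for the basis-fit RTOP estimator; strictly
#' decreasing in any compartment's eigenvalues.
#'
#' @param compartments list of [gaussian_compartment()].
#' @param tau diffusion time (s).
#' @return RTOP in mm^-3.
#' @examples
#' rtop_oracle(list(gaussian_compartment(1, 3e-3)), tau = 0.0397)
#' @export
rtop_oracle <- function(compartments, tau) {
  compartments <- check_compartments(compartments)
  assert_that(tau > 0, "tau must be > 0")
  sum(vapply(compartments, function(cp) {
    cp$volume_fraction * (4 * pi * tau)^(-1.5) / sqrt(det(cp$diffusion_tensor))
  }, numeric(1)))
}

#' Random Gaussian-mixture voxel
#'
#' Draws a voxel with 1-3 Gaussian compartments with random orientations,
#' eigenvalues spanning a broad physiological range (0.2e-3 to 2.8e-3
#' mm^2/s, from restricted pools to near-free water), and Dirichlet-ish
#' volume fractions. This is the stress-test population for the RTOP
#' estimator oracle comparisons; see [random_gm_mixture()] for the
#' gray-matter tissue model used by the volumetric phantom.
#'
#' @param n_compartments number of compartments (default random 1-3).
#' @param seed integer seed.
#' @return list of [gaussian_compartment()].
#' @export
random_mixture <- function(n_compartments = NULL, seed = 1L) {
  with_seed(seed, {
    k <- n_compartments %||% sample(1:3, 1)
    fr <- stats::rgamma(k, 2); fr <- fr / sum(fr)
    lapply(seq_len(k), function(i) {
      ev <- stats::runif(3, 0.2e-3, 2.8e-3)
      r <- random_rotation()
      gaussian_compartment(fr[i], r %*% diag(ev) %*% t(r))
    })
  })
}

#' Random cortical gray-matter voxel
#'
#' Tissue model for the volumetric phantom: 2-3 Gaussian compartments with
#' per-compartment mean diffusivity in the cortical gray-matter range
#' (0.5e-3 to 1.3e-3 mm^2/s), mild anisotropy, and (with probability 0.3) a
#' small free-water fraction (2-10%) emulating CSF partial volume at the
#' pial boundary.
#'
#' @param seed integer seed.
#' @param md_range per-compartment mean diffusivity range (mm^2/s).
#' @return list of [gaussian_compartment()].
#' @export
random_gm_mixture <- function(seed = 1L, md_range = c(0.5e-3, 1.3e-3)) {
  with_seed(seed, {
    k <- sample(1:2, 1) + 1
    fr <- stats::rgamma(k, 4); fr <- fr / sum(fr)
    cps <- lapply(seq_len(k), function(i) {
      md <- stats::runif(1, md_range[1], md_range[2])
      shape <- stats::runif(3, 0.6, 1.4)
      ev <- md * 3 * shape / sum(shape)
      r <- random_rotation()
      gaussian_compartment(fr[i], r %*% diag(ev) %*% t(r))
    })
    if (stats::runif(1) < 0.3) {
      fw <- stats::runif(1, 0.02, 0.10)
      cps <- lapply(cps, function(cp)
        gaussian_compartment(cp$volume_fraction * (1 - fw),
                             cp$diffusion_tensor))
      cps <- c(cps, list(gaussian_compartment(fw, 3.0e-3)))
    }
    cps
  })
}

#' Volumetric diffusion phantom with known ground-truth RTOP
#'
#' A small voxel grid of gray-matter-like mixtures ([random_gm_mixture()])
#' whose mean diffusivity decreases linearly along x, so ground-truth
#' normalized RTOP increases anteriorly-to-posteriorly like the insular
#' sheet it feeds. Returns signals, the voxelwise ground-truth RTOP, and the
#' world-coordinate affine (2 mm isotropic, origin at the first voxel
#' center).
#'
#' @param grid_shape integer 3-vector.
#' @param scheme acquisition scheme.
#' @param snr b0 SNR for Rician noise, or NULL for noiseless.
#' @param voxel_size_mm isotropic voxel size.
#' @param seed integer seed.
#' @return `dmri_phantom`: list with `signals` (voxels x measurements),
#'   `grid_shape`, `affine`, `truth_rtop`, `truth_normalized_rtop`,
#'   `mixtures`.
#' @export
make_dmri_phantom <- function(grid_shape = c(6, 6, 4), scheme,
                              snr = NULL, voxel_size_mm = 2, seed = 1L) {
  n_vox <- prod(grid_shape)
  md_lo <- 0.6e-3; md_hi <- 1.2e-3
  ix <- arrayInd(seq_len(n_vox), grid_shape)
  # faster diffusion (lower RTOP) anterior (low x), slower posterior
  md_mid <- md_lo + (ix[, 1] - 1) / max(grid_shape[1] - 1, 1) *
    (md_hi - md_lo)
  mixtures <- lapply(seq_len(n_vox), function(v)
    random_gm_mixture(seed = seed + v,
                      md_range = sort(c(0.85, 1.15)) * md_mid[v]))
  signals <- t(vapply(seq_len(n_vox), function(v)
    simulate_voxel_signal(scheme, mixtures[[v]], snr = snr,
                          seed = seed + 31L * v),
    numeric(length(scheme$bvals))))
  truth <- vapply(mixtures, rtop_oracle, numeric(1), tau = scheme$tau)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  structure(list(signals = signals, grid_shape = grid_shape,
                 affine = affine, truth_rtop = truth,
                 truth_normalized_rtop = normalize_rtop(truth, 3.0e-3,
                                                        scheme$tau),
                 mixtures = mixtures),
            class = "dmri_phantom")
}
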