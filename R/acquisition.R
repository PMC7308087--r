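#' Build a multi-shell diffusion acquisition scheme
#'
#' Creates an HCP-like multi-shell pulsed-gradient scheme: `n_b0` b = 0
#' measurements followed by `dirs_per_shell` approximately uniform gradient
#' directions on each shell. Directions are laid out with a Fibonacci spiral
#' (hemisphere-symmetrized by construction of diffusion encoding) and each
#' shell receives an independent seeded random rotation so shells do not share
#' directions. The effective diffusion time is tau = Delta - delta/3.
#'
#' @param b_values numeric vector of positive, distinct b-values (s/mm^2).
#' @param dirs_per_shell number of gradient directions per shell.
#' @param n_b0 number of b = 0 measurements.
#' @param small_delta gradient pulse duration delta (ms).
#' @param big_delta pulse separation Delta (ms); must exceed `small_delta`.
#' @param seed integer seed controlling the per-shell rotations.
#' @return An object of class `acquisition_scheme`: list with `bvals` (s/mm^2,
#'   one per measurement), `bvecs` (measurements x 3 unit rows; zero rows for
#'   b = 0), `small_delta`, `big_delta` and `tau` (all seconds), and
#'   `q_magnitudes` (1/mm), where q = sqrt(b / tau) / (2*pi).
#' @examples
#' sch <- make_acquisition_scheme(c(1000, 2000, 3000), 90, 6, 10, 43, seed = 1)
#' length(sch$bvals)  # 276
#' sch$tau            # 0.039667 s
#' @export
make_acquisition_scheme <- function(b_values = c(1000, 2000, 3000),
                                    dirs_per_shell = 90, n_b0 = 6,
                                    small_delta = 10, big_delta = 43,
                                    seed = 1L) {
  assert_that(length(b_values) >= 1 && all(b_values > 0),
              "b_values must be positive")
  assert_that(!anyDuplicated(b_values), "b_values must be distinct")
  assert_that(dirs_per_shell >= 1, "dirs_per_shell must be >= 1")
  assert_that(n_b0 >= 0, "n_b0 must be >= 0")
  assert_that(small_delta > 0 && big_delta > small_delta,
              "need big_delta > small_delta > 0")

  tau <- (big_delta - small_delta / 3) / 1000  # ms -> s

  dirs <- with_seed(seed, {
    lapply(seq_along(b_values), function(i) {
      d <- fibonacci_sphere(dirs_per_shell)
      d %*% t(random_rotation())
    })
  })

  bvals <- c(rep(0, n_b0), rep(b_values, each = dirs_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3), do.call(rbind, dirs))
  structure(list(
    bvals = bvals,
    bvecs = bvecs,
    shell = c(rep(0L, n_b0), rep(seq_along(b_values), each = dirs_per_shell)),
    small_delta = small_delta / 1000,
    big_delta = big_delta / 1000,
    tau = tau,
    q_magnitudes = sqrt(bvals / tau) / (2 * pi)
  ), class = "acquisition_scheme")
}

# Fibonacci spiral points on the unit sphere (deterministic).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  shells <- sort(unique(x$bvals[x$bvals > 0]))
  cat("Multi-shell acquisition scheme\n")
  cat(sprintf("  measurements: %d (%d b0)\n", length(x$bvals), sum(x$bvals == 0)))
  cat(sprintf("  shells (s/mm^2): %s\n", paste(shells, collapse = ", ")))
  cat(sprintf("  delta = %.4g s, Delta = %.4g s, tau = %.6g s\n",
              x$small_delta, x$big_delta, x$tau))
  invisible(x)
}
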