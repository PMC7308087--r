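# Shared fixtures and independent oracles.

# Small HCP-like scheme reused across tests (fewer directions for speed
# where full angular resolution is not the point).
test_scheme <- function(dirs = 90, n_b0 = 6) {
  make_acquisition_scheme(c(1000, 2000, 3000), dirs, n_b0, 10, 43, seed = 1)
}

# Brute-force numeric integral of the true mixture signal over q-space
# (spherical product quadrature out to many sigmas). Independent of the
# basis-fit path.
quadrature_rtop_truth <- function(compartments, tau, n_r = 160, n_dir = 400,
                                  r_max_factor = 8) {
  lam_min <- min(vapply(compartments, function(cp)
    min(eigen(cp$diffusion_tensor, symmetric = TRUE,
              only.values = TRUE)$values), numeric(1)))
  sigma_q <- 1 / sqrt(8 * pi^2 * tau * lam_min)
  r_max <- r_max_factor * sigma_q
  gl_r <- rtopmap:::gauss_legendre(n_r, 0, r_max)
  dirs <- rtopmap:::fibonacci_sphere(n_dir)
  tot <- 0
  for (cp in compartments) {
    quad <- rowSums((dirs %*% cp$diffusion_tensor) * dirs)
    ev <- vapply(gl_r$x, function(r)
      mean(exp(-4 * pi^2 * tau * r^2 * quad)), numeric(1))
    tot <- tot + cp$volume_fraction * 4 * pi * sum(gl_r$w * gl_r$x^2 * ev)
  }
  tot
}

# Numeric integral of the FITTED signal over q-space (for the analytic
# rtop_from_fit equivalence check).
quadrature_rtop_fitted <- function(fit, voxel, n_r = 200, n_dir = 400,
                                   r_max = NULL) {
  u_min <- min(fit$scales[voxel, ])
  r_max <- r_max %||% (10 / (2 * pi * u_min))
  gl_r <- rtopmap:::gauss_legendre(n_r, 0, r_max)
  dirs <- rtopmap:::fibonacci_sphere(n_dir)
  qpts <- dirs[rep(seq_len(n_dir), times = n_r), ] *
    rep(gl_r$x, each = n_dir)
  ev <- matrix(map_predict(fit, qpts, voxel), nrow = n_dir)
  4 * pi * sum(gl_r$w * gl_r$x^2 * colMeans(ev))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Rician mean, E[sqrt((nu+n1)^2 + n2^2)] with n ~ N(0, sigma^2):
# sigma sqrt(pi/2) L_{1/2}(-nu^2 / (2 sigma^2)), via scaled Bessel functions.
rician_mean_oracle <- function(nu, sigma) {
  t <- nu^2 / (2 * sigma^2)
  h <- t / 2
  sigma * sqrt(pi / 2) *
    ((1 + t) * besselI(h, 0, expon.scaled = TRUE) +
       t * besselI(h, 1, expon.scaled = TRUE))
}

# von Mises-Fisher sample around mu with concentration kappa (Ulrich/Wood).
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal frame around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(pmax(0, 1 - w^2))
  t(vapply(seq_len(n), function(i)
    w[i] * mu + s[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2), numeric(3)))
}

# Multi-subject parcel summary with planted subdivision and hemisphere
# effects (subject random intercepts + iid noise).
mk_parcel_summary <- function(n_subjects, effect = c(vAI = 1, dAI = 2, PI = 3),
                              hemisphere_effect = 0.1, noise_sd = 0.5,
                              subject_sd = 0.3, seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = sprintf("s%03d", seq_len(n_subjects)),
                   hemisphere = c("left", "right"),
                   subdivision = names(effect), stringsAsFactors = FALSE)
  g$mean_rtop <- effect[g$subdivision] +
    ifelse(g$hemisphere == "right", -hemisphere_effect, 0) +
    rep(rnorm(n_subjects, sd = subject_sd), length.out = nrow(g)) +
    rnorm(nrow(g), sd = noise_sd)
  g
}

# From-scratch two-way repeated-measures ANOVA by explicit sums of squares
# (independent of stats::aov). Balanced designs only.
rm_anova_by_hand <- function(summary) {
  subj <- factor(summary$subject)
  A <- factor(summary$subdivision)   # a levels
  B <- factor(summary$hemisphere)    # b levels
  y <- summary$mean_rtop
  n <- nlevels(subj); a <- nlevels(A); b <- nlevels(B)
  gm <- mean(y)
  mean_by <- function(f) tapply(y, f, mean)
  ss <- function(m, mult) mult * sum((m - gm)^2)
  ss_A <- ss(mean_by(A), n * b)
  ss_B <- ss(mean_by(B), n * a)
  ss_S <- ss(mean_by(subj), a * b)
  m_AB <- tapply(y, list(A, B), mean)
  ss_AB <- n * sum((m_AB - outer(mean_by(A) - gm, mean_by(B) - gm, `+`) - gm)^2)
  m_AS <- tapply(y, list(A, subj), mean)
  ss_AS <- b * sum((m_AS - outer(mean_by(A) - gm, mean_by(subj) - gm, `+`) - gm)^2)
  m_BS <- tapply(y, list(B, subj), mean)
  ss_BS <- a * sum((m_BS - outer(mean_by(B) - gm, mean_by(subj) - gm, `+`) - gm)^2)
  ss_T <- sum((y - gm)^2)
  ss_ABS <- ss_T - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS
  f_A <- (ss_A / (a - 1)) / (ss_AS / ((a - 1) * (n - 1)))
  f_B <- (ss_B / (b - 1)) / (ss_BS / ((b - 1) * (n - 1)))
  f_AB <- (ss_AB / ((a - 1) * (b - 1))) / (ss_ABS / ((a - 1) * (b - 1) * (n - 1)))
  data.frame(effect = c("subdivision", "hemisphere",
                        "subdivision:hemisphere"),
             F = c(f_A, f_B, f_AB),
             df_num = c(a - 1, b - 1, (a - 1) * (b - 1)),
             df_den = c((a - 1) * (n - 1), (b - 1) * (n - 1),
                        (a - 1) * (b - 1) * (n - 1)))
}
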