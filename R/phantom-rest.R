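# Resting-state phantom: a small 4-D volume with three seed regions and
# three disjoint target ("ACC") zones, each target coupled to exactly one
# seed's time series, plus a weak global component and realistic slow motion
# drift. The planted seed -> target correlation ordering is strict by
# construction.

#' Resting-state connectivity phantom
#'
#' The grid is split into a "seed slab" (low x) holding three cubic seed
#' regions and a "target slab" (high x) holding three disjoint target zones.
#' Each target voxel's series is `coupling * seed_series + sqrt(1 -
#' coupling^2) * noise`; every voxel additionally receives a weak global
#' component (`global_amp`) so nuisance regression has work to do. Motion
#' parameters are smooth small drifts well below standard exclusion
#' thresholds.
#'
#' @param grid_shape integer 3-vector of volume dimensions.
#' @param n_timepoints number of frames (>= 100).
#' @param tr repetition time (s).
#' @param coupling seed-target correlation strength in [0, 1).
#' @param global_amp amplitude of the shared global signal.
#' @param seed integer seed.
#' @return `rest_phantom`: list with `data` (4-D array), `tr`,
#'   `motion_params` (frames x 6; translations mm, rotations rad),
#'   `seed_masks` and `target_masks` (lists of 3 logical arrays, names
#'   vAI/dAI/PI), `brain_mask`, `target_mask` (union zone, the "ACC" mask),
#'   and `seed_series` (frames x 3).
#' @export
make_rest_phantom <- function(grid_shape = c(14, 12, 10), n_timepoints = 180,
                              tr = 0.72, coupling = 0.6, global_amp = 0.3,
                              seed = 1L) {
  assert_that(n_timepoints >= 100, "n_timepoints must be >= 100")
  assert_that(coupling >= 0 && coupling < 1, "coupling must be in [0, 1)")
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 8),
              "grid_shape must be 3 dimensions of at least 8")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  t_len <- n_timepoints

  cube <- function(xr, yr, zr) {
    m <- array(FALSE, grid_shape)
    m[xr, yr, zr] <- TRUE
    m
  }
  third <- function(i, n) {
    lo <- floor((i - 1) * n / 3) + 1
    hi <- floor(i * n / 3)
    lo:hi
  }
  seeds_x <- 1:max(3, floor(nx / 4))
  targ_x <- (nx - max(3, floor(nx / 4)) + 1):nx
  zr <- 2:(nz - 1)
  seed_masks <- list(vAI = cube(seeds_x, third(1, ny), zr),
                     dAI = cube(seeds_x, third(2, ny), zr),
                     PI  = cube(seeds_x, third(3, ny), zr))
  target_masks <- list(vAI = cube(targ_x, third(1, ny), zr),
                       dAI = cube(targ_x, third(2, ny), zr),
                       PI  = cube(targ_x, third(3, ny), zr))

  with_seed(seed, {
    seed_series <- matrix(stats::rnorm(t_len * 3), t_len, 3,
                          dimnames = list(NULL, names(seed_masks)))
    global <- stats::rnorm(t_len)
    data <- array(stats::rnorm(prod(grid_shape) * t_len, sd = 1),
                  c(grid_shape, t_len))
    # add global component everywhere
    data <- data + array(rep(global, each = prod(grid_shape)) * global_amp,
                         c(grid_shape, t_len))
    flat <- matrix(data, nrow = prod(grid_shape))
    for (k in seq_along(seed_masks)) {
      sm <- as.vector(seed_masks[[k]])
      # seed voxels carry their seed series plus small noise
      flat[sm, ] <- matrix(rep(seed_series[, k], each = sum(sm)),
                           nrow = sum(sm)) +
        0.3 * matrix(stats::rnorm(sum(sm) * t_len), ncol = t_len) +
        global_amp * matrix(rep(global, each = sum(sm)), nrow = sum(sm))
      tm <- as.vector(target_masks[[k]])
      flat[tm, ] <- coupling *
        matrix(rep(seed_series[, k], each = sum(tm)), nrow = sum(tm)) +
        sqrt(1 - coupling^2) *
        matrix(stats::rnorm(sum(tm) * t_len), ncol = t_len) +
        global_amp * matrix(rep(global, each = sum(tm)), nrow = sum(tm))
    }
    data <- array(flat, c(grid_shape, t_len))
    # slow small motion drift: random walk scaled to stay well under limits
    drift <- apply(matrix(stats::rnorm(t_len * 6, sd = 1), t_len, 6), 2,
                   cumsum)
    drift <- sweep(drift, 2, drift[1, ])
    scale <- c(rep(0.002, 3), rep(0.00002, 3))  # mm, rad per step
    motion <- sweep(drift, 2, scale, `*`)

    structure(list(data = data, tr = tr, motion_params = motion,
                   seed_masks = seed_masks, target_masks = target_masks,
                   brain_mask = array(TRUE, grid_shape),
                   target_mask = Reduce(`|`, target_masks),
                   seed_series = seed_series, coupling = coupling),
              class = "rest_phantom")
  })
}
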