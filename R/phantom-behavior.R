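# Brain-behavior phantom: subdivision RTOP means (6 columns) and behavioral
# measures (11 columns) sharing one planted canonical pair.

BRAIN_COLS <- c("vAI_left", "dAI_left", "PI_left",
                "vAI_right", "dAI_right", "PI_right")
BEHAVIOR_COLS <- c("nback_accuracy", "nback_rt", "relational_accuracy",
                   "relational_rt", "gambling_accuracy", "gambling_rt",
                   "list_sorting", "flanker", "card_sorting",
                   "picture_sequence", "processing_speed")

#' Brain-behavior phantom with one planted canonical pair
#'
#' Two latent variables with correlation `planted_canonical_r` drive one
#' direction in each block: `brain = z_x a' * signal + noise` (6 RTOP-scaled
#' columns) and `behavior = z_y b' * signal + noise` (11 columns). With
#' `planted_canonical_r = 0` the blocks are independent. A fraction of
#' subjects receive one missing behavioral cell, emulating incomplete
#' phenotyping.
#'
#' @param n_subjects number of subjects.
#' @param planted_canonical_r latent correlation in [0, 1).
#' @param missing_fraction fraction of subjects with a missing behavioral
#'   cell, in [0, 0.5).
#' @param noise_sd column noise relative to unit latent signal.
#' @param seed integer seed.
#' @return `brain_behavior_phantom`: list with `brain` (data.frame with
#'   subject + 6 columns), `behavior` (subject + 11 columns, possibly with
#'   NAs), `planted_canonical_r`, `planted_brain_weights`,
#'   `planted_behavior_weights`, `missing_subjects`.
#' @export
make_brain_behavior <- function(n_subjects = 413, planted_canonical_r = 0.32,
                                missing_fraction = 0, noise_sd = 0.3,
                                seed = 1L) {
  assert_that(n_subjects >= 30, "n_subjects must be >= 30")
  assert_that(planted_canonical_r >= 0 && planted_canonical_r < 1,
              "planted_canonical_r must be in [0, 1)")
  assert_that(missing_fraction >= 0 && missing_fraction < 0.5,
              "missing_fraction must be in [0, 0.5)")
  with_seed(seed, {
    a <- normalize_vec(stats::rnorm(6))
    b <- normalize_vec(stats::rnorm(11))
    zx <- stats::rnorm(n_subjects)
    zy <- planted_canonical_r * zx +
      sqrt(1 - planted_canonical_r^2) * stats::rnorm(n_subjects)
    brain <- outer(zx, a) +
      noise_sd * matrix(stats::rnorm(n_subjects * 6), ncol = 6)
    behavior <- outer(zy, b) +
      noise_sd * matrix(stats::rnorm(n_subjects * 11), ncol = 11)
    # RTOP-like location/scale for the brain block
    brain <- sweep(brain * 0.25, 2, c(2.2, 2.5, 2.9, 2.1, 2.4, 2.8), `+`)
    colnames(brain) <- BRAIN_COLS
    colnames(behavior) <- BEHAVIOR_COLS

    n_missing <- round(missing_fraction * n_subjects)
    missing_subjects <- sort(sample.int(n_subjects, n_missing))
    for (s in missing_subjects)
      behavior[s, sample.int(11, 1)] <- NA_real_

    ids <- sprintf("sub-%04d", seq_len(n_subjects))
    structure(list(
      brain = data.frame(subject = ids, brain, check.names = FALSE),
      behavior = data.frame(subject = ids, behavior, check.names = FALSE),
      planted_canonical_r = planted_canonical_r,
      planted_brain_weights = a, planted_behavior_weights = b,
      missing_subjects = ids[missing_subjects]),
      class = "brain_behavior_phantom")
  })
}
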