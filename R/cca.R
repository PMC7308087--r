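# Canonical correlation between subdivision microstructure and behavior,
# with Pillai's trace significance, effect sizes, and leave-one-out
# prediction.

#' Listwise deletion of subjects with missing behavior
#'
#' Aligns the brain and behavior tables on subject id and drops subjects
#' with any missing behavioral cell or present in only one table; emits an
#' exclusion log. Errors when fewer than `min_subjects` remain (CCA
#' under-determination guard).
#'
#' @param behavior data.frame with a `subject` column and measure columns.
#' @param brain data.frame with a `subject` column and measure columns.
#' @param min_subjects minimum retained subjects.
#' @return list with `brain`, `behavior` (aligned, complete), `excluded`
#'   (data.frame subject/reason).
#' @export
exclude_missing <- function(behavior, brain, min_subjects = 30) {
  assert_that("subject" %in% names(behavior) && "subject" %in% names(brain),
              "both tables need a subject column")
  log <- list()
  only_beh <- setdiff(behavior$subject, brain$subject)
  only_br <- setdiff(brain$subject, behavior$subject)
  for (s in only_beh)
    log[[length(log) + 1]] <- data.frame(subject = s, reason = "unmatched id (behavior only)")
  for (s in only_br)
    log[[length(log) + 1]] <- data.frame(subject = s, reason = "unmatched id (brain only)")
  shared <- intersect(brain$subject, behavior$subject)
  beh <- behavior[match(shared, behavior$subject), , drop = FALSE]
  br <- brain[match(shared, brain$subject), , drop = FALSE]
  incomplete <- !stats::complete.cases(beh) | !stats::complete.cases(br)
  for (s in shared[incomplete])
    log[[length(log) + 1]] <- data.frame(subject = s, reason = "missing value")
  keep <- !incomplete
  if (sum(keep) < min_subjects)
    stop("only ", sum(keep), " complete subjects remain; need >= ",
         min_subjects)
  list(brain = br[keep, , drop = FALSE],
       behavior = beh[keep, , drop = FALSE],
       excluded = if (length(log)) do.call(rbind, log)
       else data.frame(subject = character(0), reason = character(0)))
}

strip_subject <- function(d) {
  as.matrix(d[, setdiff(names(d), "subject"), drop = FALSE])
}

# Resolve CCA sign indeterminacy: largest-magnitude brain weight positive
# per axis; behavior weights and variates flipped so each canonical
# correlation stays positive.
fix_cca_signs <- function(wx, wy, u, v) {
  for (k in seq_len(ncol(wx))) {
    if (wx[which.max(abs(wx[, k])), k] < 0) {
      wx[, k] <- -wx[, k]; u[, k] <- -u[, k]
    }
    if (stats::cor(u[, k], v[, k]) < 0) {
      wy[, k] <- -wy[, k]; v[, k] <- -v[, k]
    }
  }
  list(wx = wx, wy = wy, u = u, v = v)
}

# Rank-aware CCA core: QR of each standardized block, SVD of the Q'Q cross
# product. Handles exactly collinear blocks (returns rank-limited pairs with
# correlation 1 in the deterministic-map limit) where a normal-equation
# solver breaks down.
cca_core <- function(xs, ys, tol = 1e-9) {
  qx <- qr(xs, tol = tol); qy <- qr(ys, tol = tol)
  rx <- qx$rank; ry <- qy$rank
  Qx <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  k <- min(rx, ry)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  solve_coef <- function(qrd, r, um) {
    R <- qr.R(qrd)[seq_len(r), seq_len(r), drop = FALSE]
    w <- matrix(0, ncol(qrd$qr), ncol(um))
    w[qrd$pivot[seq_len(r)], ] <- backsolve(R, um)
    w
  }
  wx <- solve_coef(qx, rx, sv$u[, seq_len(k), drop = FALSE])
  wy <- solve_coef(qy, ry, sv$v[, seq_len(k), drop = FALSE])
  n <- nrow(xs)
  # Q columns are orthonormal -> variates have variance 1/(n-1); rescale
  list(wx = wx * sqrt(n - 1), wy = wy * sqrt(n - 1), cor = rho, k = k)
}

#' Canonical correlation analysis with Pillai's trace
#'
#' Full CCA between the standardized brain (n x p) and behavior (n x q)
#' blocks (QR + singular value decomposition, rank-aware), returning up to
#' min(p, q) canonical pairs with unit-variance variate scores, Pillai's
#' trace V = sum(rho_i^2) with its standard approximate-F test, and a
#' deterministic sign convention (the largest-magnitude brain weight of each
#' axis is positive and canonical correlations are non-negative).
#'
#' @param brain numeric matrix or data.frame (subject column allowed).
#' @param behavior numeric matrix or data.frame (subject column allowed).
#' @param n_perm optional number of seeded permutations for a permutation
#'   p-value of Pillai's trace (0 = analytic only).
#' @param seed seed for the permutation test.
#' @return `cca_result`: brain_weights (p x k), behavior_weights (q x k),
#'   canonical_correlations (k), brain_variates / behavior_variates (n x k,
#'   unit variance), pillai_trace, pillai_f, pillai_df, pillai_p (and
#'   pillai_p_perm when requested), n.
#' @export
fit_cca <- function(brain, behavior, n_perm = 0, seed = 1L) {
  if (is.data.frame(brain)) brain <- strip_subject(brain)
  if (is.data.frame(behavior)) behavior <- strip_subject(behavior)
  n <- nrow(brain)
  p <- ncol(brain); q <- ncol(behavior)
  assert_that(nrow(behavior) == n, "blocks must share subjects")
  assert_that(n > p + q, "need n > p + q subjects for a full CCA")
  sdx <- apply(brain, 2, stats::sd)
  sdy <- apply(behavior, 2, stats::sd)
  if (any(sdx == 0))
    stop("degenerate brain column(s): ",
         paste(colnames(brain)[sdx == 0], collapse = ", "))
  if (any(sdy == 0))
    stop("degenerate behavior column(s): ",
         paste(colnames(behavior)[sdy == 0], collapse = ", "))
  xs <- scale(brain); ys <- scale(behavior)
  cc <- cca_core(xs, ys)
  k <- cc$k
  wx <- cc$wx
  wy <- cc$wy
  u <- xs %*% wx
  v <- ys %*% wy
  sg <- fix_cca_signs(wx, wy, u, v)
  rho <- vapply(seq_len(k), function(i) stats::cor(sg$u[, i], sg$v[, i]),
                numeric(1))

  # Pillai's trace approximate F
  V <- sum(rho^2)
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (n - p - q - 2) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f_stat <- (2 * nn + s + 1) / (2 * m + s + 1) * V / (s - V)
  pillai_p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  res <- structure(list(
    brain_weights = sg$wx, behavior_weights = sg$wy,
    canonical_correlations = rho,
    brain_variates = sg$u, behavior_variates = sg$v,
    pillai_trace = V, pillai_f = f_stat, pillai_df = c(df1, df2),
    pillai_p = pillai_p, n = n), class = "cca_result")

  if (n_perm > 0) {
    perm_v <- with_seed(seed, {
      replicate(n_perm, {
        idx <- sample.int(n)
        sum(cca_core(xs, ys[idx, , drop = FALSE])$cor^2)
      })
    })
    res$pillai_p_perm <- (1 + sum(perm_v >= V)) / (n_perm + 1)
  }
  res
}

#' Correlation between canonical variate scores
#'
#' Pearson correlation between the brain and behavior variate scores of one
#' canonical axis across subjects; by construction this equals the canonical
#' correlation of that axis (asserted to 1e-10).
#'
#' @param result a [fit_cca()] result.
#' @param axis canonical axis (default 1).
#' @return list with r, p, axis, n.
#' @export
variate_correlation <- function(result, axis = 1) {
  ct <- stats::cor.test(result$brain_variates[, axis],
                        result$behavior_variates[, axis])
  stopifnot(abs(unname(ct$estimate) -
                  result$canonical_correlations[axis]) < 1e-10)
  list(r = unname(ct$estimate), p = ct$p.value, axis = axis, n = result$n)
}

#' Cohen's d from a Pearson correlation
#'
#' d = 2 r / sqrt(1 - r^2); e.g. r = 0.19 gives d = 0.387 (prints 0.39).
#'
#' @param r correlation with |r| < 1.
#' @return Cohen's d (unrounded).
#' @export
cohens_d_from_r <- function(r) {
  assert_that(all(abs(r) < 1), "|r| must be < 1")
  2 * r / sqrt(1 - r^2)
}

#' Leave-one-out canonical prediction
#'
#' For each subject: fit the CCA on the remaining subjects (standardization
#' statistics from the training fold only, per-fold sign alignment), then
#' score the held-out subject on the first canonical pair — the predicted
#' behavioral variate from the brain row and the actual behavioral variate
#' from the behavior row. Pearson correlation between predicted and actual
#' scores across subjects summarizes out-of-sample prediction, with Cohen's
#' d via [cohens_d_from_r()]. Folds whose CCA fails are skipped with a log;
#' more than `max_skip_fraction` skipped is an error.
#'
#' @param brain,behavior aligned complete-case tables (subject column
#'   allowed).
#' @param max_skip_fraction tolerated fraction of failed folds.
#' @return `prediction_result`: per-subject predicted/actual scores,
#'   pearson_r, p, cohens_d, skipped.
#' @export
loo_predict <- function(brain, behavior, max_skip_fraction = 0.05) {
  if (is.data.frame(brain)) brain <- strip_subject(brain)
  if (is.data.frame(behavior)) behavior <- strip_subject(behavior)
  n <- nrow(brain)
  pred <- rep(NA_real_, n)
  act <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    xtr <- brain[-i, , drop = FALSE]
    ytr <- behavior[-i, , drop = FALSE]
    res <- tryCatch({
      mx <- colMeans(xtr); sx <- apply(xtr, 2, stats::sd)
      my <- colMeans(ytr); sy <- apply(ytr, 2, stats::sd)
      fit <- fit_cca(xtr, ytr)
      xz <- (brain[i, ] - mx) / sx
      yz <- (behavior[i, ] - my) / sy
      c(sum(xz * fit$brain_weights[, 1]),
        sum(yz * fit$behavior_weights[, 1]))
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, i)
    else { pred[i] <- res[1]; act[i] <- res[2] }
  }
  if (length(skipped) > max_skip_fraction * n)
    stop(length(skipped), " of ", n, " folds failed")
  ok <- !is.na(pred)
  ct <- stats::cor.test(pred[ok], act[ok])
  r <- unname(ct$estimate)
  structure(list(predicted = pred, actual = act,
                 pearson_r = r, p = ct$p.value,
                 cohens_d = if (abs(r) < 1) cohens_d_from_r(r)
                 else sign(r) * Inf,  # perfect (noiseless) prediction
                 skipped = skipped, n = sum(ok)),
            class = "prediction_result")
}
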