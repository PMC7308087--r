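# Subdivision x hemisphere statistics: repeated-measures ANOVA, Bonferroni
# post-hoc paired t-tests, and the subsampling stability analysis.

check_parcel_summary <- function(summary) {
  need <- c("subject", "hemisphere", "subdivision", "mean_rtop")
  assert_that(all(need %in% names(summary)),
              "summary must have columns ", paste(need, collapse = ", "))
  tab <- table(summary$subject)
  cells <- length(unique(summary$hemisphere)) *
    length(unique(summary$subdivision))
  bad <- names(tab)[tab != cells]
  if (length(bad))
    stop("incomplete cells for subject(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(summary)
}

#' Two-way repeated-measures ANOVA on subdivision means
#'
#' Within-subject ANOVA with factors subdivision and hemisphere (subject as
#' the random factor), fitted through `stats::aov` with the standard
#' `Error(subject/(subdivision*hemisphere))` strata. With n subjects, 3
#' subdivisions and 2 hemispheres the subdivision and interaction effects
#' carry df (2, 2(n-1)) and hemisphere (1, n-1); no sphericity correction is
#' applied, matching the uncorrected dfs convention.
#'
#' @param summary data.frame (subject, hemisphere, subdivision, mean_rtop).
#' @return data.frame with effect, F, df_num, df_den, p.
#' @export
two_way_rm_anova <- function(summary) {
  check_parcel_summary(summary)
  d <- data.frame(subject = factor(summary$subject),
                  hemisphere = factor(summary$hemisphere),
                  subdivision = factor(summary$subdivision),
                  y = summary$mean_rtop)
  fit <- stats::aov(y ~ subdivision * hemisphere +
                      Error(subject / (subdivision * hemisphere)), data = d)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tb <- stratum[[1]]
    terms <- rownames(tb)
    res_row <- grep("^Residuals", trimws(terms))
    if (!length(res_row)) next
    df_den <- tb[res_row, "Df"]
    for (i in seq_along(terms)) {
      nm <- trimws(terms[i])
      if (nm == "Residuals" || is.na(tb[i, "F value"])) next
      out[[nm]] <- data.frame(effect = nm, F = tb[i, "F value"],
                              df_num = tb[i, "Df"], df_den = df_den,
                              p = tb[i, "Pr(>F)"])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni-corrected post-hoc paired t-tests
#'
#' All pairwise subdivision contrasts within each hemisphere plus the
#' between-hemisphere contrast for each subdivision, as paired t-tests across
#' subjects; p-values are Bonferroni-adjusted over the full contrast set.
#'
#' @param summary data.frame (subject, hemisphere, subdivision, mean_rtop).
#' @return data.frame with contrast descriptors, mean_diff, t, df, p_raw,
#'   p_adj (Bonferroni), ordered by p_adj.
#' @export
posthoc_paired_ttests <- function(summary) {
  check_parcel_summary(summary)
  summary$cell <- paste(summary$hemisphere, summary$subdivision, sep = ".")
  subs <- sort(unique(summary$subject))
  cells <- sort(unique(summary$cell))
  m <- matrix(NA_real_, length(subs), length(cells),
              dimnames = list(subs, cells))
  m[cbind(match(summary$subject, subs), match(summary$cell, cells))] <-
    summary$mean_rtop
  if (nrow(m) < 3) stop("need at least 3 subjects for paired t-tests")

  hemis <- sort(unique(summary$hemisphere))
  sds <- sort(unique(summary$subdivision))
  contrasts <- list()
  for (h in hemis) {
    pr <- utils::combn(sds, 2, simplify = FALSE)
    for (p in pr)
      contrasts[[length(contrasts) + 1]] <-
        list(a = paste(h, p[1], sep = "."), b = paste(h, p[2], sep = "."),
             label = sprintf("%s: %s - %s", h, p[1], p[2]))
  }
  if (length(hemis) == 2) for (s in sds)
    contrasts[[length(contrasts) + 1]] <-
      list(a = paste(hemis[1], s, sep = "."), b = paste(hemis[2], s, sep = "."),
           label = sprintf("%s: %s - %s", s, hemis[1], hemis[2]))

  rows <- lapply(contrasts, function(ct) {
    diff <- m[, ct$a] - m[, ct$b]
    if (stats::sd(diff) == 0) {
      data.frame(contrast = ct$label, mean_diff = mean(diff), t = 0,
                 df = length(diff) - 1, p_raw = 1)
    } else {
      tt <- stats::t.test(diff)
      data.frame(contrast = ct$label, mean_diff = mean(diff),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value)
    }
  })
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p_raw * nrow(res))
  res[order(res$p_adj, res$p_raw), ]
}

#' Minimum stable sample size by subsampling
#'
#' For each post-hoc contrast and each candidate sample size N, draws
#' `n_resamples` random subject subsets (without replacement) and records the
#' fraction whose paired t-test reaches p < `alpha` with the full-sample
#' effect direction. A contrast is stable at N when that fraction reaches
#' `criterion`; the minimum such N is reported (NA when never reached).
#'
#' @param summary data.frame (subject, hemisphere, subdivision, mean_rtop).
#' @param sample_sizes increasing candidate Ns (all <= number of subjects).
#' @param n_resamples resamples per N (>= 10).
#' @param alpha significance level of each subsample test.
#' @param criterion required fraction of significant resamples.
#' @param seed integer seed.
#' @return list with `fractions` (contrast x N matrix) and `min_stable_n`
#'   (named vector, NA = not stable at any tested N).
#' @export
stability_analysis <- function(summary, sample_sizes = c(10, 25, 50, 100),
                               n_resamples = 100, alpha = 0.01,
                               criterion = 0.95, seed = 1L) {
  check_parcel_summary(summary)
  assert_that(n_resamples >= 10, "n_resamples must be >= 10")
  subs <- sort(unique(summary$subject))
  assert_that(max(sample_sizes) <= length(subs),
              "max(sample_sizes) exceeds the number of subjects")
  summary$cell <- paste(summary$hemisphere, summary$subdivision, sep = ".")
  cells <- sort(unique(summary$cell))
  m <- matrix(NA_real_, length(subs), length(cells),
              dimnames = list(subs, cells))
  m[cbind(match(summary$subject, subs), match(summary$cell, cells))] <-
    summary$mean_rtop

  full <- posthoc_paired_ttests(summary)
  labels <- full$contrast
  pair_cols <- lapply(seq_len(nrow(full)), function(i) {
    parts <- strsplit(full$contrast[i], ": | - ")[[1]]
    if (parts[1] %in% unique(summary$hemisphere))
      c(paste(parts[1], parts[2], sep = "."), paste(parts[1], parts[3], sep = "."))
    else
      c(paste(parts[2], parts[1], sep = "."), paste(parts[3], parts[1], sep = "."))
  })
  signs <- sign(full$mean_diff)

  fractions <- matrix(NA_real_, length(labels), length(sample_sizes),
                      dimnames = list(labels, sample_sizes))
  with_seed(seed, {
    for (j in seq_along(sample_sizes)) {
      n <- sample_sizes[j]
      hits <- matrix(FALSE, length(labels), n_resamples)
      for (r in seq_len(n_resamples)) {
        take <- sample.int(length(subs), n)
        for (i in seq_along(labels)) {
          diff <- m[take, pair_cols[[i]][1]] - m[take, pair_cols[[i]][2]]
          if (stats::sd(diff) == 0) next
          tt <- stats::t.test(diff)
          hits[i, r] <- tt$p.value < alpha &&
            sign(mean(diff)) == signs[i]
        }
      }
      fractions[, j] <- rowMeans(hits)
    }
  })
  min_stable <- apply(fractions, 1, function(f) {
    w <- which(f >= criterion)
    if (length(w)) sample_sizes[min(w)] else NA_integer_
  })
  list(fractions = fractions, min_stable_n = min_stable,
       alpha = alpha, criterion = criterion)
}
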