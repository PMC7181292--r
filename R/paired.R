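# Paired scenario statistics: paired t-test, exact Wilcoxon signed-rank and
# the summary comparisons of the two-scenario driving study.

#' Exact two-sided Wilcoxon signed-rank p-value
#'
#' Computes the exact null distribution of the signed-rank statistic by
#' dynamic programming over all `2^n` sign assignments. Zero differences are
#' dropped; ties get mid-ranks (the distribution is built on doubled ranks
#' so mid-ranks stay integral). Two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param d numeric vector of paired differences (n <= 30 after zero
#'   removal).
#' @return list `statistic` (signed-rank sum of positive differences),
#'   `p_value`, `n` (non-zero pairs), `degenerate` (all differences zero).
#' @export
wilcoxon_exact <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L, degenerate = TRUE))
  if (n > 30) stop("exact enumeration limited to n <= 30", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))          # doubled ranks are integers
  total <- sum(r2)
  # dist[k+1] = number of sign assignments with doubled statistic k
  dist <- numeric(total + 1L)
  dist[1L] <- 1
  for (a in r2) {
    shifted <- c(numeric(a), dist[seq_len(length(dist) - a)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):length(dist)])
  list(statistic = w, p_value = min(1, 2 * min(p_le, p_ge)), n = n,
       degenerate = FALSE)
}

#' Paired comparison of a feature between two scenarios
#'
#' Runs a two-sided paired t-test and the exact two-sided Wilcoxon
#' signed-rank test on per-subject values from two conditions, and reports
#' the count of subjects that increased plus the percent increase of the
#' scenario means (`100 * (mean(b) / mean(a) - 1)`).
#'
#' @param a,b equal-length per-subject vectors (condition A = baseline,
#'   condition B = stressor), `n >= 5`, paired by position.
#' @param feature_name label carried into the result.
#' @return An object of class `paired_comparison`.
#' @export
paired_compare <- function(a, b, feature_name = "feature") {
  if (length(a) != length(b)) stop("paired vectors of equal length required",
                                   call. = FALSE)
  if (length(a) < 5) stop("need n >= 5 pairs", call. = FALSE)
  d <- b - a
  degenerate <- all(d == 0)
  t_p <- if (degenerate) NA_real_ else stats::t.test(b, a, paired = TRUE)$p.value
  wx <- wilcoxon_exact(d)
  structure(list(feature_name = feature_name,
                 values_a = a, values_b = b,
                 t_p = t_p, wilcoxon_p = wx$p_value,
                 n_increase = sum(d > 0),
                 pct_increase_of_means = 100 * (mean(b) / mean(a) - 1),
                 degenerate = degenerate),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s (n = %d)\n", x$feature_name,
              length(x$values_a)))
  cat(sprintf("  increase in %d/%d subjects; means +%.1f%%\n",
              x$n_increase, length(x$values_a), x$pct_increase_of_means))
  if (x$degenerate) {
    cat("  degenerate: all differences zero (p = 1)\n")
  } else {
    cat(sprintf("  paired t (two-sided) p = %.3g | exact Wilcoxon p = %.3g\n",
                x$t_p, x$wilcoxon_p))
  }
  invisible(x)
}

#' Load the bundled driving-study feature table
#'
#' Per-subject features (SPR RMS in mV, HR in bpm, SDNN in ms, LF in ms^2
#' and LF/HF) for ten drivers in two simulator scenarios (no traffic vs
#' aggressive traffic), as printed by the study this package reproduces.
#'
#' @param path optional path to a CSV with the same schema; defaults to the
#'   bundled fixture.
#' @return data.frame with columns `subject`, `scenario`, `spr_rms_mv`,
#'   `hr_bpm`, `sdnn_ms`, `lf_ms2`, `lf_hf`.
#' @export
driving_features <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "driving_features.csv", package = "sprecg",
                        mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("subject", "scenario", "spr_rms_mv", "hr_bpm", "sdnn_ms",
            "lf_ms2", "lf_hf")
  if (!all(need %in% names(tab)))
    stop("feature table schema mismatch: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(c("no_traffic", "traffic") %in% tab$scenario))
    stop("feature table must contain scenarios 'no_traffic' and 'traffic'",
         call. = FALSE)
  tab
}

#' Scenario statistics over a driving feature table
#'
#' Reproduces the study's derived statistics for each feature: percent
#' increase of the scenario means, count of subjects that increased, paired
#' t and exact Wilcoxon p-values; plus the composite `SDNN * LF/HF`
#' comparison.
#'
#' @param table a data.frame in the [driving_features()] schema.
#' @return list with `per_feature` (data.frame) and `comparisons` (named
#'   list of [paired_compare()] results, including `sdnn_lfhf`).
#' @export
compare_feature_tables <- function(table = driving_features()) {
  a <- table[table$scenario == "no_traffic", ]
  b <- table[table$scenario == "traffic", ]
  a <- a[order(a$subject), ]
  b <- b[order(b$subject), ]
  if (!identical(a$subject, b$subject))
    stop("subjects must be paired across scenarios", call. = FALSE)
  feats <- c(spr_rms = "spr_rms_mv", hr = "hr_bpm", sdnn = "sdnn_ms",
             lf = "lf_ms2", lf_hf = "lf_hf")
  comparisons <- lapply(seq_along(feats), function(i)
    paired_compare(a[[feats[i]]], b[[feats[i]]], names(feats)[i]))
  names(comparisons) <- names(feats)
  comparisons$sdnn_lfhf <- paired_compare(a$sdnn_ms * a$lf_hf,
                                          b$sdnn_ms * b$lf_hf, "sdnn_lfhf")
  per_feature <- do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(feature = cmp$feature_name,
               mean_a = mean(cmp$values_a), mean_b = mean(cmp$values_b),
               pct_increase = cmp$pct_increase_of_means,
               n_increase = cmp$n_increase,
               t_p = cmp$t_p, wilcoxon_p = cmp$wilcoxon_p)))
  rownames(per_feature) <- NULL
  list(per_feature = per_feature, comparisons = comparisons)
}
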