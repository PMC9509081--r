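#' Predict CTC levels from PCL-like score and tumor burden
#'
#' Fits `logit(CTC) ~ PCL-like score + logit(burden)` by ordinary least
#' squares and decomposes the variance of observed CTC levels by sequential
#' (Type-I) analysis of variance with the score entered first; term
#' fractions are each term's sum of squares over the total. Also reports
#' the adjusted R-squared of observed versus fitted values.
#'
#' @param pcl_scores Per-sample PCL-like scores.
#' @param logit_burden Per-sample tumor burden on the log-odds scale.
#' @param logit_ctc_observed Per-sample observed CTC level, log-odds scale.
#' @return An object of class `"ctc_prediction"`: coefficients, variance
#'   fractions (`var_fraction_score`, `var_fraction_burden`,
#'   `var_fraction_residual`, summing to 1), `adj_r2_obs_vs_pred`, `n`, and
#'   the underlying `lm` fit.
#' @export
predict_ctc <- function(pcl_scores, logit_burden, logit_ctc_observed) {
  keep <- stats::complete.cases(pcl_scores, logit_burden, logit_ctc_observed)
  d <- data.frame(score = pcl_scores[keep], burden = logit_burden[keep],
                  ctc = logit_ctc_observed[keep])
  if (nrow(d) < 4L) stop("need >= 4 complete observations", call. = FALSE)
  if (stats::sd(d$score) == 0) stop("constant predictor: pcl_scores", call. = FALSE)
  if (stats::sd(d$burden) == 0) stop("constant predictor: logit_burden", call. = FALSE)
  fit <- stats::lm(ctc ~ score + burden, data = d)
  an <- stats::anova(fit)                      # sequential SS, score first
  ss <- an[["Sum Sq"]]
  names(ss) <- rownames(an)
  total <- sum(ss)
  out <- list(intercept = unname(stats::coef(fit)[1L]),
              coef_score = unname(stats::coef(fit)["score"]),
              coef_burden = unname(stats::coef(fit)["burden"]),
              var_fraction_score = unname(ss["score"] / total),
              var_fraction_burden = unname(ss["burden"] / total),
              var_fraction_residual = unname(ss["Residuals"] / total),
              adj_r2_obs_vs_pred = summary(fit)$adj.r.squared,
              n = nrow(d), fit = fit)
  class(out) <- "ctc_prediction"
  out
}

#' @export
print.ctc_prediction <- function(x, ...) {
  cat("CTC prediction from PCL-like score + tumor burden (n =", x$n, ")\n")
  cat(sprintf("  variance explained: score %.1f%%, burden %.1f%%, residual %.1f%%\n",
              100 * x$var_fraction_score, 100 * x$var_fraction_burden,
              100 * x$var_fraction_residual))
  cat(sprintf("  adjusted R^2 (observed vs predicted): %.3f\n",
              x$adj_r2_obs_vs_pred))
  invisible(x)
}

#' Compare two groups of continuous values by Wilcoxon test
#'
#' Two-sided Wilcoxon signed-rank test for paired samples or rank-sum
#' (Mann-Whitney) test for unpaired samples. The p-value is exact when the
#' effective sample size is at most 25 and no ties (or zero differences)
#' are present; otherwise the normal approximation with tie correction and
#' continuity correction is used. The method actually applied is recorded.
#'
#' @param values_a,values_b Numeric vectors; equal length when `paired`.
#' @param paired Paired (signed-rank) or unpaired (rank-sum) comparison.
#' @return A list with `statistic`, `p_value`, `method`, `exact`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (paired && length(values_a) != length(values_b))
    stop("paired comparison needs equal-length groups", call. = FALSE)
  if (paired) {
    diffs <- values_a - values_b
    diffs <- diffs[diffs != 0]
    n_eff <- length(diffs)
    exact <- n_eff <= 25L && !any(duplicated(abs(diffs)))
  } else {
    n_eff <- max(length(values_a), length(values_b))
    exact <- n_eff <= 25L && !any(duplicated(c(values_a, values_b)))
  }
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = paired,
                                            exact = exact, correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, exact = exact)
}

#' Fisher's exact test with the sample odds ratio
#'
#' Two-sided conditional exact test on a 2x2 table: the p-value sums the
#' hypergeometric probabilities of all tables no more likely than the one
#' observed (the minimum-likelihood convention). The reported odds ratio is
#' the sample odds ratio `(a*d)/(b*c)`; when a margin cell is zero, 0.5 is
#' added to every cell for display and the result is flagged
#' (`continuity_corrected`).
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A list with `odds_ratio`, `p_value`, `continuity_corrected`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  cc <- any(table == 0)
  tb <- if (cc) table + 0.5 else table
  or <- (tb[1L, 1L] * tb[2L, 2L]) / (tb[1L, 2L] * tb[2L, 1L])
  list(odds_ratio = or, p_value = min(p, 1), continuity_corrected = cc)
}

#' Pairwise co-occurrence of binary features
#'
#' Tests every unordered pair of binary features with Fisher's exact test
#' on pairwise-complete samples, adjusts p-values across all tested pairs
#' by Benjamini-Hochberg, and reports pairs passing the FDR cutoff with a
#' sigmoid-scaled odds ratio `scaled_or = sigmoid(log OR)` — 0.5 at OR = 1,
#' above 0.5 for co-occurrence, below for mutual exclusivity. Pairs where a
#' feature has a single level after missing-data removal are skipped and
#' listed in the `skipped` attribute.
#'
#' @param binary_features Samples-by-features matrix or data frame of
#'   logical/0-1 values (`NA` allowed).
#' @param fdr_cutoff Report pairs with `q_value` below this cutoff; set to
#'   `Inf` to return all tested pairs.
#' @return A data frame with `feature_a`, `feature_b`, `odds_ratio`,
#'   `p_value`, `q_value`, `scaled_or`, filtered to `q_value < fdr_cutoff`.
#' @export
cooccurrence_matrix <- function(binary_features, fdr_cutoff = 0.05) {
  bf <- as.matrix(as.data.frame(binary_features))
  storage.mode(bf) <- "double"
  if (ncol(bf) < 2L) stop("need >= 2 features", call. = FALSE)
  if (any(!is.na(bf) & !(bf %in% c(0, 1))))
    stop("features must be binary (0/1 or logical)", call. = FALSE)
  feats <- colnames(bf)
  pairs <- utils::combn(seq_along(feats), 2L)
  rows <- list()
  skipped <- character(0)
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    keep <- !is.na(bf[, i]) & !is.na(bf[, j])
    a <- bf[keep, i]; b <- bf[keep, j]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
      skipped <- c(skipped, paste(feats[i], feats[j], sep = ":"))
      next
    }
    tab <- table(factor(a, levels = c(1, 0)), factor(b, levels = c(1, 0)))
    ft <- fisher_exact(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_a = feats[i], feature_b = feats[j],
      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable feature pairs", call. = FALSE)
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$scaled_or <- stats::plogis(log(res$odds_ratio))
  out <- res[res$q_value < fdr_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_pairs_tested") <- nrow(res)
  out
}
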