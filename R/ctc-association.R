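#' Per-gene association with CTC level, adjusted for tumor burden
#'
#' Fits, for one gene, the ordinary least-squares model
#' `expression ~ 1 + logit(CTC) + logit(burden)`. The CTC coefficient is the
#' expression change per log-odds unit increase in CTC level, independent of
#' tumor burden — the quantity the classifier ranks genes by. Samples with a
#' missing value in any of the three vectors are dropped pairwise.
#'
#' @param expr_g Per-sample expression of the gene.
#' @param logit_ctc Per-sample CTC level on the log-odds scale.
#' @param logit_burden Per-sample BM plasmacytosis on the log-odds scale.
#' @param gene_id Identifier carried into the result.
#' @return A one-row data frame with `gene_id`, `beta_ctc`, `se_ctc`,
#'   `beta_burden`, `p_value` (two-sided t-test, n - 3 df) and `n_used`.
#' @export
fit_gene_model <- function(expr_g, logit_ctc, logit_burden, gene_id = "gene") {
  if (length(expr_g) != length(logit_ctc) || length(expr_g) != length(logit_burden))
    stop("expression and covariate vectors must have equal length", call. = FALSE)
  keep <- stats::complete.cases(expr_g, logit_ctc, logit_burden)
  y <- matrix(expr_g[keep], ncol = 1L, dimnames = list(NULL, gene_id))
  fits <- fit_gene_models(t(y), logit_ctc[keep], logit_burden[keep],
                          drop_incomplete = FALSE)
  fits
}

#' Vectorized per-gene OLS against logit CTC and logit burden
#'
#' Solves the shared-design least-squares problem for every gene at once via
#' one QR decomposition of the n-by-3 design, the workhorse behind
#' [rank_genes()]. Equivalent to calling `lm()` per gene, orders of magnitude
#' faster for genome-scale matrices.
#'
#' @param mat Genes-by-samples expression matrix (rownames = gene ids).
#' @param logit_ctc,logit_burden Per-sample covariates on the log-odds scale.
#' @param drop_incomplete Drop samples with a missing covariate first.
#' @return A data frame with one row per gene: `gene_id`, `beta_ctc`,
#'   `se_ctc`, `beta_burden`, `p_value`, `n_used`.
#' @export
fit_gene_models <- function(mat, logit_ctc, logit_burden, drop_incomplete = TRUE) {
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L, dimnames = list("gene", NULL))
  if (ncol(mat) != length(logit_ctc) || ncol(mat) != length(logit_burden))
    stop("covariate length must equal the number of samples", call. = FALSE)
  if (drop_incomplete) {
    keep <- !is.na(logit_ctc) & !is.na(logit_burden)
    mat <- mat[, keep, drop = FALSE]
    logit_ctc <- logit_ctc[keep]
    logit_burden <- logit_burden[keep]
  }
  n <- ncol(mat)
  if (n < 4L)
    stop("need >= 4 complete samples for a 3-parameter model, got ", n,
         call. = FALSE)
  X <- cbind(intercept = 1, logit_ctc = logit_ctc, logit_burden = logit_burden)
  qx <- qr(X)
  if (qx$rank < 3L) {
    # name the column responsible for the rank deficiency
    degen <- if (stats::sd(logit_ctc) == 0) "logit_ctc"
             else if (stats::sd(logit_burden) == 0) "logit_burden"
             else "logit_burden (collinear with logit_ctc)"
    stop("degenerate design: column `", degen, "` carries no independent variation",
         call. = FALSE)
  }
  Y <- t(mat)                              # samples x genes
  coefs <- qr.coef(qx, Y)                  # 3 x genes
  resid <- Y - X %*% coefs
  rss <- colSums(resid^2)
  df <- n - 3L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se_ctc <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tstat <- coefs[2L, ] / se_ctc
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(gene_id = rownames(mat),
             beta_ctc = unname(coefs[2L, ]),
             se_ctc = unname(se_ctc),
             beta_burden = unname(coefs[3L, ]),
             p_value = unname(p),
             n_used = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, clipped to 1 and
#' returned in the input order. Delegates to `stats::p.adjust(method =
#' "BH")` after validating the domain.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Rank genes by burden-adjusted association with CTC level
#'
#' The classifier-construction ranking step: fits
#' `expression ~ logit(CTC) + logit(burden)` for every gene over the
#' eligible samples, adjusts p-values across all tested genes by
#' Benjamini-Hochberg, and orders genes by ascending p-value, breaking ties
#' by descending `|beta_ctc|` and then gene id so selection is
#' deterministic.
#'
#' Samples with undetectable CTC are excluded by default, matching an
#' analysis restricted to patients with detectable CTC levels; with
#' `undetectable = "impute_lod2"` they instead enter at half the limit of
#' detection.
#'
#' @param mat Genes-by-samples expression matrix.
#' @param annotation Per-sample annotation table covering the matrix columns
#'   (see [validate_annotation()]).
#' @param fdr_cutoff Significance cutoff on the BH q-value.
#' @param undetectable Either `"exclude"` (default) or `"impute_lod2"`.
#' @param lod Limit of detection used by the imputation rule.
#' @param ndmm_only If `TRUE`, fit on NDMM samples only; by default pPCL
#'   samples enter alongside NDMM with their morphology-derived fractions.
#' @param eps Clamping bound for [logit()].
#' @return A data frame of class `"gene_association"`, one row per gene in
#'   ranked order, with `beta_ctc`, `se_ctc`, `beta_burden`, `p_value`,
#'   `q_value`, `n_used` and a logical `significant` column
#'   (`q_value < fdr_cutoff`).
#' @export
rank_genes <- function(mat, annotation, fdr_cutoff = 0.05,
                       undetectable = c("exclude", "impute_lod2"),
                       lod = 1e-5, ndmm_only = FALSE, eps = 1e-6) {
  validate_expression(mat)
  validate_annotation(annotation)
  undetectable <- match.arg(undetectable)
  idx <- match(colnames(mat), annotation$sample_id)
  if (anyNA(idx))
    stop("annotation missing sample(s): ",
         paste(utils::head(colnames(mat)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  ann <- annotation[idx, ]

  ctc <- ann$ctc_fraction
  if (undetectable == "impute_lod2") {
    ctc[!ann$ctc_detectable] <- lod / 2
  } else {
    ctc[!ann$ctc_detectable] <- NA_real_
  }
  eligible <- !is.na(ctc) & !is.na(ann$burden_fraction)
  if (ndmm_only) eligible <- eligible & ann$disease_label == "NDMM"
  if (!any(eligible)) stop("no eligible samples for association fitting", call. = FALSE)

  fits <- fit_gene_models(mat[, eligible, drop = FALSE],
                          logit(ctc[eligible], eps),
                          logit(ann$burden_fraction[eligible], eps))
  fits$q_value <- bh_adjust(fits$p_value)
  ord <- order(fits$p_value, -abs(fits$beta_ctc), fits$gene_id)
  fits <- fits[ord, c("gene_id", "beta_ctc", "se_ctc", "beta_burden",
                      "p_value", "q_value", "n_used")]
  rownames(fits) <- NULL
  fits$significant <- fits$q_value < fdr_cutoff
  attr(fits, "fdr_cutoff") <- fdr_cutoff
  class(fits) <- c("gene_association", "data.frame")
  fits
}

#' @export
print.gene_association <- function(x, n = 10L, ...) {
  cat("Gene-CTC association ranking:", nrow(x), "genes,",
      sum(x$significant), "significant at FDR <", attr(x, "fdr_cutoff"), "\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more genes\n")
  invisible(x)
}
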