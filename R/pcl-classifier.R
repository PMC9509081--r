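#' PCL-like score of samples under a classifier model
#'
#' The PCL-like score of a sample is the equal-weight signed mean of its
#' training-standardized expression over the model genes:
#' `score = (1/k) * sum_g sign_g * weight_g * z_g`, where `z_g` standardizes
#' gene g by the training-set mean and sd and the sum runs over the k model
#' genes present in the sample's gene space. Missing model genes are skipped
#' and counted; if fewer than `min_coverage` of the model genes are present
#' the sample cannot be scored and an error is raised.
#'
#' @param model A `"pcl_classifier"` object (see [pcl_classifier()] /
#'   [load_packaged_model()]).
#' @param mat Genes-by-samples expression matrix to score.
#' @param ref_stats Optional per-gene reference statistics (`gene_id`,
#'   `mean`, `sd`) to standardize with; required when the model carries no
#'   `train_stats` (a packaged model applied to a new cohort).
#' @param min_coverage Minimum fraction of model genes that must be present.
#' @return A data frame of class `"scored_samples"`: `sample_id`,
#'   `pcl_score`, `call` (`"PCL-like"` iff `pcl_score >= model$threshold`),
#'   `n_genes_used`, `n_genes_missing`.
#' @export
compute_score <- function(model, mat, ref_stats = NULL, min_coverage = 0.5) {
  stopifnot(inherits(model, "pcl_classifier"))
  validate_expression(mat)
  stats_df <- if (!is.null(ref_stats)) ref_stats else model$train_stats
  if (is.null(stats_df))
    stop("model carries no train_stats; supply `ref_stats` from a reference cohort",
         call. = FALSE)

  genes <- model$genes
  present <- genes$gene_id %in% rownames(mat)
  k_used <- sum(present)
  if (k_used < min_coverage * nrow(genes))
    stop(sprintf("only %d of %d model genes present (< %.0f%% coverage)",
                 k_used, nrow(genes), 100 * min_coverage), call. = FALSE)
  gsub_df <- genes[present, , drop = FALSE]
  sub <- mat[gsub_df$gene_id, , drop = FALSE]
  idx <- match(gsub_df$gene_id, stats_df$gene_id)
  if (anyNA(idx))
    stop("standardization statistics missing for model gene(s): ",
         paste(utils::head(gsub_df$gene_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  z <- (sub - stats_df$mean[idx]) / stats_df$sd[idx]
  w <- gsub_df$sign * gsub_df$weight
  score <- as.numeric(crossprod(z, w)) / k_used
  out <- data.frame(sample_id = colnames(mat),
                    pcl_score = score,
                    call = ifelse(score >= model$threshold, "PCL-like", "not-PCL-like"),
                    n_genes_used = k_used,
                    n_genes_missing = nrow(genes) - k_used,
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_samples", "data.frame")
  out
}

#' Calibrate the PCL-like decision threshold
#'
#' The threshold is the minimal PCL-like score observed among discovery-set
#' pPCL tumors, so that with the inclusive rule `score >= threshold` every
#' discovery pPCL sample is classified PCL-like by construction.
#'
#' @param ppcl_scores Scores of the discovery pPCL samples (>= 1 value).
#' @return The threshold (their minimum).
#' @export
calibrate_threshold <- function(ppcl_scores) {
  if (length(ppcl_scores) == 0L || all(is.na(ppcl_scores)))
    stop("need at least one pPCL score to calibrate a threshold", call. = FALSE)
  min(ppcl_scores, na.rm = TRUE)
}

# Mann-Whitney AUC of `score` for labels (TRUE = positive class).
auc_score <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Top-k gene sub-model from a ranking, with training stats from `mat`.
top_k_model <- function(ranking, k, mat, threshold = -Inf) {
  sel <- utils::head(ranking, k)
  std <- standardize_genes(mat[sel$gene_id, , drop = FALSE])
  structure(list(genes = data.frame(gene_id = sel$gene_id,
                                    sign = sign(sel$beta_ctc),
                                    weight = rep(1, nrow(sel)),
                                    stringsAsFactors = FALSE),
                 train_stats = std$stats,
                 threshold = threshold,
                 provenance = "built",
                 metadata = sprintf("top-%d interim model", k)),
            class = "pcl_classifier")
}

#' Choose the number of classifier genes by leave-one-out cross-validation
#'
#' For every left-out sample, genes are re-ranked on the remaining samples
#' (so the held-out sample influences neither the gene ranking nor the
#' standardization statistics), top-k models are built for each candidate k,
#' and the held-out sample is scored. Per-k performance is the AUC of the
#' held-out scores for discriminating pPCL from NDMM; the selected size
#' `k_star` is the smallest k attaining the maximal AUC.
#'
#' Re-ranking inside each fold avoids selection bias; `refit_rank = FALSE`
#' switches to a fast mode that ranks once on the full data and
#' cross-validates only the scoring, which is cheaper but mildly optimistic.
#'
#' @param mat Genes-by-samples discovery expression matrix.
#' @param annotation Annotation covering the matrix samples; both NDMM and
#'   pPCL labels must be present.
#' @param size_grid Candidate gene-set sizes (positive integers).
#' @param refit_rank Re-rank genes within each fold (default) or once.
#' @param max_skipped_folds Error if more than this fraction of folds fails
#'   (degenerate within-fold design).
#' @param ... Passed to [rank_genes()] (e.g. `undetectable`, `fdr_cutoff`).
#' @return A list with `k_star`, `performance` (data frame of `k`, `auc`),
#'   `held_out_scores` (samples x sizes matrix) and `n_folds_skipped`.
#' @export
loocv_select_size <- function(mat, annotation, size_grid = c(10L, 25L, 54L, 100L),
                              refit_rank = TRUE, max_skipped_folds = 0.1, ...) {
  validate_expression(mat)
  validate_annotation(annotation)
  size_grid <- sort(unique(as.integer(size_grid)))
  if (length(size_grid) == 0L || any(size_grid < 1L))
    stop("`size_grid` must contain positive sizes", call. = FALSE)
  if (any(size_grid > nrow(mat)))
    stop("`size_grid` exceeds the number of genes", call. = FALSE)
  ann <- annotation[match(colnames(mat), annotation$sample_id), ]
  lab <- ann$disease_label
  for (cls in c("NDMM", "pPCL"))
    if (!any(lab == cls)) stop("class absent from discovery set: ", cls, call. = FALSE)

  n <- ncol(mat)
  scores <- matrix(NA_real_, nrow = n, ncol = length(size_grid),
                   dimnames = list(colnames(mat), paste0("k", size_grid)))
  full_rank <- if (!refit_rank) rank_genes(mat, annotation, ...) else NULL
  skipped <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      train_mat <- mat[, -i, drop = FALSE]
      ranking <- if (refit_rank) rank_genes(train_mat, annotation, ...) else full_rank
      for (j in seq_along(size_grid)) {
        m <- top_k_model(ranking, size_grid[j], train_mat)
        scores[i, j] <- compute_score(m, mat[, i, drop = FALSE])$pcl_score
      }
      TRUE
    }, error = function(e) {
      message("LOOCV fold ", i, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (!res) skipped <- skipped + 1L
  }
  if (skipped > max_skipped_folds * n)
    stop(sprintf("%d of %d LOOCV folds skipped (> %.0f%% allowed)",
                 skipped, n, 100 * max_skipped_folds), call. = FALSE)

  used <- !is.na(scores[, 1L])
  auc <- vapply(seq_along(size_grid), function(j)
    auc_score(scores[used, j], lab[used] == "pPCL"), numeric(1))
  perf <- data.frame(k = size_grid, auc = auc)
  k_star <- size_grid[which.max(auc)]   # ties -> smallest k (grid ascending)
  list(k_star = k_star, performance = perf, held_out_scores = scores,
       n_folds_skipped = skipped)
}

#' Build a PCL-like classifier from a discovery cohort
#'
#' The full construction pipeline: (1) rank genes by their burden-adjusted
#' association with CTC level ([rank_genes()]); (2) choose the number of
#' genes by leave-one-out cross-validation against the pPCL/NDMM labels
#' ([loocv_select_size()]); (3) assemble the final model from the top
#' `k_star` genes re-ranked on the full discovery set — unit weights, signs
#' from the CTC coefficient, standardization statistics from the discovery
#' set — and set the decision threshold to the minimal PCL-like score of
#' the discovery pPCL samples ([calibrate_threshold()]), so discovery pPCL
#' sensitivity is 100% by construction.
#'
#' @param mat Genes-by-samples discovery expression matrix.
#' @param annotation Annotation table covering the matrix samples.
#' @param fdr_cutoff FDR cutoff recorded with the ranking.
#' @param size_grid Candidate gene-set sizes for the LOOCV step.
#' @param refit_rank Re-rank genes within each LOOCV fold (default TRUE).
#' @param ... Further arguments to [rank_genes()].
#' @return An object of class `"pcl_classifier"` with elements `genes`
#'   (gene_id, sign, weight), `train_stats`, `threshold`, `provenance`
#'   (`"built"`), `loocv` (size-selection results), `ranking` (full
#'   discovery ranking) and `metadata`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_samples = 60, n_genes = 300,
#'                                   n_signal_genes = 30, seed = 11))
#' fit <- pcl_classifier(coh$expression, coh$annotation,
#'                       size_grid = c(10, 30))
#' fit
#' head(predict(fit, coh$expression))
#' @export
pcl_classifier <- function(mat, annotation, fdr_cutoff = 0.05,
                           size_grid = c(10L, 25L, 54L, 100L),
                           refit_rank = TRUE, ...) {
  validate_expression(mat)
  validate_annotation(annotation)
  ranking <- rank_genes(mat, annotation, fdr_cutoff = fdr_cutoff, ...)
  cv <- loocv_select_size(mat, annotation, size_grid = size_grid,
                          refit_rank = refit_rank, fdr_cutoff = fdr_cutoff, ...)
  model <- top_k_model(ranking, cv$k_star, mat)
  ann <- annotation[match(colnames(mat), annotation$sample_id), ]
  disc_scores <- compute_score(model, mat)
  model$threshold <- calibrate_threshold(
    disc_scores$pcl_score[ann$disease_label == "pPCL"])
  model$loocv <- cv[c("k_star", "performance", "n_folds_skipped")]
  model$ranking <- ranking
  model$provenance <- "built"
  model$metadata <- sprintf(
    "built from %d-sample discovery set (%d pPCL, %d NDMM), %d genes tested",
    ncol(mat), sum(ann$disease_label == "pPCL"),
    sum(ann$disease_label == "NDMM"), nrow(mat))
  model
}

#' Load a packaged PCL-like classifier model from JSON
#'
#' Reads a serialized model (gene list with signs and weights, decision
#' threshold, provenance, optional training statistics). The fixture
#' shipped with the package, `pcl54_model_synthetic.json`, carries the
#' published constants of the 54-gene classifier — 54 gene entries and the
#' decision threshold 3.55 — but, as its name states, the gene identities
#' are a synthetic stand-in (the published table of identifiers is not
#' redistributed here); see the package vignette. A packaged model without
#' `train_stats` must be scored with `ref_stats` from a user-declared
#' reference cohort.
#'
#' @param path Path to the model JSON; defaults to the packaged fixture.
#' @return A `"pcl_classifier"` object.
#' @export
load_packaged_model <- function(path = system.file("extdata", "pcl54_model_synthetic.json",
                                                   package = "pcllike")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("model fixture not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- c("genes", "threshold", "provenance")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L)
    stop("model file missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  genes <- as.data.frame(raw$genes, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "sign", "weight") %in% names(genes)))
    stop("model genes need gene_id, sign, weight", call. = FALSE)
  if (nrow(genes) < 1L) stop("model must contain >= 1 gene", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene id in model: ",
         genes$gene_id[duplicated(genes$gene_id)][1L], call. = FALSE)
  if (!all(genes$sign %in% c(-1, 1)))
    stop("gene signs must be +1 or -1", call. = FALSE)
  if (any(!is.finite(genes$weight)))
    stop("gene weights must be finite", call. = FALSE)
  if (!is.finite(raw$threshold))
    stop("threshold must be finite", call. = FALSE)
  ts <- NULL
  if (!is.null(raw$train_stats)) {
    ts <- as.data.frame(raw$train_stats, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "mean", "sd") %in% names(ts)))
      stop("train_stats needs gene_id, mean, sd", call. = FALSE)
  }
  structure(list(genes = genes[, c("gene_id", "sign", "weight")],
                 train_stats = ts,
                 threshold = raw$threshold,
                 provenance = raw$provenance,
                 metadata = if (!is.null(raw$metadata)) raw$metadata else ""),
            class = "pcl_classifier")
}

#' Serialize a classifier model to JSON
#'
#' @param model A `"pcl_classifier"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pcl_classifier"))
  obj <- list(genes = model$genes, threshold = model$threshold,
              provenance = model$provenance, metadata = model$metadata)
  if (!is.null(model$train_stats)) obj$train_stats <- model$train_stats
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pcl_classifier <- function(x, ...) {
  cat("PCL-like classifier (", x$provenance, "): ", nrow(x$genes),
      " genes, threshold ", format(x$threshold, digits = 4), "\n", sep = "")
  cat("  signs: +", sum(x$genes$sign > 0), " / -", sum(x$genes$sign < 0),
      "; rule: score >= threshold => PCL-like\n", sep = "")
  if (!is.null(x$loocv))
    cat("  LOOCV-selected size k* =", x$loocv$k_star, "\n")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pcl_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$loocv)) {
    cat("\nLOOCV size selection (held-out AUC, pPCL vs NDMM):\n")
    print(object$loocv$performance, digits = 4, row.names = FALSE)
  }
  cat("\nModel genes:\n")
  print(utils::head(object$genes, 10L), row.names = FALSE)
  if (nrow(object$genes) > 10L)
    cat("... and", nrow(object$genes) - 10L, "more genes\n")
  invisible(object)
}

#' @export
coef.pcl_classifier <- function(object, ...) {
  stats::setNames(object$genes$sign * object$genes$weight, object$genes$gene_id)
}

#' Score new samples with a fitted classifier
#'
#' @param object A `"pcl_classifier"`.
#' @param newdata Genes-by-samples expression matrix.
#' @param ref_expr Optional reference expression matrix from which
#'   standardization statistics are re-estimated (for packaged models or
#'   cross-platform application); overrides the model's `train_stats`.
#' @param min_coverage Minimum fraction of model genes required.
#' @param ... Unused.
#' @return A `"scored_samples"` data frame; see [compute_score()].
#' @export
predict.pcl_classifier <- function(object, newdata, ref_expr = NULL,
                                   min_coverage = 0.5, ...) {
  ref_stats <- NULL
  if (!is.null(ref_expr)) {
    present <- object$genes$gene_id[object$genes$gene_id %in% rownames(ref_expr)]
    ref_stats <- standardize_genes(ref_expr[present, , drop = FALSE])$stats
  }
  compute_score(object, newdata, ref_stats = ref_stats,
                min_coverage = min_coverage)
}

#' @export
plot.pcl_classifier <- function(x, ...) {
  if (is.null(x$loocv))
    stop("no LOOCV results stored in this model", call. = FALSE)
  perf <- x$loocv$performance
  graphics::plot(perf$k, perf$auc, type = "b", log = "x",
                 xlab = "number of classifier genes (k)",
                 ylab = "held-out AUC (pPCL vs NDMM)",
                 main = "LOOCV gene-number selection", ...)
  graphics::abline(v = x$loocv$k_star, lty = 2)
  invisible(x)
}
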