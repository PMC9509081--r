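#' Log-odds (logit) transform with detection-limit clamping
#'
#' Fractions such as CTC levels and bone-marrow plasmacytosis are analysed on
#' a log-odds scale throughout the package. Values of exactly 0 or 1 have an
#' infinite log-odds; they are clamped to `[eps, 1 - eps]` first so that, for
#' example, a CTC measurement below the assay's limit of detection maps to a
#' finite, extreme log-odds value. The default `eps = 1e-6` sits below the
#' reported flow-cytometry limit of detection (< 1e-5).
#'
#' @param p Numeric vector of fractions in `[0, 1]`. `NA` is propagated.
#' @param eps Clamping bound, a single number in `(0, 0.5)`.
#' @return `log(p' / (1 - p'))` where `p' = min(max(p, eps), 1 - eps)`.
#' @examples
#' logit(0.5)            # 0
#' logit(c(0, 1))        # finite, symmetric extremes
#' logit(0.2)            # the pPCL CTC cutoff on the log-odds scale
#' @seealso [inv_logit()]
#' @export
logit <- function(p, eps = 1e-6) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0 || eps >= 0.5)
    stop("`eps` must be a single number in (0, 0.5)", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("`p` must lie in [0, 1]; offending value(s): ",
         paste(utils::head(p[bad], 3L), collapse = ", "), call. = FALSE)
  pc <- pmin(pmax(p, eps), 1 - eps)
  log(pc / (1 - pc))
}

#' Inverse logit
#'
#' @param x Numeric vector on the log-odds scale.
#' @return Fractions `exp(x) / (1 + exp(x))`.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header names the samples; all remaining cells must be numeric
#' log-scale expression values. Duplicate gene or sample identifiers and
#' non-numeric cells are rejected with the offending coordinate named.
#'
#' @param path Path to the TSV file.
#' @param platform Platform tag attached to the matrix, one of
#'   `"microarray"`, `"rnaseq"`, `"synthetic"`.
#' @return A numeric matrix (genes in rows, samples in columns) with a
#'   `platform` attribute.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, platform = c("synthetic", "microarray", "rnaseq")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("malformed header in ", path, ": need a gene-id column plus >= 1 sample",
         call. = FALSE)
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, sample_ids))
  bad <- which(is.na(vals) & !is.na(as.matrix(raw[-1L])) & as.matrix(raw[-1L]) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at gene '%s' (row %d), sample '%s'",
                 gene_ids[bad[1L, 1L]], bad[1L, 1L], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_expression(vals)
  attr(vals, "platform") <- platform
  vals
}

#' Write an expression matrix to TSV
#'
#' Writes at full precision (`%.17g`) so a write/read round-trip reproduces
#' the matrix exactly.
#'
#' @param mat Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param id_column Header of the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "gene_id") {
  validate_expression(mat)
  df <- data.frame(rownames(mat),
                   matrix(sprintf("%.17g", mat), nrow = nrow(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: a numeric matrix
#' with unique, named genes (rows) and samples (columns) and finite values.
#'
#' @param mat Candidate matrix.
#' @return `mat`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  dg <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dg) > 0L)
    stop("duplicate gene id(s): ", paste(unique(dg), collapse = ", "), call. = FALSE)
  ds <- colnames(mat)[duplicated(colnames(mat))]
  if (length(ds) > 0L)
    stop("duplicate sample id(s): ", paste(unique(ds), collapse = ", "), call. = FALSE)
  if (any(!is.finite(mat)))
    stop("expression values must be finite", call. = FALSE)
  invisible(mat)
}

#' Filter genes by expression prevalence
#'
#' Keeps genes whose expression strictly exceeds `min_level` in at least
#' `min_fraction` of samples, preserving gene order. The published analyses
#' work on an "expressed genes" subset whose exact definition is not fixed,
#' so both thresholds are parameters.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param min_fraction Minimum fraction of samples (in `[0, 1]`) in which a
#'   gene must exceed `min_level`.
#' @param min_level Expression level a gene must exceed to count as expressed
#'   in a sample.
#' @return The filtered matrix (platform attribute preserved).
#' @export
filter_expressed <- function(mat, min_fraction = 0.5, min_level = 0) {
  validate_expression(mat)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must be a single number in [0, 1]", call. = FALSE)
  keep <- rowMeans(mat > min_level) >= min_fraction
  if (!any(keep)) stop("no genes pass filter", call. = FALSE)
  out <- mat[keep, , drop = FALSE]
  attr(out, "platform") <- attr(mat, "platform")
  out
}

#' Standardize genes with training-set statistics
#'
#' Centers and scales each gene (row), either by statistics re-estimated from
#' `mat` or by supplied reference statistics (so validation samples reuse the
#' training set's mean/sd). A zero-variance gene without reference statistics
#' is assigned sd = 1 and flagged with a warning.
#'
#' @param mat Numeric gene-by-sample matrix.
#' @param reference_stats Optional data frame with columns `gene_id`, `mean`,
#'   `sd` covering every gene of `mat` (as returned by this function).
#' @return A list with `matrix` (standardized values) and `stats` (the
#'   per-gene mean/sd data frame actually used).
#' @export
standardize_genes <- function(mat, reference_stats = NULL) {
  validate_expression(mat)
  if (is.null(reference_stats)) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1L, stats::sd)
    zero <- !is.na(sdv) & sdv == 0
    if (any(zero)) {
      warning("zero-variance gene(s) assigned sd = 1: ",
              paste(utils::head(rownames(mat)[zero], 5L), collapse = ", "),
              call. = FALSE)
      sdv[zero] <- 1
    }
    stats_df <- data.frame(gene_id = rownames(mat), mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE)
  } else {
    req <- c("gene_id", "mean", "sd")
    if (!is.data.frame(reference_stats) || !all(req %in% names(reference_stats)))
      stop("`reference_stats` needs columns gene_id, mean, sd", call. = FALSE)
    idx <- match(rownames(mat), reference_stats$gene_id)
    if (anyNA(idx))
      stop("reference_stats missing gene(s): ",
           paste(utils::head(rownames(mat)[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    stats_df <- reference_stats[idx, req]
    rownames(stats_df) <- NULL
    if (any(stats_df$sd <= 0)) stop("reference sd must be > 0", call. = FALSE)
  }
  z <- (mat - stats_df$mean) / stats_df$sd
  attr(z, "platform") <- attr(mat, "platform")
  list(matrix = z, stats = stats_df)
}

#' Read a per-sample annotation table from CSV
#'
#' Expected columns: `sample_id`, `ctc_fraction` (in `[0,1]` or NA),
#' `ctc_detectable` (logical), `burden_fraction` (in `[0,1]` or NA),
#' `disease_label`, `study_id`, optionally `age_le_65`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' Validate a per-sample annotation table
#'
#' @param ann Data frame of per-sample annotation.
#' @return `ann`, invisibly, if valid.
#' @export
validate_annotation <- function(ann) {
  req <- c("sample_id", "ctc_fraction", "ctc_detectable", "burden_fraction",
           "disease_label", "study_id")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0L)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation", call. = FALSE)
  for (col in c("ctc_fraction", "burden_fraction")) {
    v <- ann[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " must lie in [0, 1] where present", call. = FALSE)
  }
  invisible(ann)
}
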