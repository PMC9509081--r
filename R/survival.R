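#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' chi-square test (k - 1 degrees of freedom). Composite groups (e.g. stage
#' crossed with PCL-like status) can be formed by passing several grouping
#' columns; levels are joined with `sep`.
#'
#' @param records Data frame of one row per subject for a single endpoint:
#'   columns `time` (> 0), `event` (0/1) and the grouping column(s).
#' @param group_by Character vector of grouping column names (default
#'   `"pcl_like"`).
#' @param sep Separator for composite group labels.
#' @return An object of class `"km_logrank"`: `curves` (data frame of
#'   `group`, `time`, `n_risk`, `n_event`, `survival`), `chisq`, `df`,
#'   `p_value`, and the underlying `survfit` object.
#' @export
km_logrank <- function(records, group_by = "pcl_like", sep = " & ") {
  stopifnot(is.data.frame(records))
  miss <- setdiff(c("time", "event", group_by), names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$time <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(records$event %in% c(0L, 1L))) stop("event must be 0/1", call. = FALSE)
  grp <- do.call(paste, c(lapply(group_by, function(g) records[[g]]), sep = sep))
  if (length(unique(grp)) < 2L)
    stop("need >= 2 non-empty groups for a log-rank comparison", call. = FALSE)
  d <- data.frame(time = records$time, event = records$event, group = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  k <- length(unique(grp))
  s <- summary(sf)
  curves <- data.frame(group = sub("^group=", "", as.character(s$strata)),
                       time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                       survival = s$surv, stringsAsFactors = FALSE)
  out <- list(curves = curves, chisq = sd$chisq, df = k - 1L,
              p_value = stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE),
              survfit = sf)
  class(out) <- "km_logrank"
  out
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Log-rank test:", length(unique(x$curves$group)), "groups, chisq =",
      format(x$chisq, digits = 4), "on", x$df, "df, p =",
      format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Study-stratified Cox proportional hazards model
#'
#' Partial-likelihood estimation with a separate baseline hazard per
#' stratum (study cohort) and Breslow handling of tied event times. Reports
#' per-covariate hazard ratios with Wald 95% confidence intervals and
#' p-values. Non-convergence or a monotone likelihood (perfect separation,
#' flagged by an extreme coefficient) raises an error naming the covariate.
#'
#' @param records Data frame with `time`, `event`, the covariate columns and
#'   the stratification column.
#' @param covariates Character vector of covariate column names.
#' @param strata Name of the stratification column (`NULL` for none).
#' @return An object of class `"cox_fit"`: `table` (data frame of `term`,
#'   `log_hr`, `se`, `hr`, `ci_lower`, `ci_upper`, `p_value`), `n`,
#'   `n_events`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariates = "pcl_like", strata = "study_id") {
  stopifnot(is.data.frame(records))
  miss <- setdiff(c("time", "event", covariates, strata), names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", cv, call. = FALSE)
  }
  rhs <- paste(covariates, collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(", strata, ")")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  diverged <- any(grepl("infinite|converge|singular", warn_msgs))
  if (any(!is.finite(beta)) || any(abs(beta) > 15) || diverged) {
    bad <- names(beta)[which.max(abs(beta))]
    if (any(!is.finite(beta))) bad <- names(beta)[!is.finite(beta)][1L]
    stop("non-convergence or monotone likelihood (perfect separation) for ",
         "covariate `", bad, "`", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = names(beta), log_hr = unname(beta), se = unname(se),
                    hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - z * se),
                    ci_upper = exp(unname(beta) + z * se),
                    p_value = 2 * stats::pnorm(abs(unname(beta) / se),
                                               lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, n = fit$n, n_events = fit$nevent, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Stratified Cox model (Breslow ties):", x$n, "subjects,",
      x$n_events, "events\n")
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[, c("term", "hr", "p_value")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' DerSimonian-Laird random-effects meta-analysis of log hazard ratios
#'
#' Pools per-study log hazard ratios with the DerSimonian-Laird moment
#' estimator of between-study variance:
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2` and Cochran's
#' `Q = sum(w * (theta - theta_FE)^2)`; the pooled estimate uses weights
#' `w* = 1/(se^2 + tau2)` with a normal-approximation 95% CI. With one
#' study, or homogeneous studies (`Q <= k - 1`), `tau2 = 0` and the result
#' reduces to inverse-variance fixed-effect pooling.
#'
#' @param log_hr Per-study log hazard ratios.
#' @param se Per-study standard errors (> 0).
#' @param study_ids Optional study labels.
#' @return An object of class `"meta_result"`: `per_study` data frame,
#'   `pooled_log_hr`, `pooled_hr`, `pooled_ci_95` (on the HR scale),
#'   `tau2`, `q_stat`, `method = "DerSimonian-Laird"`.
#' @export
random_effects_meta <- function(log_hr, se, study_ids = NULL) {
  k <- length(log_hr)
  if (k == 0L) stop("need >= 1 study", call. = FALSE)
  if (length(se) != k) stop("`log_hr` and `se` lengths differ", call. = FALSE)
  if (any(!is.finite(log_hr)) || any(!is.finite(se)) || any(se <= 0))
    stop("log_hr must be finite and se > 0", call. = FALSE)
  if (is.null(study_ids)) study_ids <- paste0("study", seq_len(k))

  w <- 1 / se^2
  theta_fe <- sum(w * log_hr) / sum(w)
  q <- sum(w * (log_hr - theta_fe)^2)
  tau2 <- if (k > 1L) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * log_hr) / sum(w_star)
  se_pooled <- sqrt(1 / sum(w_star))
  z <- stats::qnorm(0.975)
  out <- list(per_study = data.frame(study_id = study_ids, log_hr = log_hr,
                                     se = se, stringsAsFactors = FALSE),
              pooled_log_hr = pooled,
              pooled_se = se_pooled,
              pooled_hr = exp(pooled),
              pooled_ci_95 = exp(c(pooled - z * se_pooled, pooled + z * se_pooled)),
              tau2 = tau2, q_stat = q, method = "DerSimonian-Laird")
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Random-effects meta-analysis (", x$method, "), k = ",
      nrow(x$per_study), " studies\n", sep = "")
  cat(sprintf("  pooled HR %.2f (95%% CI %.2f-%.2f), tau^2 = %.4f, Q = %.2f\n",
              x$pooled_hr, x$pooled_ci_95[1L], x$pooled_ci_95[2L],
              x$tau2, x$q_stat))
  invisible(x)
}

#' Per-study Cox fits pooled by random-effects meta-analysis
#'
#' Convenience wrapper for the multi-cohort prognostic analysis: fits an
#' unstratified Cox model for `covariate` within each study, then pools the
#' per-study log hazard ratios with [random_effects_meta()].
#'
#' @param records Survival records across studies (`time`, `event`,
#'   `study_id`, covariate column).
#' @param covariate The covariate whose HR is meta-analysed.
#' @return A `"meta_result"` whose `per_study` table also carries `n` and
#'   `n_events`.
#' @export
meta_cox_by_study <- function(records, covariate = "pcl_like") {
  studies <- unique(records$study_id)
  rows <- lapply(studies, function(s) {
    rec <- records[records$study_id == s, ]
    cf <- cox_fit(rec, covariates = covariate, strata = NULL)
    data.frame(study_id = s, log_hr = cf$table$log_hr[1L], se = cf$table$se[1L],
               n = cf$n, n_events = cf$n_events, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  res <- random_effects_meta(tab$log_hr, tab$se, tab$study_id)
  res$per_study <- tab
  res
}
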