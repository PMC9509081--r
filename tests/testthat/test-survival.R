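test_that("KM with no censoring equals the empirical survival function", {
  t1 <- c(3, 5, 7, 11, 13)
  rec <- data.frame(time = c(t1, t1 * 2), event = 1L,
                    pcl_like = rep(c(TRUE, FALSE), each = 5))
  km <- km_logrank(rec)
  g1 <- km$curves[km$curves$group == "TRUE", ]
  expect_equal(g1$survival, 1 - seq_along(t1) / length(t1), tolerance = 1e-12)
})

test_that("identical groups give a null log-rank statistic", {
  t1 <- c(2, 4, 6, 8)
  rec <- data.frame(time = c(t1, t1 + 1e-9), event = 1L,
                    pcl_like = rep(c(TRUE, FALSE), each = 4))
  km <- km_logrank(rec)
  expect_lt(km$chisq, 1e-6)
  expect_gt(km$p_value, 0.999)
  expect_error(km_logrank(rec[rec$pcl_like, ]), "2 non-empty groups")
})

test_that("log-rank matches a hand-tabulated 6-subject worked example", {
  # groups A (times 1,3,5) and B (times 2,4,6), all events; risk sets by hand:
  # t=1: E_A=3/6, V=1/4;  t=2: E_A=2/5, V=6/25;  t=3: E_A=2/4, V=1/4
  # t=4: E_A=1/3, V=2/9;  t=5: E_A=1/2, V=1/4;   t=6: E_A=0
  rec <- data.frame(time = 1:6, event = 1L,
                    pcl_like = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  e_a <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2
  v_a <- 1 / 4 + 6 / 25 + 1 / 4 + 2 / 9 + 1 / 4
  hand_chisq <- (3 - e_a)^2 / v_a
  km <- km_logrank(rec)
  expect_equal(km$chisq, hand_chisq, tolerance = 1e-10)
  expect_identical(km$df, 1L)
})

test_that("two-group log-rank equals the Cox score test on no-tie data", {
  set.seed(21)
  n <- 60
  x <- rep(c(0, 1), each = n / 2)
  tt <- rexp(n, rate = 0.05 * exp(0.5 * x))
  rec <- data.frame(time = tt, event = 1L, pcl_like = x == 1, study_id = "s1")
  km <- km_logrank(rec)
  cf <- survival::coxph(survival::Surv(time, event) ~ pcl_like, data = rec,
                        ties = "breslow")
  expect_equal(km$chisq, unname(cf$score), tolerance = 1e-6)
})

test_that("composite groups join factor levels with the separator", {
  set.seed(22)
  rec <- data.frame(time = rexp(40, 0.1), event = 1L,
                    pcl_like = rep(c(TRUE, FALSE), 20),
                    riss = rep(c("I", "III"), each = 20))
  km <- km_logrank(rec, group_by = c("riss", "pcl_like"))
  expect_identical(km$df, 3L)
  expect_true("I & TRUE" %in% km$curves$group)
})

test_that("a strong simulated effect is detected with high power", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 500
    x <- rep(c(0, 1), each = n)
    tt <- rexp(2 * n, rate = 0.02 * 2^x)   # true HR = 2, no censoring
    rec <- data.frame(time = tt, event = 1L, pcl_like = x == 1)
    km_logrank(rec)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Cox partial likelihood is maximized where the grid-search oracle says", {
  # 5 subjects, single stratum, no ties, binary covariate
  rec <- data.frame(time = c(1.3, 2.1, 3.7, 4.2, 6.9),
                    event = c(1L, 1L, 0L, 1L, 1L),
                    pcl_like = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                    study_id = "s1")
  cf <- cox_fit(rec, covariates = "pcl_like", strata = NULL)
  orc <- optimize(function(b) oracle_cox_loglik(b, rec$time, rec$event,
                                                as.numeric(rec$pcl_like)),
                  interval = c(-6, 6), maximum = TRUE, tol = 1e-10)
  expect_equal(cf$table$log_hr, orc$maximum, tolerance = 1e-6)
  ll_fit <- oracle_cox_loglik(cf$table$log_hr, rec$time, rec$event,
                              as.numeric(rec$pcl_like))
  expect_equal(ll_fit, orc$objective, tolerance = 1e-8)
})

test_that("stratified Cox recovers the simulated PCL-like hazard ratio", {
  cfg <- sim_config(n_genes = 10L, n_signal_genes = 0L, n_confounded_genes = 0L,
                    seed = 77L)
  studies <- simulate_multistudy(cfg, n_studies = 4L, per_study_n = 400L)
  rec <- do.call(rbind, lapply(studies, function(s) s$survival))
  pfs <- rec[rec$endpoint == "PFS", ]
  cf <- cox_fit(pfs, covariates = "pcl_like", strata = "study_id")
  expect_gt(cf$table$hr, 1.4)
  expect_lt(cf$table$hr, 2.4)
  expect_true(cf$table$ci_lower < cf$table$hr && cf$table$hr < cf$table$ci_upper)
})

test_that("a null covariate's confidence interval covers HR = 1 at the nominal rate", {
  covered <- vapply(1:60, function(seed) {
    set.seed(seed)
    n <- 150
    rec <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1L, 0.8),
                      pcl_like = runif(n) < 0.4, study_id = "s1")
    tab <- cox_fit(rec, covariates = "pcl_like", strata = NULL)$table
    tab$ci_lower <= 1 && 1 <= tab$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("Cox errors name degenerate or separating covariates", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = 1L,
                    pcl_like = TRUE, study_id = "s1")
  expect_error(cox_fit(rec, covariates = "pcl_like", strata = NULL),
               "constant covariate: pcl_like")
  # perfect separation: all early events in one group
  sep <- data.frame(time = c(1, 2, 3, 4, 100, 200, 300, 400),
                    event = c(rep(1L, 4), rep(0L, 4)),
                    pcl_like = rep(c(TRUE, FALSE), each = 4), study_id = "s1")
  expect_error(cox_fit(sep, covariates = "pcl_like", strata = NULL),
               "pcl_like")
})

test_that("DerSimonian-Laird pooling matches the hand-computed example", {
  # theta = (0.2, 0.6, 1.0), se = 0.2 each: w = 25, theta_FE = 0.6,
  # Q = 25*(0.4^2 + 0 + 0.4^2) = 8, denom = 75 - 1875/75 = 50,
  # tau2 = (8 - 2)/50 = 0.12, w* = 1/(0.04 + 0.12) = 6.25 -> pooled = 0.6,
  # se_pooled = sqrt(1/18.75)
  mr <- random_effects_meta(c(0.2, 0.6, 1.0), rep(0.2, 3))
  expect_equal(mr$q_stat, 8, tolerance = 1e-10)
  expect_equal(mr$tau2, 0.12, tolerance = 1e-10)
  expect_equal(mr$pooled_log_hr, 0.6, tolerance = 1e-10)
  expect_equal(mr$pooled_se, sqrt(1 / 18.75), tolerance = 1e-10)
  ci <- log(mr$pooled_ci_95)
  expect_equal(ci, 0.6 + c(-1, 1) * qnorm(0.975) * sqrt(1 / 18.75),
               tolerance = 1e-10)
})

test_that("meta edge cases: single study, homogeneity, bounds, fixed-effect limit", {
  one <- random_effects_meta(0.4, 0.1)
  expect_equal(one$pooled_log_hr, 0.4)
  expect_equal(one$tau2, 0)

  homo <- random_effects_meta(c(0.5, 0.5), c(0.2, 0.2))
  expect_equal(homo$tau2, 0)
  expect_equal(homo$pooled_log_hr, 0.5)

  set.seed(23)
  th <- rnorm(6); se <- runif(6, 0.1, 0.5)
  mr <- random_effects_meta(th, se)
  expect_gte(mr$pooled_log_hr, min(th))
  expect_lte(mr$pooled_log_hr, max(th))
  expect_true(mr$pooled_ci_95[1] < mr$pooled_hr &&
                mr$pooled_hr < mr$pooled_ci_95[2])

  # tau2 = 0 recovers inverse-variance fixed-effect pooling
  homo_w <- random_effects_meta(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.4))
  w <- 1 / c(0.1, 0.2, 0.4)^2
  expect_equal(homo_w$pooled_log_hr, sum(w * 0.2) / sum(w), tolerance = 1e-12)

  expect_error(random_effects_meta(numeric(0), numeric(0)), ">= 1")
  expect_error(random_effects_meta(c(0.1, 0.2), c(0.1, -0.1)), "se > 0")
})

test_that("DL pooling agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(24)
  for (i in 1:5) {
    k <- sample(2:8, 1)
    th <- rnorm(k, 0.5, 0.4)
    se <- runif(k, 0.05, 0.4)
    mr <- random_effects_meta(th, se)
    ref <- metafor::rma(yi = th, sei = se, method = "DL")
    expect_equal(mr$pooled_log_hr, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mr$tau2, ref$tau2, tolerance = 1e-8)
  }
})

test_that("per-study Cox plus meta pools toward the simulated hazard ratio", {
  cfg <- sim_config(n_genes = 10L, n_signal_genes = 0L, n_confounded_genes = 0L,
                    seed = 88L)
  studies <- simulate_multistudy(cfg, n_studies = 6L, per_study_n = 300L)
  rec <- do.call(rbind, lapply(studies, function(s) s$survival))
  mr <- meta_cox_by_study(rec[rec$endpoint == "PFS", ])
  expect_identical(nrow(mr$per_study), 6L)
  expect_gt(mr$pooled_hr, 1.3)
  expect_lt(mr$pooled_hr, 2.6)
  expect_gte(mr$tau2, 0)
})
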