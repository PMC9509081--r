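make_toy_model <- function(genes, signs, weights = rep(1, length(genes)),
                           means = rep(0, length(genes)),
                           sds = rep(1, length(genes)), threshold = 0) {
  structure(list(genes = data.frame(gene_id = genes, sign = signs,
                                    weight = weights, stringsAsFactors = FALSE),
                 train_stats = data.frame(gene_id = genes, mean = means, sd = sds,
                                          stringsAsFactors = FALSE),
                 threshold = threshold, provenance = "built", metadata = ""),
            class = "pcl_classifier")
}

test_that("the PCL-like score is the signed mean of standardized expression", {
  # 5-gene toy model, mixed signs, hand-computed expectation
  m <- make_toy_model(paste0("g", 1:5), signs = c(1, 1, -1, -1, 1),
                      weights = c(1, 2, 1, 0.5, 1),
                      means = c(0, 1, -1, 2, 0), sds = c(1, 2, 1, 4, 0.5))
  x <- matrix(c(1.0, 3.0, -2.0, 4.0, 0.25), ncol = 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  z <- (x[, 1] - c(0, 1, -1, 2, 0)) / c(1, 2, 1, 4, 0.5)
  hand <- mean(c(1, 2, -1, -0.5, 1) * z)
  sc <- compute_score(m, x)
  expect_equal(sc$pcl_score, hand, tolerance = 1e-12)
  expect_identical(sc$n_genes_used, 5L)

  # all-centered sample scores 0; single-gene model passes z through
  x0 <- matrix(c(0, 1, -1, 2, 0), ncol = 1,
               dimnames = list(paste0("g", 1:5), "s0"))
  expect_equal(compute_score(m, x0)$pcl_score, 0)
  m1 <- make_toy_model("g1", signs = 1)
  expect_equal(compute_score(m1, matrix(3.2, dimnames = list("g1", "s")))$pcl_score, 3.2)
})

test_that("missing model genes are skipped, counted, and bounded by coverage", {
  m <- make_toy_model(paste0("g", 1:4), signs = rep(1, 4))
  x <- matrix(c(1, 2), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  sc <- compute_score(m, x, min_coverage = 0.5)
  expect_identical(sc$n_genes_used, 2L)
  expect_identical(sc$n_genes_missing, 2L)
  expect_equal(sc$pcl_score, mean(c(1, 2)))
  expect_error(compute_score(m, x, min_coverage = 0.75), "coverage")
})

test_that("threshold calibration is the minimum of discovery pPCL scores", {
  expect_equal(calibrate_threshold(c(3.55, 4.2, 7.0)), 3.55)
  expect_equal(calibrate_threshold(5.1), 5.1)
  set.seed(6)
  s <- rnorm(50)
  expect_equal(calibrate_threshold(s), min(s))
  expect_error(calibrate_threshold(numeric(0)), "pPCL")
})

test_that("classification is monotone in the score with an inclusive threshold", {
  m <- make_toy_model("g1", signs = 1, threshold = 1.5)
  x <- matrix(c(1.4999, 1.5, 1.6), nrow = 1,
              dimnames = list("g1", c("below", "at", "above")))
  sc <- compute_score(m, x)
  expect_identical(sc$call, c("not-PCL-like", "PCL-like", "PCL-like"))
  expect_true(all(diff(sc$pcl_score) > 0))
})

test_that("LOOCV selects a size that recovers the signal and honors tie-breaks", {
  cfg <- sim_config(n_samples = 70L, n_genes = 200L, n_signal_genes = 20L,
                    n_confounded_genes = 20L, signal_effect = 0.5, seed = 21L)
  coh <- simulate_cohort(cfg)
  cv <- loocv_select_size(coh$expression, coh$annotation,
                          size_grid = c(5L, 10L, 20L, 40L, 80L))
  expect_true(cv$k_star %in% c(5L, 10L, 20L, 40L, 80L))
  expect_gte(max(cv$performance$auc), 0.95)
  expect_identical(cv$n_folds_skipped, 0L)

  # singleton grid returns that size
  cv1 <- loocv_select_size(coh$expression, coh$annotation, size_grid = 15L)
  expect_identical(cv1$k_star, 15L)

  # ties break to the smallest size: near-separable data saturates the AUC
  strong <- simulate_cohort(sim_config(n_samples = 50L, n_genes = 80L,
                                       n_signal_genes = 20L, n_confounded_genes = 0L,
                                       signal_effect = 3, noise_sd = 0.1, seed = 22L))
  cvs <- loocv_select_size(strong$expression, strong$annotation,
                           size_grid = c(5L, 10L, 20L))
  expect_equal(cvs$performance$auc, rep(1, 3))
  expect_identical(cvs$k_star, 5L)

  # a class missing from the discovery set is an error
  ann_one <- coh$annotation
  ann_one$disease_label <- "NDMM"
  expect_error(loocv_select_size(coh$expression, ann_one, size_grid = 5L), "pPCL")
})

test_that("per-fold training never sees the held-out label", {
  coh <- simulate_cohort(tiny_config(seed = 33L))
  cv <- loocv_select_size(coh$expression, coh$annotation, size_grid = c(5L, 10L))
  # permute the disease labels (keeping class counts): the held-out scores,
  # which depend only on CTC/burden-based rankings, must not change
  ann2 <- coh$annotation
  set.seed(1)
  ann2$disease_label <- sample(ann2$disease_label)
  cv2 <- loocv_select_size(coh$expression, ann2, size_grid = c(5L, 10L))
  expect_identical(cv$held_out_scores, cv2$held_out_scores)
})

test_that("the built classifier detects all discovery pPCL and generalizes", {
  cfg <- sim_config(n_samples = 90L, n_genes = 300L, n_signal_genes = 30L,
                    n_confounded_genes = 30L, seed = 41L)
  coh <- simulate_cohort(cfg)
  fit <- pcl_classifier(coh$expression, coh$annotation, size_grid = c(10L, 30L))
  expect_s3_class(fit, "pcl_classifier")
  expect_identical(fit$provenance, "built")
  expect_true(all(fit$genes$sign %in% c(-1, 1)))

  disc <- predict(fit, coh$expression)
  ppcl <- coh$annotation$disease_label == "pPCL"
  expect_true(all(disc$call[ppcl] == "PCL-like"))  # exact, by construction
  expect_equal(min(disc$pcl_score[ppcl]), fit$threshold)

  val_cfg <- cfg; val_cfg$seed <- 142L
  val <- simulate_cohort(val_cfg)
  vs <- predict(fit, val$expression)
  vp <- val$annotation$disease_label == "pPCL"
  expect_gte(mean(vs$call[vp] == "PCL-like"), 0.8)

  # determinism: rebuilding gives the identical model
  fit2 <- pcl_classifier(coh$expression, coh$annotation, size_grid = c(10L, 30L))
  expect_identical(fit$genes, fit2$genes)
  expect_identical(fit$threshold, fit2$threshold)
})

test_that("model methods expose genes, weights and the LOOCV curve", {
  coh <- simulate_cohort(tiny_config(seed = 51L))
  fit <- pcl_classifier(coh$expression, coh$annotation, size_grid = c(5L, 10L))
  cw <- coef(fit)
  expect_named(cw)
  expect_true(all(abs(cw) == 1))
  expect_output(print(fit), "PCL-like classifier")
  expect_output(summary(fit), "LOOCV")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("noiseless platform distortion leaves scores unchanged after re-standardization", {
  cfg <- tiny_config(seed = 61L)
  coh <- simulate_cohort(cfg)
  fit <- pcl_classifier(coh$expression, coh$annotation, size_grid = c(5L, 10L))
  base <- predict(fit, coh$expression, ref_expr = coh$expression)
  dist <- platform_distort(coh, cfg, noise_sd = 0)
  moved <- predict(fit, dist, ref_expr = dist)
  expect_equal(moved$pcl_score, base$pcl_score, tolerance = 1e-12)

  # with noise the scores stay strongly correlated across platforms
  noisy <- platform_distort(coh, cfg, noise_sd = cfg$noise_sd)
  ns <- predict(fit, noisy, ref_expr = noisy)
  expect_gt(cor(ns$pcl_score, base$pcl_score), 0.9)
})

test_that("model JSON serialization round-trips and validates", {
  coh <- simulate_cohort(tiny_config(seed = 71L))
  fit <- pcl_classifier(coh$expression, coh$annotation, size_grid = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- load_packaged_model(path)
  expect_equal(back$genes, fit$genes)
  expect_equal(back$threshold, fit$threshold)
  sc1 <- compute_score(fit, coh$expression)
  sc2 <- compute_score(back, coh$expression)
  expect_equal(sc2$pcl_score, sc1$pcl_score, tolerance = 1e-12)
})

test_that("the packaged model fixture loads, validates, and rejects corruption", {
  m <- load_packaged_model()
  expect_identical(nrow(m$genes), 54L)
  expect_identical(m$provenance, "packaged_table2")
  expect_null(m$train_stats)
  # scoring without a reference cohort is refused
  x <- matrix(0, nrow = 54, ncol = 1, dimnames = list(m$genes$gene_id, "s1"))
  expect_error(compute_score(m, x), "ref_stats")

  # a duplicated gene id fails validation
  raw <- jsonlite::fromJSON(system.file("extdata", "pcl54_model_synthetic.json",
                                        package = "pcllike"))
  raw$genes$gene_id[2L] <- raw$genes$gene_id[1L]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_packaged_model(bad), "duplicated")
  expect_error(load_packaged_model("/nonexistent/model.json"), "not found")
})
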