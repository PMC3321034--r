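test_that("median split halves the cohort with the odd sample going low", {
  expect_identical(as.character(median_split(c(a = 1, b = 2, c = 3, d = 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(c(a = 1, b = 2, c = 3))),
                   c("low", "low", "high"))
  # degenerate all-equal scores: assignment by sample ID, sizes differ by <= 1
  sp <- median_split(c(b = 1, a = 1, c = 1))
  expect_identical(as.character(sp[c("a", "b")]), c("low", "low"))
  expect_identical(as.character(sp["c"]), "high")
  expect_lte(abs(sum(sp == "low") - sum(sp == "high")), 1)
})

test_that("log-rank test is null for identical groups and KM starts at 1", {
  d <- data.frame(sample_id = sprintf("s%02d", 1:20),
                  time = rep(c(50, 120, 300, 600, 900), 4),
                  event = TRUE,
                  subtype = "UNKNOWN", stringsAsFactors = FALSE)
  g <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  km <- km_logrank(d, stats::setNames(g, d$sample_id))
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.999)
  expect_true(all(summary(km$fit, times = 0)$surv == 1))
})

test_that("log-rank warns when a group has no events", {
  d <- data.frame(sample_id = letters[1:10], time = 1:10,
                  event = rep(c(TRUE, FALSE), each = 5),
                  subtype = "UNKNOWN", stringsAsFactors = FALSE)
  g <- stats::setNames(factor(rep(c("A", "B"), each = 5)), d$sample_id)
  expect_warning(km_logrank(d, g), "zero events")
})

test_that("a metagene split separates survival on an associated synthetic cohort", {
  p <- sim_params(n_samples = 400, n_background_genes = 0,
                  signature = small_signature(6),
                  loadings = seq(0.5, 2.5, length.out = 6),
                  hazard_coef = 1.5, seed = 8)
  co <- simulate_cohort(p)
  sc <- compute_metagene(co$expression, small_signature(6))
  surv <- as_survival_dataset(co$clinical)
  km <- km_logrank(surv, median_split(sc)[surv$sample_id])
  expect_lt(km$p, 0.05)
  # log-rank p agrees with the Cox score test for the binary group covariate
  grp <- as.integer(median_split(sc)[surv$sample_id] == "high")
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ grp)
  expect_equal(km$p, unname(summary(fit)$sctest["pvalue"]), tolerance = 0.05)
})

test_that("univariate Cox recovers the generative hazard coefficient", {
  p <- sim_params(n_samples = 500, n_background_genes = 0,
                  signature = small_signature(3), hazard_coef = 1.0, seed = 31)
  co <- simulate_cohort(p)
  surv <- as_survival_dataset(co$clinical)
  fit <- cox_univariate(surv, co$truth$latent_activity[surv$sample_id])
  expect_identical(fit$terms$term, "covariate")
  expect_gt(fit$terms$coef, 0.5)
  expect_lt(fit$terms$coef, 1.5)
  # CoxFit invariants: HR = exp(coef), CI = exp(coef +/- 1.96 se)
  expect_equal(fit$terms$hr, exp(fit$terms$coef))
  expect_equal(fit$terms$ci_lo, exp(fit$terms$coef - 1.96 * fit$terms$se))
  expect_equal(fit$terms$ci_hi, exp(fit$terms$coef + 1.96 * fit$terms$se))
})

test_that("degenerate designs are rejected", {
  d <- data.frame(sample_id = letters[1:6], time = c(5, 8, 13, 21, 34, 55),
                  event = TRUE, subtype = "UNKNOWN", stringsAsFactors = FALSE)
  expect_error(cox_univariate(d, rep(0, 6)), "zero variance")
  expect_error(cox_univariate(d[1:2, ], c(1, 2) * NA), "non-finite")
})

test_that("deviation-coded multivariate Cox yields four contrasts summing to zero", {
  cen <- make_centroids(n_genes = 16, sep = 2)
  p <- sim_params(n_samples = 250, n_background_genes = 10,
                  signature = small_signature(6),
                  loadings = seq(0.5, 2.5, length.out = 6),
                  hazard_coef = 1.2, subtype_centroids = cen,
                  centroid_sd = 0.4, seed = 17)
  co <- simulate_cohort(p)
  sc <- compute_metagene(co$expression, small_signature(6))
  surv <- as_survival_dataset(co$clinical)
  fit <- cox_multivariate_deviation(surv, sc[surv$sample_id])
  expect_identical(fit$terms$term,
                   c("metagene", paste0("subtype:",
                     c("Mesenchymal", "Classical", "Neural", "Proneural"))))
  # deviation-coding identity
  expect_lt(abs(sum(fit$terms$coef[-1])), 1e-8)
  # model has 1 + (L - 1) = 4 degrees of freedom
  expect_equal(fit$lrt$df, 4)
  # the generator ties hazard to the metagene, not the subtype: the
  # metagene term should dominate
  expect_lt(fit$terms$p[1], 0.05)
  expect_gt(fit$terms$coef[1], 0)
})

test_that("subtype contrasts are null-calibrated when subtype has no effect", {
  cen <- make_centroids(n_genes = 16, sep = 2)
  ok <- 0L
  for (seed in 1:6) {
    p <- sim_params(n_samples = 200, n_background_genes = 0,
                    signature = small_signature(4), hazard_coef = 0,
                    subtype_centroids = cen, centroid_sd = 0.4, seed = seed)
    co <- simulate_cohort(p)
    sc <- compute_metagene(co$expression, small_signature(4))
    surv <- as_survival_dataset(co$clinical)
    fit <- cox_multivariate_deviation(surv, sc[surv$sample_id])
    sub <- fit$terms[-1, ]
    ok <- ok + all(abs(sub$coef) < 2 * sub$se)
  }
  expect_gte(ok, 4L)
})
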