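test_that("null logistic model reproduces the closed-form AIC", {
  # balanced y, no features: loglik = n log(1/2), AIC = 2 - 2 n log(1/2)
  y <- rep(c(0, 1), each = 50)
  res <- logistic_fit_aic(NULL, y)
  expect_equal(res$aic, 2 - 2 * 100 * log(0.5), tolerance = 1e-8)
  expect_equal(res$n, 100)
})

test_that("perfect separation raises a classed error", {
  y <- rep(c(0, 1), each = 20)
  expect_error(logistic_fit_aic(matrix(y, ncol = 1), y),
               class = "igsem_separation_error")
  expect_error(logistic_fit_aic(matrix(0.5, 10, 1), rep(1, 10)),
               "both classes")
})

test_that("Wald p values are uniform under the null", {
  set.seed(80)
  pvals <- replicate(1000, {
    y <- rbinom(100, 1, 0.5)
    f <- matrix(rnorm(100), ncol = 1)
    tryCatch(logistic_fit_aic(f, y)$coefficients$p_value[2],
             error = function(e) NA_real_)
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("score combination follows the max and Fisher definitions", {
  pA <- matrix(c(0.01, 0.20), 2, 1)
  pL <- c(0.03, 0.50)
  expect_equal(unname(combine_snp_scores(pA, pL, "max")), 0.03)

  # single pair (0.01, 0.03): statistic -2(log .01 + log .03) = 16.2235,
  # chi^2_4 upper tail e^(-x/2)(1 + x/2) = 2.73e-3
  stat <- -2 * (log(0.01) + log(0.03))
  expect_equal(stat, 16.2235, tolerance = 1e-4)
  pf <- fisher_combine(0.01, 0.03)
  expect_equal(pf, exp(-stat / 2) * (1 + stat / 2), tolerance = 1e-12)
  expect_equal(pf, 2.73e-3, tolerance = 1e-2)

  # boundary: all p = 1
  expect_equal(unname(combine_snp_scores(matrix(1, 2, 3), c(1, 1), "max")),
               rep(1, 3))
  expect_equal(unname(combine_snp_scores(matrix(1, 2, 3), c(1, 1),
                                         "fisher")), rep(1, 3))
  # zero p values are clamped with a warning
  expect_warning(combine_snp_scores(matrix(c(0, 0.5), 2, 1), c(0.5, 0.5),
                                    "max"), "clamped")
})

test_that("Fisher combination of uniform nulls follows chi-squared(4)", {
  set.seed(81)
  p <- fisher_combine(runif(1e4), runif(1e4))
  # combined p is uniform iff the statistic is chi^2_4
  expect_lt(suppressWarnings(
    stats::ks.test(p, "punif")$statistic), 0.02)
})

test_that("retrieval AUC matches pair enumeration and handles ties", {
  expect_equal(retrieval_auc(c(0.01, 0.02, 0.5, 0.9),
                             c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(retrieval_auc(c(0.1, 0.2, 0.3, 0.4),
                             c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(retrieval_auc(rep(0.5, 6), c(1, 1, 0, 0, 0, 1)), 0.5)
  expect_error(retrieval_auc(c(0.1, 0.2), c(TRUE, TRUE)), "at least one")
  # invariant under strictly monotone transforms
  set.seed(82)
  sc <- runif(30); tr <- rbinom(30, 1, 0.4)
  expect_equal(retrieval_auc(sc, tr), retrieval_auc(qnorm(sc), tr))
  expect_equal(retrieval_auc(sc, tr), retrieval_auc(sc^3, tr))
})

test_that("retrieval AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  sc <- round(runif(40), 2)   # induce some ties
  tr <- rbinom(40, 1, 0.5)
  ours <- retrieval_auc(sc, tr)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = tr, predictor = sc, direction = ">", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("baseline SNP p values: modes coincide for one SNP, null is uniform", {
  set.seed(84)
  g <- matrix(rbinom(200, 2, 0.3), ncol = 1)
  y <- rbinom(200, 1, 0.5)
  pu <- baseline_snp_pvalues(g, y, "univariate")
  pm <- baseline_snp_pvalues(g, y, "multivariate")
  expect_equal(pu, pm, tolerance = 1e-10)

  pvals <- replicate(400, {
    g1 <- matrix(rbinom(150, 2, 0.3), ncol = 1)
    y1 <- rbinom(150, 1, 0.5)
    baseline_snp_pvalues(g1, y1, "univariate")
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("latent-to-phenotype p values have length m and a uniform null", {
  set.seed(85)
  sc <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("G1", "G2", "G3")))
  y <- rbinom(100, 1, 0.5)
  pL <- latent_phenotype_pvalues(sc, y)
  expect_length(pL, 3)
  expect_named(pL, c("G1", "G2", "G3"))

  pvals <- replicate(400, {
    latent_phenotype_pvalues(matrix(rnorm(150), ncol = 1),
                             rbinom(150, 1, 0.5))
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("compare_models_aic returns the five labelled models", {
  rep1 <- run_replicate(sim_config(seed = 86))
  expect_setequal(rep1$aic$model,
                  c("fitted_latents", "pcs_regions", "all_regions",
                    "all_regions_snps", "all_snps"))
  expect_true(all(is.finite(rep1$aic$aic)))
  expect_true(all(rep1$auc$auc >= 0 & rep1$auc$auc <= 1))
})
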