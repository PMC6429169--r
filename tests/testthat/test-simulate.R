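test_that("genotypes follow Hardy-Weinberg at a forced allele frequency", {
  n <- 1e5
  gen <- simulate_genotypes(n, 1, maf = 0.5, seed = 61)
  freq <- tabulate(gen$g + 1L, 3L) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  zero <- simulate_genotypes(50, 1, maf = 0, seed = 62)
  expect_true(all(zero$g == 0))
})

test_that("MAF draws have the Beta(1,2) mean", {
  gen <- simulate_genotypes(2, 1e4, beta_shapes = c(1, 2), seed = 63)
  expect_equal(mean(gen$maf), 1 / 3, tolerance = 0.02)
  expect_error(simulate_genotypes(10, 2, beta_shapes = c(-1, 2)), "positive")
})

test_that("HWE goodness of fit passes at the nominal rate", {
  # chi-squared GOF against the known per-SNP genotype probabilities,
  # restricted to frequencies where the large-sample approximation holds
  set.seed(64)
  maf <- runif(1000, 0.05, 0.95)
  gen <- simulate_genotypes(5000, 1000, maf = maf)
  pvals <- vapply(seq_len(1000), function(j) {
    f <- maf[j]
    obs <- tabulate(gen$g[, j] + 1L, 3L)
    suppressWarnings(
      stats::chisq.test(obs, p = c((1 - f)^2, 2 * f * (1 - f), f^2))$p.value
    )
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.94)
})

test_that("dataset honours the count and block-structure invariants", {
  ds <- simulate_dataset(sim_config(seed = 65))
  expect_equal(dim(ds$g), c(500L, 20L))
  expect_equal(dim(ds$x), c(500L, 50L))
  expect_equal(dim(ds$z_true), c(500L, 5L))
  expect_equal(sum(ds$truth$A != 0), 10L)
  expect_true(all(ds$truth$A %in% c(-1, 0, 1)))
  expect_equal(sum(ds$truth$phenotype_weights != 0), 2L)
  expect_true(all(abs(ds$truth$phenotype_weights[
    ds$truth$phenotype_weights != 0]) == 10))
  # B block structure: each region loads only on its own group
  pat <- igsem:::loading_pattern(ds$spec)
  expect_true(all(ds$truth$B[!pat] == 0))
  expect_true(all(ds$truth$B[pat] >= 0.5 & ds$truth$B[pat] <= 1.5))
  # true-effect SNPs: nonzero weight on a phenotype-linked latent
  linked <- ds$truth$phenotype_weights != 0
  expect_equal(unname(ds$truth$true_effect_snps),
               unname(colSums(abs(ds$truth$A[linked, , drop = FALSE])) > 0))
})

test_that("simulation is deterministic under a fixed seed", {
  d1 <- simulate_dataset(sim_config(seed = 66))
  d2 <- simulate_dataset(sim_config(seed = 66))
  expect_identical(d1$g, d2$g)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$truth$A, d2$truth$A)
})

test_that("no signal and no noise gives identically zero regions", {
  cfg <- sim_config(latent_noise_sd = 0, region_noise_sd = 0,
                    n_nonzero_A = 0L, seed = 67)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$x == 0))
  expect_true(all(ds$z_true == 0))
})

test_that("phenotype rate responds monotonically to the weight scale", {
  rates <- vapply(c(0.1, 1, 10), function(wm) {
    ds <- simulate_dataset(sim_config(phenotype_weight = wm, seed = 68))
    z <- ds$z_true; w <- ds$truth$phenotype_weights
    mean(plogis(abs(as.numeric(z %*% w))))   # tail mass beyond 1/2
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("within-group region correlations approach one as noise vanishes", {
  cfg <- sim_config(n_individuals = 2000L, latent_noise_sd = 0.01,
                    region_noise_sd = 0.01, seed = 69)
  ds <- simulate_dataset(cfg)
  first_group <- ds$spec$region_ids[ds$spec$membership == "G1"]
  cc <- cor(ds$x[, first_group])
  expect_true(all(abs(cc) > 0.999))
})

test_that("swaps preserve sizes, change two links each, and never return", {
  spec <- build_spec(data.frame(
    region_id = c("r1", "r2", "r3", "r4", "r5"),
    group_code = c("G1", "G1", "G1", "G2", "G2")
  ))
  sw <- swap_region_links(spec, 1, seed = 70)
  sizes <- table(sw$membership)[c("G1", "G2")]
  expect_equal(unname(as.integer(sizes)), c(3L, 2L))
  expect_equal(sum(sw$membership != spec$membership), 2L)

  sw_a <- swap_region_links(spec, 1, seed = 71)
  sw_b <- swap_region_links(spec, 1, seed = 71)
  expect_identical(sw_a$membership, sw_b$membership)

  # G2 has 2 regions: after both have moved once, a further swap must fail
  expect_error(swap_region_links(spec, 3, seed = 72), "previous group")
  expect_error(swap_region_links(spec, 0), ">= 1")
})

test_that("dataset files round-trip through write_dataset/load_study", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(tiny_config(seed = 73))
  write_dataset(ds, dir)
  tabs <- load_study(list(genotypes = file.path(dir, "genotypes.csv"),
                          regions = file.path(dir, "regions.csv"),
                          grouping = file.path(dir, "grouping.tsv")))
  expect_equal(as.matrix(tabs$genotypes[, -1]), ds$g, ignore_attr = TRUE)
  expect_equal(as.matrix(tabs$regions[, -1]), ds$x, ignore_attr = TRUE,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unname(truth$phenotype_weights),
               unname(ds$truth$phenotype_weights), tolerance = 1e-12)
  expect_equal(unname(as.matrix(truth$A)), unname(ds$truth$A),
               tolerance = 1e-12)
  expect_setequal(truth$true_effect_snps,
                  names(which(ds$truth$true_effect_snps)))
})
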