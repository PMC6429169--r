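#' Simulation configuration
#'
#' Collects the generative settings for the synthetic study data: genotypes
#' in Hardy-Weinberg equilibrium with Beta-distributed minor allele
#' frequencies, latent variables as noisy linear combinations of the centred
#' SNP values, region measurements as noisy linear combinations of the
#' latents (block loading structure), and a logistic binary phenotype driven
#' by a subset of the latents.
#'
#' Defaults reproduce the reference study design: 500 individuals, 20 SNPs,
#' five region groups of sizes 20/10/10/5/5 (50 regions), MAFs from
#' Beta(1, 2), 10 nonzero SNP-to-latent weights of value +/-1, loadings
#' uniform on (0.5, 1.5), Gaussian noise with sd 2 on both the latent and
#' the region layer, and 2 phenotype-linked latents with weights +/-10.
#'
#' @param n_individuals Number of samples.
#' @param n_snps Number of SNPs (p).
#' @param group_sizes Integer vector of region-group sizes (all >= 2);
#'   its length is the number of latent variables m.
#' @param maf_beta_shapes Shape parameters of the Beta distribution the minor
#'   allele frequencies are drawn from.
#' @param n_nonzero_A Number of nonzero entries (value +/-1, signs
#'   equiprobable) placed uniformly at random in the m x p weight matrix A.
#' @param loading_range Lower/upper bound of the uniform distribution for
#'   the nonzero loadings in B.
#' @param latent_noise_sd,region_noise_sd Gaussian noise sd on the latent
#'   and region layer.
#' @param n_phenotype_latents Number of latents with a nonzero phenotype
#'   weight (+/-10).
#' @param phenotype_weight Magnitude of the nonzero phenotype weights.
#' @param n_swaps Number of region-group link swaps applied to the *fitting*
#'   specification (0 = fit the true grouping; see [swap_region_links()]).
#' @param seed Integer seed; every draw in [simulate_dataset()] is derived
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500L, n_snps = 20L,
                       group_sizes = c(20L, 10L, 10L, 5L, 5L),
                       maf_beta_shapes = c(1, 2),
                       n_nonzero_A = 10L,
                       loading_range = c(0.5, 1.5),
                       latent_noise_sd = 2, region_noise_sd = 2,
                       n_phenotype_latents = 2L,
                       phenotype_weight = 10,
                       n_swaps = 0L,
                       seed = 1L) {
  m <- length(group_sizes)
  if (any(group_sizes < 2)) abort("All `group_sizes` must be >= 2.")
  if (n_nonzero_A > m * n_snps)
    abort("`n_nonzero_A` cannot exceed m * p.")
  if (n_phenotype_latents > m)
    abort("`n_phenotype_latents` cannot exceed the number of groups.")
  if (latent_noise_sd < 0 || region_noise_sd < 0)
    abort("Noise sds must be non-negative.")
  if (length(maf_beta_shapes) != 2 || any(maf_beta_shapes <= 0))
    abort("`maf_beta_shapes` must be two positive numbers.")
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps),
         group_sizes = as.integer(group_sizes),
         maf_beta_shapes = as.numeric(maf_beta_shapes),
         n_nonzero_A = as.integer(n_nonzero_A),
         loading_range = as.numeric(loading_range),
         latent_noise_sd = latent_noise_sd,
         region_noise_sd = region_noise_sd,
         n_phenotype_latents = as.integer(n_phenotype_latents),
         phenotype_weight = phenotype_weight,
         n_swaps = as.integer(n_swaps),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n_individuals, ", p =", x$n_snps,
      ", groups =", paste(x$group_sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP a minor allele frequency f is drawn from Beta(shape1, shape2)
#' (unless `maf` is supplied), and additive genotypes 0/1/2 are drawn iid
#' with probabilities (1-f)^2, 2f(1-f), f^2.
#'
#' @param n,p Samples and SNPs.
#' @param beta_shapes Beta shape parameters for the MAF distribution.
#' @param maf Optional fixed MAF vector (length p), bypassing the Beta draw.
#' @param seed Optional integer seed.
#' @return List with `g` (n x p integer matrix, columns `S01`, ...) and
#'   `maf` (length-p vector).
#' @export
simulate_genotypes <- function(n, p, beta_shapes = c(1, 2), maf = NULL,
                               seed = NULL) {
  if (n < 1 || p < 1) abort("`n` and `p` must be >= 1.")
  if (length(beta_shapes) != 2 || any(!is.finite(beta_shapes)) ||
      any(beta_shapes <= 0)) {
    abort("`beta_shapes` must be two positive finite numbers.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- rbeta(p, beta_shapes[1], beta_shapes[2])
  if (length(maf) != p || any(maf < 0 | maf > 1))
    abort("`maf` must be length p with values in [0, 1].")
  g <- vapply(maf, function(f) {
    sample.int(3L, n, replace = TRUE,
               prob = c((1 - f)^2, 2 * f * (1 - f), f^2)) - 1L
  }, integer(n))
  g <- matrix(g, nrow = n)
  colnames(g) <- sprintf("S%02d", seq_len(p))
  list(g = g, maf = setNames(maf, colnames(g)))
}

#' Simulate a complete dataset from the grouped-latent model
#'
#' Draws genotypes, latent variables `z = A g_centred + eps`, region
#' measurements `x = B z + zeta`, and a binary phenotype
#' `y ~ Bernoulli(plogis(w'z))` (no intercept). The true-effect SNP set is
#' every SNP with a nonzero weight onto any phenotype-linked latent.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `g` (raw 0/1/2), `z_true`, `x`,
#'   `y`, `spec` (the true grouping as a [build_spec()] object), and a
#'   `truth` list (`A`, `B`, `phenotype_weights`, `maf`,
#'   `true_effect_snps` — logical over SNPs).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals; p <- config$n_snps
  sizes <- config$group_sizes; m <- length(sizes); q <- sum(sizes)

  gen <- simulate_genotypes(n, p, config$maf_beta_shapes)
  g <- gen$g
  gc <- sweep(g, 2L, colMeans(g))          # latents driven by centred SNPs

  A <- matrix(0, m, p)
  nz <- sample.int(m * p, config$n_nonzero_A)
  A[nz] <- sample(c(-1, 1), config$n_nonzero_A, replace = TRUE)

  group_of_region <- rep(seq_len(m), sizes)
  B <- matrix(0, q, m)
  B[cbind(seq_len(q), group_of_region)] <-
    runif(q, config$loading_range[1], config$loading_range[2])

  z <- gc %*% t(A) +
    matrix(rnorm(n * m, sd = config$latent_noise_sd), n, m)
  x <- z %*% t(B) +
    matrix(rnorm(n * q, sd = config$region_noise_sd), n, q)

  w <- numeric(m)
  linked <- sample.int(m, config$n_phenotype_latents)
  w[linked] <- sample(c(-config$phenotype_weight, config$phenotype_weight),
                      config$n_phenotype_latents, replace = TRUE)
  y <- rbinom(n, 1L, plogis(as.numeric(z %*% w)))

  region_ids <- sprintf("R%02d", seq_len(q))
  group_ids <- sprintf("G%d", seq_len(m))
  colnames(x) <- region_ids
  colnames(z) <- group_ids
  dimnames(A) <- list(group_ids, colnames(g))
  dimnames(B) <- list(region_ids, group_ids)
  names(w) <- group_ids
  spec <- build_spec(
    data.frame(region_id = region_ids,
               group_code = group_ids[group_of_region]),
    snp_ids = colnames(g)
  )

  true_effect <- colSums(abs(A[w != 0, , drop = FALSE])) > 0
  structure(
    list(g = g, z_true = z, x = x, y = y, spec = spec,
         truth = list(A = A, B = B, phenotype_weights = w, maf = gen$maf,
                      true_effect_snps = setNames(true_effect, colnames(g))),
         config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> n =", nrow(x$g), ", p =", ncol(x$g),
      ", q =", ncol(x$x), ", m =", ncol(x$z_true), "\n")
  cat("  true-effect SNPs:", sum(x$truth$true_effect_snps),
      "; phenotype rate:", mean(x$y), "\n")
  invisible(x)
}

#' Misspecify a model specification by swapping region-group links
#'
#' Each swap picks two distinct groups, moves one region from the first to
#' the second and one from the second to the first, so group sizes are
#' preserved and every swap misspecifies exactly two links. Regions that
#' have already been moved are never swapped back to a group they belonged
#' to before (including their original one).
#'
#' @param spec A [build_spec()] object with at least two groups.
#' @param n_swaps Number of swaps (>= 1).
#' @param seed Optional integer seed.
#' @return A new `sem_spec` with the permuted membership (anchors re-derived
#'   from the original region order).
#' @export
swap_region_links <- function(spec, n_swaps, seed = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  if (n_swaps < 1) abort("`n_swaps` must be >= 1 (use the spec unchanged for 0).")
  if (spec$m < 2) abort("Swapping needs at least two region groups.")
  if (!is.null(seed)) set.seed(seed)

  membership <- spec$membership
  # per region: set of groups it has belonged to at any point (no-return rule)
  history <- lapply(membership, function(g) g)

  for (s in seq_len(n_swaps)) {
    # candidate pairs: region a in group ga movable to gb, region b in gb
    # movable to ga, where neither has previously held the target group
    ok <- FALSE
    groups <- unique(unname(membership))
    eligible <- function(gfrom, gto) {
      rs <- names(membership)[membership == gfrom]
      rs[!vapply(rs, function(r) gto %in% history[[r]], logical(1))]
    }
    for (attempt in seq_len(500L)) {
      gab <- sample(groups, 2L)
      ga <- gab[1]; gb <- gab[2]
      cand_a <- eligible(ga, gb)
      cand_b <- eligible(gb, ga)
      if (length(cand_a) == 0 || length(cand_b) == 0) next
      a <- if (length(cand_a) == 1) cand_a else sample(cand_a, 1L)
      b <- if (length(cand_b) == 1) cand_b else sample(cand_b, 1L)
      membership[a] <- gb; membership[b] <- ga
      history[[a]] <- c(history[[a]], gb)
      history[[b]] <- c(history[[b]], ga)
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(
        "Could not perform swap %d without returning a region to a previous group.",
        s))
    }
  }
  build_spec(
    data.frame(region_id = names(membership),
               group_code = unname(membership)),
    snp_ids = spec$snp_ids,
    region_order = spec$region_ids
  )
}

#' Write / read the tabular files of a simulated dataset
#'
#' Writes the same CSV/TSV tables the fitting pipeline reads: `genotypes.csv`
#' and `regions.csv` (first column `sample_id`), `grouping.tsv`
#' (`region_id`, `group_code`), `phenotype.csv` (`sample_id`, `y`), and a
#' `truth.json` with the generative parameters.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- sprintf("I%04d", seq_len(nrow(dataset$g)))
  gt <- dplyr::bind_cols(tibble(sample_id = ids), as_tibble(dataset$g))
  rt <- dplyr::bind_cols(tibble(sample_id = ids), as_tibble(dataset$x))
  readr::write_csv(gt, file.path(dir, "genotypes.csv"))
  readr::write_csv(rt, file.path(dir, "regions.csv"))
  write_grouping(dataset$spec, file.path(dir, "grouping.tsv"))
  readr::write_csv(tibble(sample_id = ids, y = dataset$y),
                   file.path(dir, "phenotype.csv"))
  jsonlite::write_json(
    list(A = dataset$truth$A, B = dataset$truth$B,
         phenotype_weights = dataset$truth$phenotype_weights,
         maf = dataset$truth$maf,
         true_effect_snps = names(which(dataset$truth$true_effect_snps)),
         config = unclass(dataset$config)),
    file.path(dir, "truth.json"), digits = NA
  )
  invisible(dir)
}
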