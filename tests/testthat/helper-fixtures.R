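# Small model specs and parameter sets reused across tests.

two_region_spec <- function() {
  build_spec(data.frame(region_id = c("r1", "r2"), group_code = "G1"))
}

# 1 SNP, 1 latent, 3 regions
small_snp_spec <- function() {
  build_spec(
    data.frame(region_id = c("r1", "r2", "r3"), group_code = "G1"),
    snp_ids = "s1"
  )
}

five_group_spec <- function(sizes = c(3L, 2L, 2L), p = 2L) {
  q <- sum(sizes)
  build_spec(
    data.frame(region_id = sprintf("R%02d", seq_len(q)),
               group_code = rep(sprintf("G%d", seq_along(sizes)), sizes)),
    snp_ids = if (p > 0) sprintf("S%02d", seq_len(p)) else character()
  )
}

# random valid parameter set for a spec (seeded by the caller)
random_params <- function(spec) {
  m <- spec$m; p <- spec$p; q <- spec$q
  B <- matrix(0, q, m)
  pat <- igsem:::loading_pattern(spec)
  B[pat] <- runif(sum(pat), 0.5, 1.5)
  B[cbind(match(spec$anchor_region, spec$region_ids), seq_len(m))] <- 1
  A <- matrix(rnorm(m * p, sd = 0.5), m, p)
  sigma_gg <- if (p > 0) {
    Z <- matrix(rnorm(3 * p * p), 3 * p, p)
    crossprod(Z) / (3 * p)
  } else matrix(0, 0, 0)
  sem_params(spec, A, B, psi = runif(m, 0.5, 2), theta = runif(m, 0.3, 1.5),
             sigma_gg = sigma_gg)
}

# small default-structure simulation config, cheap enough for unit tests
tiny_config <- function(...) {
  # small but well-behaved: both latents phenotype-linked so the
  # true-effect set is never empty, and a moderate weight keeps the
  # phenotype stochastic (no separation)
  defaults <- list(n_individuals = 200L, n_snps = 4L,
                   group_sizes = c(3L, 2L), n_nonzero_A = 3L,
                   n_phenotype_latents = 2L, phenotype_weight = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
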