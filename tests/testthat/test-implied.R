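test_that("implied covariance matches hand-expanded blocks", {
  # 1 SNP, 1 latent, 2 regions: C = 1, A = 0.5, B = (1, 1)', psi = 1,
  # theta = 0.25. Hand expansion:
  #   Sigma_gx  = C A' B'          = (0.5, 0.5)
  #   Sigma_xx  = BA C (BA)' + B psi B' + theta I
  #             = 0.25 J + J + 0.25 I  (J = all-ones)
  spec <- build_spec(data.frame(region_id = c("r1", "r2"),
                                group_code = "G1"), snp_ids = "s1")
  par <- sem_params(spec, A = matrix(0.5, 1, 1), B = matrix(c(1, 1), 2, 1),
                    psi = 1, theta = 0.25, sigma_gg = matrix(1))
  Sigma <- implied_covariance(par)
  expected <- rbind(c(1, 0.5, 0.5),
                    c(0.5, 1.5, 1.25),
                    c(0.5, 1.25, 1.5))
  expect_equal(unname(Sigma), expected, tolerance = 1e-12)
})

test_that("A = 0 zeroes the cross block and leaves the measurement part", {
  set.seed(71)
  spec <- five_group_spec()
  par <- random_params(spec)
  par0 <- sem_params(spec, A = matrix(0, spec$m, spec$p), par$B, par$psi,
                     par$theta, par$sigma_gg)
  Sigma <- implied_covariance(par0)
  ip <- seq_len(spec$p); ix <- spec$p + seq_len(spec$q)
  expect_true(all(Sigma[ip, ix] == 0))
  theta_region <- par0$theta[match(spec$membership, spec$group_ids)]
  meas <- par0$B %*% diag(par0$psi) %*% t(par0$B) + diag(theta_region)
  expect_equal(unname(Sigma[ix, ix]), unname(meas), tolerance = 1e-12)
})

test_that("implied covariance is symmetric and PD for valid parameters", {
  set.seed(99)
  spec <- five_group_spec(sizes = c(4L, 3L, 2L), p = 3L)
  for (i in 1:100) {
    par <- random_params(spec)
    Sigma <- implied_covariance(par)
    expect_equal(max(abs(Sigma - t(Sigma))), 0)
    expect_no_error(chol(Sigma))   # PD via Cholesky
  }
})

test_that("discrepancy is zero at the saturated point, positive elsewhere", {
  set.seed(5)
  spec <- five_group_spec()
  par <- random_params(spec)
  S <- implied_covariance(par)
  expect_equal(ml_discrepancy(par, S = S), 0, tolerance = 1e-10)
  for (i in 1:50) {
    pert <- sem_params(spec,
                       A = par$A + matrix(rnorm(length(par$A), sd = 0.1),
                                          nrow(par$A)),
                       B = par$B,
                       psi = par$psi * exp(rnorm(spec$m, sd = 0.1)),
                       theta = par$theta * exp(rnorm(spec$m, sd = 0.1)),
                       sigma_gg = par$sigma_gg)
    expect_gt(ml_discrepancy(pert, S = S), 0)
  }
})

test_that("discrepancy for Sigma = 2S equals d log 2 + d/2 - d", {
  # F(2S; S) = log|2S| + tr(S (2S)^-1) - log|S| - d = d log2 + d/2 - d
  set.seed(6)
  spec <- five_group_spec()
  par <- random_params(spec)
  Sigma <- implied_covariance(par)
  S <- Sigma / 2
  d <- nrow(S)
  expect_equal(ml_discrepancy(par, S = S), d * log(2) + d / 2 - d,
               tolerance = 1e-10)
})

test_that("non-positive-definite sample covariance is rejected", {
  spec <- two_region_spec()
  par <- sem_params(spec, A = matrix(0, 1, 0), B = matrix(c(1, 1), 2, 1),
                    psi = 1, theta = 1, sigma_gg = matrix(0, 0, 0))
  S_bad <- matrix(c(1, 2, 2, 1), 2, 2)   # indefinite
  expect_error(ml_discrepancy(par, S = S_bad), "positive definite")
  expect_error(ml_discrepancy(par, S = diag(3)), "dimension")
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(31)
  spec <- five_group_spec(sizes = c(3L, 2L, 2L), p = 2L)
  pidx <- igsem:::param_index(spec)
  truth <- random_params(spec)
  S <- implied_covariance(truth) + diag(0.05, spec$p + spec$q)
  C <- S[seq_len(spec$p), seq_len(spec$p)]
  logdetS <- 2 * sum(log(diag(chol(S))))
  h <- 1e-6
  for (rep in 1:5) {
    eta <- rnorm(pidx$n_free, sd = 0.3)
    eta[c(pidx$idx_psi, pidx$idx_theta)] <- rnorm(2 * spec$m, sd = 0.2)
    gan <- igsem:::discrepancy_eta(eta, spec, pidx, C, S, logdetS,
                                   grad = TRUE)$gradient
    gnum <- vapply(seq_along(eta), function(i) {
      ep <- em <- eta; ep[i] <- ep[i] + h; em[i] <- em[i] - h
      (igsem:::discrepancy_eta(ep, spec, pidx, C, S, logdetS) -
         igsem:::discrepancy_eta(em, spec, pidx, C, S, logdetS)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(gan - gnum) / (abs(gnum) + 1)), 1e-5)
  }
})

test_that("sem_params validates structure", {
  spec <- five_group_spec()
  par <- suppressWarnings(random_params(spec))
  expect_error(sem_params(spec, par$A, par$B, psi = c(-1, 1, 1),
                          theta = par$theta, sigma_gg = par$sigma_gg),
               "positive")
  B_bad <- par$B; B_bad[1, 2] <- 0.5   # region of G1 loading on G2
  expect_error(sem_params(spec, par$A, B_bad, par$psi, par$theta,
                          par$sigma_gg), "sparsity")
  B_anch <- par$B
  B_anch[match(spec$anchor_region[1], spec$region_ids), 1] <- 2
  expect_error(sem_params(spec, par$A, B_anch, par$psi, par$theta,
                          par$sigma_gg), "Anchor")
})
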