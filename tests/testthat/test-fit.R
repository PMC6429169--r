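test_that("saturated 1-group/2-region model has the closed-form solution", {
  # Moment equations for S = [[2, 1], [1, 2]] with anchor loading 1:
  #   psi + theta = 2, b psi = 1, b^2 psi + theta = 2  =>  b = psi = theta = 1
  spec <- two_region_spec()
  S <- matrix(c(2, 1, 1, 2), 2, 2)
  fit <- fit_sem_cov(S, spec, n = 100)
  expect_true(fit$converged)
  est <- fit$estimates
  expect_equal(unname(est$B[2, 1]), 1, tolerance = 1e-4)
  expect_equal(unname(est$psi), 1, tolerance = 1e-4)
  expect_equal(unname(est$theta), 1, tolerance = 1e-4)
  expect_equal(fit$discrepancy, 0, tolerance = 1e-8)
})

test_that("optimizer matches a dense grid search on a 1-SNP/1-latent/3-region model", {
  set.seed(17)
  spec <- small_snp_spec()
  truth <- sem_params(spec, A = matrix(0.8, 1, 1),
                      B = matrix(c(1, 1.2, 0.7), 3, 1),
                      psi = 1.3, theta = 0.6, sigma_gg = matrix(0.5))
  n <- 400
  # draw data from the model so the optimum is interior
  g <- matrix(rnorm(n, sd = sqrt(0.5)), n, 1)
  z <- g %*% t(truth$A) + rnorm(n, sd = sqrt(1.3))
  x <- z %*% t(truth$B) + matrix(rnorm(3 * n, sd = sqrt(0.6)), n, 3)
  colnames(g) <- "s1"; colnames(x) <- c("r1", "r2", "r3")
  fit <- fit_sem(scale(g, scale = FALSE), scale(x, scale = FALSE), spec)
  expect_true(fit$converged)

  dat <- cbind(g, x); dat <- sweep(dat, 2, colMeans(dat))
  S <- crossprod(dat) / n
  C <- S[1, 1, drop = FALSE]
  eval_F <- function(b2, b3, a, psi, theta) {
    par <- sem_params(spec, A = matrix(a, 1, 1),
                      B = matrix(c(1, b2, b3), 3, 1),
                      psi = psi, theta = theta, sigma_gg = C)
    ml_discrepancy(par, S = S)
  }
  est <- fit$estimates
  centers <- c(est$B[2, 1], est$B[3, 1], est$A[1, 1], est$psi, est$theta)
  # dense grid bracketing the optimizer solution
  step <- 0.04
  grids <- lapply(centers, function(c0) c0 + seq(-3, 3) * step)
  grid_best <- Inf; grid_arg <- NULL
  for (b2 in grids[[1]]) for (b3 in grids[[2]]) for (a in grids[[3]])
    for (psi in grids[[4]]) for (theta in grids[[5]]) {
      f <- eval_F(b2, b3, a, psi, theta)
      if (f < grid_best) { grid_best <- f; grid_arg <- c(b2, b3, a, psi, theta) }
    }
  # optimizer at least as good as the best grid point, and at the grid's
  # central cell (agreement to grid resolution)
  expect_lte(fit$discrepancy, grid_best + 1e-10)
  expect_true(all(abs(grid_arg - centers) <= step + 1e-12))
})

test_that("different random starts reach the same discrepancy", {
  ds <- simulate_dataset(tiny_config(seed = 8))
  std <- standardize(ds$g, ds$x)
  f1 <- fit_sem(std$g, std$x, ds$spec)
  set.seed(23)
  f2 <- fit_sem(std$g, std$x, ds$spec, options = list(start_jitter = 0.5))
  set.seed(24)
  f3 <- fit_sem(std$g, std$x, ds$spec, options = list(start_jitter = 0.5))
  expect_equal(f1$discrepancy, f2$discrepancy, tolerance = 1e-4)
  expect_equal(f1$discrepancy, f3$discrepancy, tolerance = 1e-4)
})

test_that("degenerate inputs are rejected and small n warns", {
  ds <- simulate_dataset(tiny_config(seed = 3))
  g <- ds$g; g[, 1] <- 2
  expect_error(fit_sem(scale(g, scale = FALSE), ds$x, ds$spec), "Constant")
  small <- simulate_dataset(tiny_config(n_individuals = 12L, seed = 4))
  std <- standardize(small$g, small$x)
  expect_warning(
    try(fit_sem(std$g, std$x, small$spec), silent = TRUE),
    "free parameters"
  )
})

test_that("estimates at n = 5000 recover A up to the anchor-loading scale", {
  # fitting centred (unscaled) regions: the latent is expressed in units of
  # its anchor region, so A-hat estimates b1 * A_true and non-anchor
  # loadings estimate b / b1
  errsA <- c(); errsB <- c()
  for (s in 1:2) {
    ds <- simulate_dataset(sim_config(n_individuals = 5000L, seed = 500 + s))
    gc <- scale(ds$g, scale = FALSE); xc <- scale(ds$x, scale = FALSE)
    fit <- fit_sem(gc, xc, ds$spec)
    expect_true(fit$converged)
    anch <- match(ds$spec$anchor_region, ds$spec$region_ids)
    b1 <- ds$truth$B[cbind(anch, seq_len(ds$spec$m))]
    nz <- ds$truth$A != 0
    errsA <- c(errsA, abs(fit$estimates$A - ds$truth$A * b1)[nz])
    Brel <- sweep(ds$truth$B, 2, b1, "/")
    pat <- ds$truth$B != 0
    pat[cbind(anch, seq_len(ds$spec$m))] <- FALSE
    errsB <- c(errsB, abs(fit$estimates$B - Brel)[pat])
  }
  expect_lt(median(errsA), 0.1)
  expect_lt(median(errsB), 0.1)
})

test_that("glance and tidy expose the fit summary", {
  ds <- simulate_dataset(tiny_config(seed = 21))
  std <- standardize(ds$g, ds$x)
  fit <- fit_sem(std$g, std$x, ds$spec)
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  expect_equal(gl$n_free, fit$n_free)
  # n_free = (q - m) free loadings + m p + m psi + m theta
  expect_equal(fit$n_free, (5 - 2) + 2 * 4 + 2 + 2)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_free)
  expect_true(all(c("estimate", "se_naive", "p_robust") %in% names(td)))
  expect_true(all(is.na(td$p_robust)))   # robust columns only after adjust
})
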