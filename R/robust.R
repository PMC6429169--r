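#' Sandwich-type robust standard errors for a fitted SEM
#'
#' Discrete genotypes violate the normality behind the naive
#' expected-information standard errors. This adjustment keeps the ML point
#' estimates but replaces their covariance by the sandwich
#' `(D'WD)^-1 D'W Gamma W D (D'WD)^-1 / n`, where `D` is the Jacobian of the
#' unique implied-covariance elements with respect to the free parameters,
#' `W` the normal-theory weight matrix at the optimum, and `Gamma` the
#' empirical fourth-moment covariance of the sample-covariance elements.
#' Robust Wald `z` statistics and two-sided p values are added to the
#' parameter table.
#'
#' @param fit A converged [fit_sem()] result.
#' @param g,x The same (centred) data matrices the model was fitted on;
#'   fourth moments of the raw observations are required.
#' @return `fit` with `se_robust`, `z_robust`, `p_robust` filled in its
#'   `param_table`, plus `acov_robust` and a `robust_moment_flag` that is
#'   `TRUE` when `n` does not exceed the number of unique second moments
#'   (the empirical `Gamma` is then necessarily rank-deficient; the sandwich
#'   itself remains well defined).
#' @export
robust_adjust <- function(fit, g, x) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) abort("Robust adjustment requires a converged fit.")
  spec <- fit$spec
  x <- as_numeric_matrix(x, spec$region_ids, "x")
  g <- if (spec$p > 0) as_numeric_matrix(g, spec$snp_ids, "g") else
    matrix(0, nrow(x), 0)
  if (nrow(g) != nrow(x)) abort("`g` and `x` must have the same rows.")
  n <- nrow(x)
  if (n != fit$n) abort("Data rows do not match the fitted sample size.")

  dat <- cbind(g, x)
  dat <- sweep(dat, 2L, colMeans(dat))
  d <- ncol(dat)
  nvech <- d * (d + 1L) / 2L
  moment_flag <- n <= nvech

  pidx <- fit$pidx
  jac <- sigma_jacobian_matrices(fit$estimates, pidx)
  Sigma <- implied_covariance(fit$estimates)
  Sigma_inv <- chol2inv(chol(Sigma))

  # half-vectorization index (row-major upper triangle a <= b)
  ut <- upper.tri(Sigma, diag = TRUE)
  wts <- matrix(2, d, d); diag(wts) <- 1

  # bread: expected information D'WD; and WD columns in vech space
  k <- pidx$n_free
  H <- lapply(jac, function(dS) Sigma_inv %*% dS %*% Sigma_inv)
  bread <- matrix(0, k, k)
  for (j in seq_len(k)) for (l in j:k) {
    v <- 0.5 * sum(H[[j]] * jac[[l]])
    bread[j, l] <- v; bread[l, j] <- v
  }
  WD <- vapply(H, function(Hj) 0.5 * (wts * Hj)[ut], numeric(nvech))

  # U = Y WD without forming Gamma: row i of Y is vech(d_i d_i')
  Y <- t(apply(dat, 1L, function(r) tcrossprod(r)[ut]))
  U <- Y %*% WD
  U <- sweep(U, 2L, colMeans(U))
  meat <- crossprod(U) / n

  bread_inv <- tryCatch(solve(bread), error = function(e) NULL)
  pinv_used <- FALSE
  if (is.null(bread_inv)) {
    # boundary optima (a latent residual variance estimated at zero, e.g.
    # under a misspecified grouping) leave that group's loadings
    # unidentified; pseudo-invert over the identified subspace and flag
    eg <- eigen(bread, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-10
    if (!any(keep)) abort("Expected information vanishes at the optimum.")
    bread_inv <- eg$vectors[, keep, drop = FALSE] %*%
      (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
    pinv_used <- TRUE
  }
  acov <- bread_inv %*% meat %*% bread_inv / n

  se <- sqrt(pmax(diag(acov), 0))
  est <- fit$param_table$estimate
  z <- ifelse(se > 0, est / se, NA_real_)
  fit$param_table$se_robust <- se
  fit$param_table$z_robust <- z
  fit$param_table$p_robust <- ifelse(est == 0, 1,
                                     2 * pnorm(-abs(z)))
  fit$acov_robust <- acov
  fit$robust <- TRUE
  fit$robust_moment_flag <- moment_flag
  fit$robust_pinv <- pinv_used
  fit
}

#' Robust p values for the SNP-to-latent weight matrix
#'
#' Convenience accessor returning the m x p matrix of robust p values for the
#' entries of `A` (rows: region groups, columns: SNPs).
#'
#' @param fit A [robust_adjust()]-ed `sem_fit`.
#' @return Numeric m x p matrix.
#' @export
snp_weight_pvalues <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$robust) abort("Run `robust_adjust()` first.")
  spec <- fit$spec
  tab <- fit$param_table[fit$param_table$kind == "snp_weight", ]
  matrix(tab$p_robust, spec$m, spec$p, byrow = TRUE,
         dimnames = list(spec$group_ids, spec$snp_ids))
}
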