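#' Fit the grouped-latent SEM by maximum likelihood
#'
#' Estimates the free parameters (non-anchor loadings, SNP-to-latent weights,
#' latent residual variances, shared per-group region residual variances) by
#' minimizing the normal-theory discrepancy [ml_discrepancy()] with a
#' quasi-Newton (BFGS) search using the analytic gradient. The SNP covariance
#' block is fixed at the observed SNP covariance and never optimized.
#' Variances are optimized on the log scale, so they stay positive.
#'
#' @param g Numeric matrix or data frame, samples x SNPs, centred (zero
#'   column means). May have zero columns for a measurement-only model.
#' @param x Numeric matrix or data frame, samples x regions, centred (and in
#'   the standard pipeline scaled to unit variance; see [standardize()]).
#' @param spec A [build_spec()] object whose `snp_ids`/`region_ids` match the
#'   columns of `g` and `x` (unnamed columns are taken in spec order).
#' @param options Named list overriding optimizer controls:
#'   `max_restarts` (default 5 jittered restarts on failure), `maxit` (2000),
#'   `grad_tol` (1e-6, gradient-norm convergence), `f_tol` (1e-10, accepted
#'   discrepancy change between polish passes), `jitter_sd` (0.1), and
#'   `start_jitter` (0; N(0, sd) noise added to the default starting point,
#'   useful for multistart consistency checks).
#'
#' @return An object of class `sem_fit` with elements `spec`, `estimates`
#'   (a [sem_params()] object), `param_table` (tibble: parameter, from, to,
#'   estimate, se_naive, se_robust, z_robust, p_robust — robust columns `NA`
#'   until [robust_adjust()]), `discrepancy`, `loglik`, `n`, `n_free`,
#'   `converged`, `n_restarts`, and `S` (the sample covariance used).
#'
#' @seealso [robust_adjust()], [bartlett_scores()], [tidy.sem_fit()]
#' @export
fit_sem <- function(g, x, spec, options = list()) {
  x <- as_numeric_matrix(x, spec$region_ids, "x")
  g <- if (spec$p > 0) as_numeric_matrix(g, spec$snp_ids, "g") else
    matrix(0, nrow(x), 0)
  if (nrow(g) != nrow(x)) abort("`g` and `x` must have the same rows.")
  check_not_constant(g, "g"); check_not_constant(x, "x")
  n <- nrow(x)
  dat <- cbind(g, x)
  S <- crossprod(sweep(dat, 2L, colMeans(dat))) / n   # ML divisor n
  fit <- fit_sem_cov(S, spec, n, options = options)
  fit$data_means <- colMeans(dat)
  fit
}

#' @rdname fit_sem
#' @param S Sample covariance ((p+q) x (p+q), SNPs then regions, divisor n).
#' @param n Number of samples behind `S`.
#' @export
fit_sem_cov <- function(S, spec, n, options = list()) {
  stopifnot(inherits(spec, "sem_spec"))
  opt <- modifyList(list(max_restarts = 5L, maxit = 2000L, grad_tol = 1e-6,
                         f_tol = 1e-10, jitter_sd = 0.1, start_jitter = 0),
                    options)
  d <- spec$p + spec$q
  S <- as.matrix(S)
  if (!all(dim(S) == d)) abort("`S` has the wrong dimension for `spec`.")
  S <- (S + t(S)) / 2
  chS <- tryCatch(chol(S), error = function(e)
    abort("Sample covariance is not positive definite."))
  logdetS <- 2 * sum(log(diag(chS)))
  pidx <- param_index(spec)
  if (n <= pidx$n_free) {
    warn(sprintf("n = %d does not exceed the number of free parameters (%d).",
                 n, pidx$n_free))
  }
  ip <- seq_len(spec$p)
  C <- S[ip, ip, drop = FALSE]
  Sxx_diag_mean <- mean(diag(S)[spec$p + seq_len(spec$q)])

  eta0 <- numeric(pidx$n_free)
  if (pidx$n_load > 0) eta0[pidx$idx_load] <- 1
  eta0[c(pidx$idx_psi, pidx$idx_theta)] <- log(0.5 * Sxx_diag_mean)

  fn <- function(eta) discrepancy_eta(eta, spec, pidx, C, S, logdetS)
  gr <- function(eta) discrepancy_eta(eta, spec, pidx, C, S, logdetS,
                                      grad = TRUE)$gradient

  best <- NULL; n_restarts <- 0L; best_ok <- FALSE
  for (attempt in 0:opt$max_restarts) {
    start <- if (attempt == 0) {
      if (opt$start_jitter > 0)
        eta0 + rnorm(length(eta0), sd = opt$start_jitter)
      else eta0
    } else {
      eta0 + rnorm(length(eta0), sd = opt$jitter_sd)
    }
    res <- tryCatch(
      optim(start, fn, gr, method = "BFGS",
            control = list(maxit = opt$maxit, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    # polish: second pass from the optimum; declares convergence when the
    # gradient is flat or the discrepancy no longer moves
    res2 <- tryCatch(
      optim(res$par, fn, gr, method = "BFGS",
            control = list(maxit = opt$maxit, reltol = 1e-14)),
      error = function(e) res
    )
    gnorm <- max(abs(gr(res2$par)))
    ok <- gnorm < opt$grad_tol || abs(res$value - res2$value) < opt$f_tol
    if (ok) { best <- res2; n_restarts <- attempt; best_ok <- TRUE; break }
    if (is.null(best) || res2$value < best$value) {
      best <- res2; n_restarts <- attempt
    }
  }
  if (is.null(best)) abort("Optimization failed on all starts.")
  gnorm <- max(abs(gr(best$par)))
  converged <- best_ok || gnorm < opt$grad_tol
  if (!converged) {
    warn(sprintf(
      "SEM fit did not converge (gradient norm %.2e after %d restarts).",
      gnorm, n_restarts))
  }

  pp <- unpack_params(best$par, spec, pidx, C)
  est <- sem_params(spec, pp$A, pp$B, pp$psi, pp$theta,
                    if (spec$p > 0) C else matrix(0, 0, 0))
  Fval <- max(best$value, 0)
  loglik <- -n / 2 * (d * log(2 * pi) + Fval + logdetS + d)

  # naive (expected-information) standard errors on the natural scale
  se_naive <- rep(NA_real_, pidx$n_free)
  info <- tryCatch(expected_information(est, pidx), error = function(e) NULL)
  acov_naive <- NULL
  if (!is.null(info)) {
    acov_naive <- tryCatch(solve(info) / n, error = function(e) NULL)
    if (!is.null(acov_naive)) {
      dg <- diag(acov_naive)
      se_naive <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }

  tab <- param_label_table(spec, pidx)
  tab$estimate <- pack_params(est, pidx, log_var = FALSE)
  tab$se_naive <- se_naive
  tab$se_robust <- NA_real_
  tab$z_robust <- NA_real_
  tab$p_robust <- NA_real_

  structure(
    list(spec = spec, estimates = est, param_table = tab,
         discrepancy = Fval, loglik = loglik, n = n,
         n_free = pidx$n_free, converged = converged,
         n_restarts = n_restarts, grad_norm = gnorm,
         S = S, pidx = pidx, acov_naive = acov_naive,
         robust = FALSE, robust_moment_flag = NA),
    class = "sem_fit"
  )
}

param_label_table <- function(spec, pidx) {
  lab <- pidx$labels
  kind <- rep(c("loading", "snp_weight", "psi", "theta"),
              c(pidx$n_load, pidx$nA, spec$m, spec$m))
  from <- to <- character(length(lab))
  if (pidx$n_load > 0) {
    fl <- pidx$free_loadings
    from[pidx$idx_load] <- fl$group_id; to[pidx$idx_load] <- fl$region_id
  }
  if (pidx$nA > 0) {
    from[pidx$idx_A] <- rep(spec$snp_ids, times = spec$m)
    to[pidx$idx_A] <- rep(spec$group_ids, each = spec$p)
  }
  from[pidx$idx_psi] <- spec$group_ids; to[pidx$idx_psi] <- spec$group_ids
  from[pidx$idx_theta] <- spec$group_ids; to[pidx$idx_theta] <- spec$group_ids
  tibble(parameter = lab, kind = kind, from = from, to = to)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> n =", x$n, ", free parameters =", x$n_free, "\n")
  cat("  discrepancy F =", format(x$discrepancy, digits = 6),
      "; log-likelihood =", format(x$loglik, digits = 8), "\n")
  cat("  converged:", x$converged,
      if (x$robust) "(robust SEs available)" else "(naive SEs only)", "\n")
  invisible(x)
}

# ---- Jacobian of vech(Sigma) w.r.t. the natural free parameters ----------

# list of d x d symmetric derivative matrices, one per free parameter
sigma_jacobian_matrices <- function(params, pidx) {
  spec <- params$spec
  p <- spec$p; q <- spec$q; m <- spec$m; d <- p + q
  C <- params$sigma_gg
  B <- params$B; A <- params$A
  Lam <- if (p > 0) B %*% A else NULL
  LamC <- if (p > 0) Lam %*% C else NULL
  ix <- p + seq_len(q); ip <- seq_len(p)
  out <- vector("list", pidx$n_free)

  put <- function(dLam = NULL, dB = NULL) {
    dS <- matrix(0, d, d)
    dxx <- matrix(0, q, q)
    if (!is.null(dLam) && p > 0) {
      M <- dLam %*% t(LamC)              # dLam C Lam'
      dxx <- dxx + M + t(M)
      dgx <- C %*% t(dLam)               # p x q
      dS[ip, ix] <- dS[ip, ix] + dgx
      dS[ix, ip] <- dS[ix, ip] + t(dgx)
    }
    if (!is.null(dB)) {
      M <- dB %*% (params$psi * t(B))    # dB Psi B'
      dxx <- dxx + M + t(M)
    }
    dS[ix, ix] <- dS[ix, ix] + dxx
    dS
  }

  if (pidx$n_load > 0) {
    fl <- pidx$free_loadings
    for (i in seq_len(pidx$n_load)) {
      r <- match(fl$region_id[i], spec$region_ids)
      k <- match(fl$group_id[i], spec$group_ids)
      dB <- matrix(0, q, m); dB[r, k] <- 1
      dLam <- if (p > 0) dB %*% A else NULL
      out[[pidx$idx_load[i]]] <- put(dLam, dB)
    }
  }
  if (pidx$nA > 0) {
    pos <- 0L
    for (k in seq_len(m)) for (j in seq_len(p)) {
      pos <- pos + 1L
      dLam <- matrix(0, q, p); dLam[, j] <- B[, k]
      out[[pidx$idx_A[pos]]] <- put(dLam, NULL)
    }
  }
  for (k in seq_len(m)) {
    dS <- matrix(0, d, d)
    dS[ix, ix] <- tcrossprod(B[, k])
    out[[pidx$idx_psi[k]]] <- dS
  }
  gmem <- match(spec$membership, spec$group_ids)
  for (k in seq_len(m)) {
    dS <- matrix(0, d, d)
    dd <- numeric(q); dd[gmem == k] <- 1
    dS[ix, ix] <- diag(dd, q)
    out[[pidx$idx_theta[k]]] <- dS
  }
  out
}

# expected information per observation:
#   I_jk = 0.5 tr(Sigma^-1 dSigma_j Sigma^-1 dSigma_k)
expected_information <- function(params, pidx,
                                 jac = sigma_jacobian_matrices(params, pidx),
                                 Sigma_inv = NULL) {
  Sigma <- implied_covariance(params)
  if (is.null(Sigma_inv)) Sigma_inv <- chol2inv(chol(Sigma))
  H <- lapply(jac, function(dS) Sigma_inv %*% dS %*% Sigma_inv)
  k <- pidx$n_free
  info <- matrix(0, k, k)
  for (j in seq_len(k)) for (l in j:k) {
    v <- 0.5 * sum(H[[j]] * jac[[l]])
    info[j, l] <- v; info[l, j] <- v
  }
  info
}

# ---- input coercion helpers ----------------------------------------------

as_numeric_matrix <- function(x, ids, what) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), c("sample_id", "id")), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", what))
  if (ncol(x) != length(ids)) {
    abort(sprintf("`%s` has %d columns; the spec expects %d.",
                  what, ncol(x), length(ids)))
  }
  if (!is.null(colnames(x)) && all(ids %in% colnames(x))) {
    x <- x[, ids, drop = FALSE]
  } else {
    colnames(x) <- ids
  }
  x
}

check_not_constant <- function(x, what) {
  if (ncol(x) == 0) return(invisible())
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant column(s) in `%s`: %s.", what,
                  paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  invisible()
}
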