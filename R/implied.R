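#' Model-implied covariance matrix
#'
#' Assembles the covariance matrix of the observed variables (SNPs first,
#' then regions) implied by the structural model. With SNP covariance
#' `C = sigma_gg` and combined regression weights `Lambda = B A`, the blocks
#' are `Sigma_gg = C`, `Sigma_gx = C Lambda'`, `Sigma_xg = Lambda C`, and
#' `Sigma_xx = Lambda C Lambda' + B Psi B' + Theta`, where `Psi = diag(psi)`
#' and `Theta` puts each group's shared residual variance on the diagonal
#' entries of its member regions.
#'
#' @param params A [sem_params()] object.
#' @param spec A [build_spec()] object consistent with `params` (defaults to
#'   `params$spec`).
#' @return A symmetric (p+q) x (p+q) matrix with dimnames
#'   `c(snp_ids, region_ids)`.
#' @examples
#' grouping <- data.frame(region_id = c("r1", "r2"), group_code = "G1")
#' spec <- build_spec(grouping, snp_ids = "s1")
#' par <- sem_params(spec, A = matrix(0.5, 1, 1), B = matrix(c(1, 1), 2, 1),
#'                   psi = 1, theta = 0.25, sigma_gg = diag(1))
#' implied_covariance(par, spec)
#' @export
implied_covariance <- function(params, spec = params$spec) {
  stopifnot(inherits(params, "sem_params"), inherits(spec, "sem_spec"))
  if (!identical(spec$region_ids, params$spec$region_ids) ||
      !identical(spec$snp_ids, params$spec$snp_ids)) {
    abort("`params` and `spec` describe different variable sets.")
  }
  sig <- implied_blocks(params$A, params$B, params$psi, params$theta,
                        params$sigma_gg, spec)
  sig$full
}

# shared block assembly used by the optimizer (no class validation)
implied_blocks <- function(A, B, psi, theta, C, spec) {
  q <- spec$q; p <- spec$p
  theta_region <- theta[match(spec$membership, spec$group_ids)]
  BP <- sweep(B, 2L, psi, "*")            # B Psi
  Sxx_meas <- tcrossprod(BP, B)           # B Psi B'
  diag(Sxx_meas) <- diag(Sxx_meas) + theta_region
  if (p > 0) {
    Lam <- B %*% A                        # q x p
    LamC <- Lam %*% C                     # q x p
    Sxx <- LamC %*% t(Lam) + Sxx_meas
    Sxx <- (Sxx + t(Sxx)) / 2
    full <- rbind(cbind(C, t(LamC)), cbind(LamC, Sxx))
  } else {
    Lam <- NULL; LamC <- NULL
    Sxx <- (Sxx_meas + t(Sxx_meas)) / 2
    full <- Sxx
  }
  nm <- c(spec$snp_ids, spec$region_ids)
  dimnames(full) <- list(nm, nm)
  list(full = full, Sxx = Sxx, Lam = Lam, LamC = LamC)
}

#' Maximum-likelihood discrepancy between model and sample covariance
#'
#' The normal-theory fit function
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - (p+q)`,
#' whose minimizer over the model parameters is the Gaussian maximum
#' likelihood estimate. `F >= 0`, with equality exactly when the implied
#' covariance reproduces `S`.
#'
#' @inheritParams implied_covariance
#' @param S Sample covariance of the observed variables (SNPs then regions),
#'   symmetric positive definite, computed with divisor n.
#' @return Non-negative scalar.
#' @export
ml_discrepancy <- function(params, spec = params$spec, S) {
  Sigma <- implied_covariance(params, spec)
  d <- nrow(Sigma)
  S <- as.matrix(S)
  if (!all(dim(S) == d)) abort("`S` has the wrong dimension.")
  if (max(abs(S - t(S))) > 1e-8) abort("`S` must be symmetric.")
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) abort("`S` must be positive definite.")
  chSig <- tryCatch(chol(Sigma), error = function(e) {
    abort(paste0("Implied covariance is singular (condition number ",
                 format(kappa(Sigma), digits = 3), ")."))
  })
  Sinv <- chol2inv(chSig)
  2 * sum(log(diag(chSig))) + sum(S * Sinv) - 2 * sum(log(diag(chS))) - d
}

# ---- fit function + analytic gradient on the transformed scale -----------
#
# For G = Sigma^-1 - Sigma^-1 S Sigma^-1 (symmetric), dF = tr(G dSigma):
#   dF/dLambda = 2 (G_xg C + G_xx Lambda C)
#   dF/dA      = B' dF/dLambda
#   dF/dB      = dF/dLambda A' + 2 G_xx B Psi   (free entries only)
#   dF/dpsi_k  = b_k' G_xx b_k
#   dF/dtheta_g= sum of diag(G_xx) over regions of g
# Log-variance chain rule multiplies the psi/theta entries by the variance.
discrepancy_eta <- function(eta, spec, pidx, C, S, logdetS, grad = FALSE) {
  pp <- unpack_params(eta, spec, pidx, C)
  blk <- implied_blocks(pp$A, pp$B, pp$psi, pp$theta, C, spec)
  d <- spec$p + spec$q
  ch <- tryCatch(chol(blk$full), error = function(e) NULL)
  if (is.null(ch)) {
    return(if (grad) list(value = 1e10, gradient = rep(0, pidx$n_free))
           else 1e10)
  }
  Sinv <- chol2inv(ch)
  f <- 2 * sum(log(diag(ch))) + sum(S * Sinv) - logdetS - d
  if (!grad) return(f)

  G <- Sinv - Sinv %*% S %*% Sinv
  G <- (G + t(G)) / 2
  ip <- seq_len(spec$p)
  ix <- spec$p + seq_len(spec$q)
  Gxx <- G[ix, ix, drop = FALSE]

  gr <- numeric(pidx$n_free)
  if (spec$p > 0) {
    Gxg <- G[ix, ip, drop = FALSE]
    dLam <- 2 * (Gxg %*% C + Gxx %*% blk$LamC)   # q x p
    dA <- crossprod(pp$B, dLam)                  # m x p
    gr[pidx$idx_A] <- as.numeric(t(dA))
    dB <- dLam %*% t(pp$A) + 2 * Gxx %*% sweep(pp$B, 2L, pp$psi, "*")
  } else {
    dB <- 2 * Gxx %*% sweep(pp$B, 2L, pp$psi, "*")
  }
  if (pidx$n_load > 0) {
    fl <- pidx$free_loadings
    gr[pidx$idx_load] <- dB[cbind(match(fl$region_id, spec$region_ids),
                                  match(fl$group_id, spec$group_ids))]
  }
  GB <- Gxx %*% pp$B
  gr[pidx$idx_psi] <- colSums(pp$B * GB) * pp$psi
  gmem <- match(spec$membership, spec$group_ids)
  gr[pidx$idx_theta] <- as.numeric(
    rowsum(diag(Gxx), gmem)[as.character(seq_len(spec$m)), 1]
  ) * pp$theta
  list(value = f, gradient = gr)
}
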