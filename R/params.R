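#' Construct a full SEM parameter set
#'
#' Collects the structural weight matrices and residual variances of the
#' grouped-latent model: `A` (m x p, SNP -> latent weights), `B` (q x m
#' loadings, nonzero only within each region's own group, anchors fixed at 1),
#' `psi` (latent residual variances, one per group), `theta` (region residual
#' variances, one shared value per group), and the fixed SNP covariance
#' `sigma_gg`.
#'
#' @param spec A [build_spec()] object.
#' @param A Numeric m x p matrix (ignored when `spec$p == 0`).
#' @param B Numeric q x m matrix respecting the group sparsity pattern, with
#'   each group's anchor loading equal to 1.
#' @param psi Positive numeric vector of length m.
#' @param theta Positive numeric vector of length m.
#' @param sigma_gg Symmetric positive-definite p x p matrix (observed SNP
#'   covariance; not a free parameter).
#' @return An object of class `sem_params`.
#' @export
sem_params <- function(spec, A, B, psi, theta, sigma_gg) {
  stopifnot(inherits(spec, "sem_spec"))
  p <- spec$p; q <- spec$q; m <- spec$m
  if (p == 0) {
    A <- matrix(0, 0, 0)
    sigma_gg <- matrix(0, 0, 0)
  }
  A <- as.matrix(A); B <- as.matrix(B); sigma_gg <- as.matrix(sigma_gg)
  if (p > 0 && !all(dim(A) == c(m, p)))
    abort(sprintf("`A` must be %d x %d.", m, p))
  if (!all(dim(B) == c(q, m)))
    abort(sprintf("`B` must be %d x %d.", q, m))
  if (length(psi) != m || length(theta) != m)
    abort(sprintf("`psi` and `theta` must have length %d.", m))
  if (any(psi <= 0) || any(theta <= 0))
    abort("`psi` and `theta` must be strictly positive.")
  if (p > 0) {
    if (!all(dim(sigma_gg) == c(p, p)))
      abort(sprintf("`sigma_gg` must be %d x %d.", p, p))
    if (max(abs(sigma_gg - t(sigma_gg))) > 1e-8)
      abort("`sigma_gg` must be symmetric.")
    ev <- eigen(sigma_gg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      abort("`sigma_gg` must be positive definite.")
  }
  pat <- loading_pattern(spec)
  if (any(B[!pat] != 0))
    abort("`B` has nonzero loadings outside the group sparsity pattern.")
  anchors <- match(spec$anchor_region, spec$region_ids)
  if (any(abs(B[cbind(anchors, seq_len(m))] - 1) > 1e-12))
    abort("Anchor loadings in `B` must equal 1.")

  dimnames(B) <- list(spec$region_ids, spec$group_ids)
  if (p > 0) {
    dimnames(A) <- list(spec$group_ids, spec$snp_ids)
    dimnames(sigma_gg) <- list(spec$snp_ids, spec$snp_ids)
  }
  structure(
    list(spec = spec, A = A, B = B,
         psi = setNames(as.numeric(psi), spec$group_ids),
         theta = setNames(as.numeric(theta), spec$group_ids),
         sigma_gg = sigma_gg),
    class = "sem_params"
  )
}

#' @export
print.sem_params <- function(x, ...) {
  cat("<sem_params> m =", x$spec$m, "latents, p =", x$spec$p,
      "SNPs, q =", x$spec$q, "regions\n")
  invisible(x)
}

# ---- free-parameter bookkeeping ------------------------------------------
#
# Natural parameter vector order: free loadings (grouped, non-anchor regions
# in region order), A entries (latent-major: for each group, all SNPs), psi,
# theta. Variances enter the optimizer on the log scale.

param_index <- function(spec) {
  fl <- free_loading_table(spec)
  n_load <- if (is.null(fl)) 0L else nrow(fl)
  nA <- spec$m * spec$p
  labels <- c(
    if (n_load > 0) sprintf("B[%s<-%s]", fl$region_id, fl$group_id),
    if (nA > 0) sprintf("A[%s<-%s]",
                        rep(spec$group_ids, each = spec$p),
                        rep(spec$snp_ids, times = spec$m)),
    sprintf("psi[%s]", spec$group_ids),
    sprintf("theta[%s]", spec$group_ids)
  )
  list(
    free_loadings = fl,
    n_load = n_load, nA = nA, m = spec$m,
    n_free = n_load + nA + 2L * spec$m,
    labels = labels,
    idx_load = seq_len(n_load),
    idx_A = n_load + seq_len(nA),
    idx_psi = n_load + nA + seq_len(spec$m),
    idx_theta = n_load + nA + spec$m + seq_len(spec$m)
  )
}

# theta -> matrices; `eta` is the transformed vector (log variances)
unpack_params <- function(eta, spec, pidx, sigma_gg, log_var = TRUE) {
  B <- matrix(0, spec$q, spec$m,
              dimnames = list(spec$region_ids, spec$group_ids))
  anchors <- match(spec$anchor_region, spec$region_ids)
  B[cbind(anchors, seq_len(spec$m))] <- 1
  if (pidx$n_load > 0) {
    fl <- pidx$free_loadings
    B[cbind(match(fl$region_id, spec$region_ids),
            match(fl$group_id, spec$group_ids))] <- eta[pidx$idx_load]
  }
  A <- if (spec$p > 0) {
    matrix(eta[pidx$idx_A], spec$m, spec$p, byrow = TRUE,
           dimnames = list(spec$group_ids, spec$snp_ids))
  } else matrix(0, 0, 0)
  psi <- eta[pidx$idx_psi]
  theta <- eta[pidx$idx_theta]
  if (log_var) { psi <- exp(psi); theta <- exp(theta) }
  list(A = A, B = B, psi = psi, theta = theta, sigma_gg = sigma_gg)
}

pack_params <- function(params, pidx, log_var = TRUE) {
  spec <- params$spec
  eta <- numeric(pidx$n_free)
  if (pidx$n_load > 0) {
    fl <- pidx$free_loadings
    eta[pidx$idx_load] <- params$B[cbind(match(fl$region_id, spec$region_ids),
                                         match(fl$group_id, spec$group_ids))]
  }
  if (pidx$nA > 0) eta[pidx$idx_A] <- as.numeric(t(params$A))
  eta[pidx$idx_psi] <- if (log_var) log(params$psi) else params$psi
  eta[pidx$idx_theta] <- if (log_var) log(params$theta) else params$theta
  eta
}
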