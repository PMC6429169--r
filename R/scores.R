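#' Bartlett factor scores for the latent variables
#'
#' Computes the conditionally unbiased Bartlett estimator
#' `z_hat_i = (B' Theta^-1 B)^-1 B' Theta^-1 x_i` from the estimated
#' measurement model (loadings `B` and region residual variances `Theta`).
#' Because `(B' Theta^-1 B)^-1 B' Theta^-1 B` is the identity,
#' `E[z_hat | z] = z` for any fit. The SNP part of the model is not used.
#'
#' @param fit A [fit_sem()] result (or any object with `estimates` holding
#'   `B` and `theta`).
#' @param x Centred (and, in the standard pipeline, scaled) region matrix
#'   with columns matching the fitted spec. May be data the model was not
#'   fitted on, e.g. a validation set.
#' @return A tibble with one column per region group (class `latent_scores`
#'   via attribute-free tibble; columns ordered as `spec$group_ids`).
#' @examples
#' grouping <- data.frame(region_id = c("r1", "r2"), group_code = "G1")
#' spec <- build_spec(grouping)
#' par <- sem_params(spec, A = matrix(0, 1, 0), B = matrix(c(1, 1), 2, 1),
#'                   psi = 1, theta = 0.5, sigma_gg = matrix(0, 0, 0))
#' fit <- list(spec = spec, estimates = par, converged = TRUE)
#' bartlett_scores(fit, matrix(c(1, 3), 1, 2)) # (1 + 3) / 2 = 2
#' @export
bartlett_scores <- function(fit, x) {
  spec <- fit$spec
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    abort("Bartlett scores require a converged fit.")
  }
  est <- fit$estimates
  x <- as_numeric_matrix(x, spec$region_ids, "x")
  theta_region <- est$theta[match(spec$membership, spec$group_ids)]
  if (any(theta_region <= 0)) abort("All region residual variances must be > 0.")
  B <- est$B
  Ti_B <- B / theta_region                 # Theta^-1 B
  M <- crossprod(B, Ti_B)                  # B' Theta^-1 B
  Minv <- tryCatch(solve(M), error = function(e)
    abort("B' Theta^-1 B is singular; latent scores are not defined."))
  scores <- x %*% Ti_B %*% t(Minv)
  colnames(scores) <- spec$group_ids
  out <- as_tibble(scores)
  if (!all(is.finite(scores))) abort("Non-finite latent scores.")
  out
}
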