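#' Bonferroni adjustment for a matrix of robust p values
#'
#' Multiplies every p value by the total number of tests (rows x columns,
#' e.g. 9 latents x 35 SNPs = 315) and caps at 1; flags entries below the
#' significance level after adjustment.
#'
#' @param p_matrix Numeric matrix of p values (latents x SNPs).
#' @param alpha Significance level for the flags.
#' @return A list with `adjusted` (matrix), `significant` (logical matrix),
#'   and `n_tests`.
#' @export
bonferroni_adjust <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (any(p_matrix < 0 | p_matrix > 1, na.rm = TRUE))
    abort("p values must lie in [0, 1].")
  n_tests <- length(p_matrix)
  adjusted <- pmin(p_matrix * n_tests, 1)
  list(adjusted = adjusted, significant = adjusted < alpha,
       n_tests = n_tests)
}

#' One-way ANOVA of latent scores across diagnosis groups
#'
#' Tests, per latent variable, whether the mean score differs between
#' diagnosis groups (e.g. cognitively normal / late mild cognitive
#' impairment / Alzheimer's disease). The labels are treated as an unordered
#' categorical factor.
#'
#' @param scores Latent scores (n x m), e.g. from [bartlett_scores()] or
#'   [score_validation()].
#' @param diagnosis Vector of group labels, length n, with at least two
#'   groups of at least two samples each.
#' @param alpha Level for the `significant` flag.
#' @return A tibble with one row per latent: `latent`, `f_statistic`,
#'   `df_between`, `df_within`, `p_value`, `significant`.
#' @export
anova_by_group <- function(scores, diagnosis, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("G", seq_len(ncol(scores)))
  diagnosis <- factor(diagnosis)
  if (nrow(scores) != length(diagnosis))
    abort("`scores` and `diagnosis` must have the same length.")
  if (nlevels(diagnosis) < 2)
    abort("Need at least two diagnosis groups.")
  if (any(table(diagnosis) < 2))
    abort("Every diagnosis group needs at least two samples.")
  rows <- lapply(colnames(scores), function(l) {
    at <- anova(lm(scores[, l] ~ diagnosis))
    f <- at$`F value`[1]
    if (!is.finite(f)) {
      warn(sprintf("Undefined F statistic for latent %s (zero variance).", l))
    }
    tibble(latent = l, f_statistic = f,
           df_between = at$Df[1], df_within = at$Df[2],
           p_value = at$`Pr(>F)`[1])
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
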