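#' Boxplots of the simulation-study results
#'
#' `plot_study_aic()` mirrors the AIC model-comparison figure (one box per
#' feature set), `plot_study_auc()` the SNP-retrieval figure (one box per
#' ranking method). `autoplot()` on a `sem_study` stacks both.
#'
#' @param study A [run_simulation_study()] result.
#' @return A ggplot object.
#' @export
plot_study_aic <- function(study) {
  stopifnot(inherits(study, "sem_study"))
  labs <- c(fitted_latents = "fitted latents", pcs_regions = "PCs regions",
            all_regions = "all regions", all_regions_snps = "all regions + SNPs",
            all_snps = "all SNPs")
  df <- dplyr::mutate(study$aic,
                      model = factor(labs[.data$model], levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$aic)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "AIC (logistic phenotype model)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_study_aic
#' @export
plot_study_auc <- function(study) {
  stopifnot(inherits(study, "sem_study"))
  labs <- c(sem_max = "SEM max", sem_fisher = "SEM Fisher",
            multivariate_logistic = "multivariate logistic",
            univariate_logistic = "univariate logistic")
  df <- dplyr::mutate(study$auc,
                      method = factor(labs[.data$method], levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "SNP-retrieval AUC") +
    ggplot2::theme_minimal()
}

#' @rdname plot_study_aic
#' @param object A `sem_study`.
#' @param ... Unused.
#' @export
autoplot.sem_study <- function(object, ...) {
  p1 <- plot_study_aic(object)
  p2 <- plot_study_auc(object)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2, ncol = 1)
  } else {
    p2
  }
}

#' Heatmap of robust z statistics for SNP-to-latent associations
#'
#' Shows, per SNP and latent variable, the robust Wald z statistic of the
#' SNP weight, masking entries above the nominal significance level
#' (the layout of a SNP-association heatmap).
#'
#' @param fit A [robust_adjust()]-ed `sem_fit`.
#' @param alpha Nominal level below which entries are shown.
#' @return A ggplot object.
#' @export
plot_snp_associations <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$robust) abort("Run `robust_adjust()` first.")
  tab <- fit$param_table[fit$param_table$kind == "snp_weight", ]
  df <- dplyr::mutate(tab,
                      z = ifelse(.data$p_robust < alpha, .data$z_robust, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$z)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_gradient2(na.value = "white", name = "robust z") +
    ggplot2::labs(x = "SNP", y = "latent (region group)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
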