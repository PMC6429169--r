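#' Logistic regression with AIC and per-feature Wald p values
#'
#' Fits an intercept-plus-features logistic regression by maximum likelihood
#' and returns its AIC (`2(k+1) - 2 loglik`) and coefficient table. Perfect
#' or quasi-perfect separation (fitted probabilities pinned at 0/1 with a
#' vanishing deviance or a non-converged fit) is raised as a classed error
#' so study code can record the replicate as failed rather than keep a
#' meaningless AIC.
#'
#' @param features Numeric matrix or data frame (n x k); k = 0 fits the
#'   intercept-only null model.
#' @param y Binary 0/1 response containing both classes.
#' @return A list with `coefficients` (tibble: term, estimate, se, z,
#'   p_value), `aic`, `loglik`, and `n`.
#' @export
logistic_fit_aic <- function(features, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  if (length(unique(y)) < 2) abort("`y` must contain both classes.")
  features <- if (is.null(features) || NCOL(features) == 0) {
    matrix(0, length(y), 0)
  } else as.matrix(features)
  if (nrow(features) != length(y))
    abort("`features` and `y` must have the same length.")
  k <- ncol(features)
  if (length(y) <= k + 1)
    abort("Need n > k + 1 observations for a k-feature logistic model.")
  if (k > 0 && is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(k))

  df <- data.frame(.y = y, features, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  # a vanishing deviance means y is deterministic given the features (the
  # MLE diverges); the 0/1-probability warning alone also fires for benign
  # quasi-separation, so it only counts when the fit failed to converge
  if (stats::deviance(fit) < 1e-6 || (sep_warn && !fit$converged)) {
    abort("Perfect separation in logistic regression.",
          class = "igsem_separation_error")
  }
  sm <- summary(fit)$coefficients
  list(
    coefficients = tibble(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      z = sm[, 3], p_value = sm[, 4]
    ),
    aic = stats::AIC(fit),
    loglik = as.numeric(stats::logLik(fit)),
    n = length(y)
  )
}

#' Phenotype-prediction AIC comparison across five feature sets
#'
#' Fits logistic regressions of the binary phenotype on (1) the SEM latent
#' scores, (2) the first m principal components of the centred+scaled region
#' matrix, (3) all region columns, (4) all region and SNP columns, and
#' (5) all SNP columns, and reports one AIC per model.
#'
#' @param dataset A [simulate_dataset()] result (or a list with `g`, `x`,
#'   `y`).
#' @param scores Latent scores from [bartlett_scores()] computed on the same
#'   dataset (a converged fit).
#' @return A tibble with columns `model` (`fitted_latents`, `pcs_regions`,
#'   `all_regions`, `all_regions_snps`, `all_snps`), `aic`, and `separated`.
#'   A model that separates perfectly keeps its limiting AIC `2(k+1)` (the
#'   deviance vanishes) and is flagged in `separated` rather than failing
#'   the replicate; strong phenotype weights make this a regular occurrence
#'   for the high-dimensional feature sets.
#' @export
compare_models_aic <- function(dataset, scores) {
  x <- as.matrix(dataset$x); g <- as.matrix(dataset$g); y <- dataset$y
  scores <- as.matrix(scores)
  m <- ncol(scores)
  xs <- scale(x)
  pcs <- prcomp(xs, center = FALSE, scale. = FALSE)$x[, seq_len(m),
                                                      drop = FALSE]
  models <- list(
    fitted_latents = scores,
    pcs_regions = pcs,
    all_regions = x,
    all_regions_snps = cbind(x, g),
    all_snps = g
  )
  rows <- purrr::imap(models, function(f, nm) {
    res <- tryCatch(logistic_fit_aic(f, y),
                    igsem_separation_error = function(e) NULL)
    if (is.null(res)) {
      # separated fit: the deviance vanishes in the limit, so the AIC
      # approaches its penalty floor 2(k+1); keep the replicate, flag it
      tibble(model = nm, aic = 2 * (ncol(f) + 1), separated = TRUE)
    } else {
      tibble(model = nm, aic = res$aic, separated = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Combine a pair of p values with Fisher's method
#'
#' Returns the upper tail of `-2 (log p1 + log p2)` under a chi-squared
#' distribution with 4 degrees of freedom. Zero p values are clamped to the
#' smallest positive double with a warning.
#'
#' @param p1,p2 Numeric vectors of p values in (0, 1].
#' @return Combined p values.
#' @export
fisher_combine <- function(p1, p2) {
  pm <- cbind(p1, p2)
  if (any(pm <= 0)) {
    warn("Zero p values clamped to the smallest positive double.")
    pm[pm <= 0] <- .Machine$double.xmin
  }
  stat <- -2 * rowSums(log(pm))
  pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Per-SNP importance scores along the SNP -> latent -> phenotype path
#'
#' Every SNP-to-phenotype path through latent l carries two p values: the
#' robust p value of the SNP's weight on latent l (`pA[l, j]`) and the
#' logistic-regression p value of latent l for the phenotype (`pL[l]`).
#' Method `"max"` scores SNP j as the minimum over latents of the pairwise
#' maximum; method `"fisher"` combines each pair with [fisher_combine()]
#' (chi-squared, 4 df) and takes the minimum over latents.
#'
#' @param pA m x p matrix of robust p values for the SNP-to-latent weights
#'   (see [snp_weight_pvalues()]).
#' @param pL Length-m vector of latent-to-phenotype p values
#'   (see [latent_phenotype_pvalues()]).
#' @param method `"max"` or `"fisher"`.
#' @return Length-p vector of scores (low = strong evidence), named by SNP.
#' @export
combine_snp_scores <- function(pA, pL, method = c("max", "fisher")) {
  method <- match.arg(method)
  pA <- as.matrix(pA)
  if (length(pL) != nrow(pA))
    abort("`pL` must have one entry per row (latent) of `pA`.")
  if (any(pA > 1) || any(pL > 1) || any(pA < 0) || any(pL < 0))
    abort("p values must lie in [0, 1].")
  if (any(pA == 0) || any(pL == 0)) {
    if (method == "max") {
      warn("Zero p values clamped to the smallest positive double.")
      pA[pA == 0] <- .Machine$double.xmin
      pL[pL == 0] <- .Machine$double.xmin
    } # fisher_combine clamps (and warns) itself
  }
  per_latent <- if (method == "max") {
    pmax(pA, matrix(pL, nrow(pA), ncol(pA)))
  } else {
    matrix(fisher_combine(as.numeric(pA),
                          rep(pL, times = ncol(pA))),
           nrow(pA), ncol(pA))
  }
  setNames(apply(per_latent, 2L, min), colnames(pA))
}

#' GWAS-style baseline SNP p values
#'
#' Logistic regression of the phenotype on SNPs, either one SNP at a time
#' (`"univariate"`, as in a GWAS) or jointly (`"multivariate"`), returning a
#' Wald p value per SNP.
#'
#' @param g Genotype matrix (n x p, any additive coding).
#' @param y Binary phenotype.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return Length-p vector of p values, named by SNP; `NA` for a SNP whose
#'   univariate model separates.
#' @export
baseline_snp_pvalues <- function(g, y, mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  g <- as.matrix(g)
  if (is.null(colnames(g))) colnames(g) <- paste0("S", seq_len(ncol(g)))
  if (mode == "multivariate") {
    res <- logistic_fit_aic(g, y)
    co <- res$coefficients
    p <- setNames(co$p_value[match(colnames(g), co$term)], colnames(g))
  } else {
    p <- vapply(seq_len(ncol(g)), function(j) {
      res <- tryCatch(logistic_fit_aic(g[, j, drop = FALSE], y),
                      igsem_separation_error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$coefficients$p_value[2]
    }, numeric(1))
    names(p) <- colnames(g)
  }
  p
}

#' Latent-to-phenotype logistic p values
#'
#' Joint logistic regression of the phenotype on all latent scores; one Wald
#' p value per latent.
#'
#' @param scores Latent scores (n x m), e.g. from [bartlett_scores()].
#' @param y Binary phenotype.
#' @return Length-m vector of p values named by latent.
#' @export
latent_phenotype_pvalues <- function(scores, y) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("G", seq_len(ncol(scores)))
  res <- logistic_fit_aic(scores, y)
  co <- res$coefficients
  setNames(co$p_value[match(colnames(scores), co$term)], colnames(scores))
}

#' SNP-retrieval AUC from importance scores
#'
#' Area under the ROC curve obtained by sweeping a threshold over the scores
#' (low score = stronger evidence). Computed by the tie-corrected rank
#' statistic: the probability that a random true-effect SNP scores below a
#' random null SNP, counting ties one half.
#'
#' @param scores Numeric score per SNP (e.g. combined p values).
#' @param true_effect Logical (or 0/1) vector marking the true-effect SNPs.
#' @return AUC in [0, 1].
#' @export
retrieval_auc <- function(scores, true_effect) {
  true_effect <- as.logical(true_effect)
  if (length(scores) != length(true_effect))
    abort("`scores` and `true_effect` must have the same length.")
  keep <- !is.na(scores)
  scores <- scores[keep]; true_effect <- true_effect[keep]
  n_t <- sum(true_effect); n_f <- sum(!true_effect)
  if (n_t == 0 || n_f == 0)
    abort("Need at least one true-effect and one null SNP.")
  r <- rank(scores)
  (sum(r[!true_effect]) - n_f * (n_f + 1) / 2) / (n_t * n_f)
}
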