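#' Residualize region measurements on covariates
#'
#' Replaces each region column by the residuals of an ordinary least-squares
#' regression (with intercept) on all covariate columns, e.g. age, sex
#' (coded 0/1) and whole-brain volume. Residuals have exactly zero mean and
#' zero sample correlation with every covariate; applying the operation
#' twice is a no-op.
#'
#' @param regions Numeric matrix or data frame, samples x regions.
#' @param covariates Numeric matrix or data frame, samples x covariates, no
#'   missing values.
#' @return Matrix of residuals with the same dimnames as `regions`.
#' @export
residualize_covariates <- function(regions, covariates) {
  X <- as.matrix(regions); Z <- as.matrix(covariates)
  if (!is.numeric(X) || !is.numeric(Z))
    abort("`regions` and `covariates` must be numeric.")
  if (nrow(X) != nrow(Z))
    abort("`regions` and `covariates` must have the same rows.")
  if (anyNA(X) || anyNA(Z)) abort("Missing values are not allowed.")
  D <- cbind(`(Intercept)` = 1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    abort("Collinear covariates: the design matrix is rank deficient.")
  res <- X - D %*% qr.coef(qrD, X)
  dimnames(res) <- dimnames(X)
  res
}

#' Centre genotypes and centre+scale region measurements
#'
#' SNP columns are centred to zero mean (eliminating model intercepts);
#' region columns are centred and scaled to unit standard deviation to
#' offset the larger variance of larger structures. Standard deviations use
#' the n-1 divisor.
#'
#' @param genotypes Numeric matrix or data frame, samples x SNPs (may have
#'   zero columns).
#' @param regions Numeric matrix or data frame, samples x regions.
#' @return List with `g` (centred) and `x` (centred, unit sd), plus the
#'   `centers` and `scales` used (for applying the same transform elsewhere).
#' @export
standardize <- function(genotypes, regions) {
  g <- as.matrix(genotypes); x <- as.matrix(regions)
  storage.mode(g) <- "double"; storage.mode(x) <- "double"
  check_not_constant(g, "genotypes")
  check_not_constant(x, "regions")
  g_c <- if (ncol(g)) colMeans(g) else numeric(0)
  x_c <- colMeans(x)
  x_s <- apply(x, 2L, sd)
  list(
    g = sweep(g, 2L, g_c),
    x = sweep(sweep(x, 2L, x_c), 2L, x_s, "/"),
    centers = list(g = g_c, x = x_c),
    scales = list(x = x_s)
  )
}

#' Split samples into two equal halves
#'
#' Seeded random 50/50 split (sizes differ by at most one for odd n) used
#' for train/validation workflows: fit on one half, score the other with
#' the training parameter estimates only.
#'
#' @param n Number of samples, or a vector of sample ids.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, covering all samples).
#' @export
split_half <- function(n, seed = 1L) {
  ids <- if (length(n) == 1 && is.numeric(n)) seq_len(n) else seq_along(n)
  set.seed(seed)
  shuffled <- sample(ids)
  k <- floor(length(ids) / 2)
  list(train = sort(shuffled[seq_len(k)]),
       validation = sort(shuffled[(k + 1):length(ids)]))
}

#' Score validation samples with a training fit
#'
#' Computes Bartlett latent scores for new samples using only the loadings
#' and residual variances estimated on the training data. By default the
#' validation regions are centred and scaled with their own moments
#' (`scale = "per_split"`); `scale = "training"` reuses the training centres
#' and scales instead.
#'
#' @param fit A [fit_sem()] result from the training half.
#' @param regions Raw validation region matrix (same columns as training).
#' @param training_std Optional [standardize()] output from the training
#'   half (required for `scale = "training"`).
#' @param scale `"per_split"` or `"training"`.
#' @return Tibble of latent scores (see [bartlett_scores()]).
#' @export
score_validation <- function(fit, regions, training_std = NULL,
                             scale = c("per_split", "training")) {
  scale <- match.arg(scale)
  x <- as_numeric_matrix(regions, fit$spec$region_ids, "regions")
  xs <- if (scale == "per_split") {
    standardize(matrix(0, nrow(x), 0), x)$x
  } else {
    if (is.null(training_std))
      abort("`training_std` is required when scale = \"training\".")
    sweep(sweep(x, 2L, training_std$centers$x), 2L,
          training_std$scales$x, "/")
  }
  bartlett_scores(fit, xs)
}
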