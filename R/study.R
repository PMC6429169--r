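#' Run one replicate of the simulation study
#'
#' Simulates a dataset, standardizes it (centred SNPs, centred+scaled
#' regions), fits the SEM (on the true grouping, or a swapped one when
#' `config$n_swaps > 0`), computes robust p values, Bartlett scores, the
#' five-model AIC comparison, and the four SNP-retrieval AUCs (SEM max,
#' SEM Fisher, multivariate and univariate logistic).
#'
#' @param config A [sim_config()]; its `seed` drives every draw.
#' @return A list with `aic` (tibble model/aic), `auc` (tibble method/auc),
#'   `fit_glance` (one-row tibble), and `dataset`.
#' @export
run_replicate <- function(config) {
  dataset <- simulate_dataset(config)
  fit_spec <- if (config$n_swaps > 0) {
    swap_region_links(dataset$spec, config$n_swaps)
  } else dataset$spec
  std <- standardize(dataset$g, dataset$x)
  fit <- fit_sem(std$g, std$x, fit_spec)
  if (!fit$converged) {
    abort("SEM fit did not converge.", class = "igsem_replicate_error")
  }
  fit <- robust_adjust(fit, std$g, std$x)
  scores <- bartlett_scores(fit, std$x)

  aic <- compare_models_aic(dataset, scores)

  pA <- snp_weight_pvalues(fit)
  pL <- latent_phenotype_pvalues(scores, dataset$y)
  truth <- dataset$truth$true_effect_snps
  auc <- tibble(
    method = c("sem_max", "sem_fisher", "multivariate_logistic",
               "univariate_logistic"),
    auc = c(
      retrieval_auc(combine_snp_scores(pA, pL, "max"), truth),
      retrieval_auc(combine_snp_scores(pA, pL, "fisher"), truth),
      retrieval_auc(baseline_snp_pvalues(dataset$g, dataset$y,
                                         "multivariate"), truth),
      retrieval_auc(baseline_snp_pvalues(dataset$g, dataset$y,
                                         "univariate"), truth)
    )
  )
  list(aic = aic, auc = auc, fit_glance = glance(fit), dataset = dataset)
}

#' Run the full simulation study
#'
#' Repeats [run_replicate()] over independent datasets, optionally across a
#' sweep grid of configuration overrides (e.g.
#' `sweep = list(region_noise_sd = c(1, 3, 5))`; multiple entries are
#' crossed). Each replicate gets a child seed derived deterministically from
#' the root seed and a replicate counter, so any cell/replicate can be
#' re-run in isolation.
#'
#' @param config Base [sim_config()].
#' @param n_replicates Replicates per sweep cell.
#' @param sweep Optional named list of parameter vectors overriding `config`
#'   fields per cell; `NULL` runs the single base configuration.
#' @param seed Root integer seed (defaults to `config$seed`).
#' @return An object of class `sem_study`: tibbles `aic` and `auc` (one row
#'   per replicate x model/method, with sweep columns and `replicate`),
#'   `failures` (replicate, cell, reason), and `n_replicates`.
#'   More than 20% failed replicates is an error.
#' @export
run_simulation_study <- function(config = sim_config(), n_replicates = 100L,
                                 sweep = NULL, seed = config$seed) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  cells <- if (is.null(sweep)) {
    tibble(.cell = 1L)
  } else {
    grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$.cell <- seq_len(nrow(grid))
    as_tibble(grid)
  }
  sweep_cols <- setdiff(names(cells), ".cell")

  aic_rows <- list(); auc_rows <- list(); fail_rows <- list()
  counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    overrides <- as.list(cells[ci, sweep_cols, drop = FALSE])
    for (r in seq_len(n_replicates)) {
      counter <- counter + 1L
      child <- child_seed(seed, counter)
      cfg_args <- modifyList(unclass(config),
                             c(overrides, list(seed = child)))
      cfg <- do.call(sim_config, cfg_args)
      rep_res <- tryCatch(
        run_replicate(cfg),
        error = function(e) e
      )
      tag <- cells[rep(ci, 1L), sweep_cols, drop = FALSE]
      if (inherits(rep_res, "error")) {
        fail_rows[[length(fail_rows) + 1L]] <- dplyr::bind_cols(
          tibble(replicate = r, cell = ci,
                 reason = conditionMessage(rep_res)), tag)
      } else {
        aic_rows[[length(aic_rows) + 1L]] <- dplyr::bind_cols(
          tibble(replicate = r, cell = ci), tag, rep_res$aic)
        auc_rows[[length(auc_rows) + 1L]] <- dplyr::bind_cols(
          tibble(replicate = r, cell = ci), tag, rep_res$auc)
      }
    }
  }
  failures <- if (length(fail_rows)) dplyr::bind_rows(fail_rows) else
    tibble(replicate = integer(), cell = integer(), reason = character())
  n_total <- nrow(cells) * n_replicates
  if (nrow(failures) > 0.2 * n_total) {
    abort(sprintf("%d of %d replicates failed (> 20%%).",
                  nrow(failures), n_total))
  }
  structure(
    list(aic = dplyr::bind_rows(aic_rows),
         auc = dplyr::bind_rows(auc_rows),
         failures = failures,
         sweep_cols = sweep_cols,
         n_replicates = n_replicates,
         config = config, seed = seed),
    class = "sem_study"
  )
}

# deterministic 32-bit child seed from a root seed and a counter
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 7919) %% 2147483647L)
}

#' @export
print.sem_study <- function(x, ...) {
  cat("<sem_study>", x$n_replicates, "replicates per cell,",
      length(unique(x$aic$cell)), "cell(s),",
      nrow(x$failures), "failure(s)\n")
  print(summary(x))
  invisible(x)
}

#' Summarize a simulation study
#'
#' Mean and sd of AIC per model and AUC per method, by sweep cell.
#'
#' @param object A [run_simulation_study()] result.
#' @param ... Unused.
#' @return A list with tibbles `aic` and `auc`.
#' @export
summary.sem_study <- function(object, ...) {
  grp_a <- c(object$sweep_cols, "model")
  grp_b <- c(object$sweep_cols, "method")
  list(
    aic = object$aic |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_a))) |>
      dplyr::summarise(mean_aic = mean(.data$aic), sd_aic = sd(.data$aic),
                       n = dplyr::n(), .groups = "drop"),
    auc = object$auc |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_b))) |>
      dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                       n = dplyr::n(), .groups = "drop")
  )
}

#' Write study results as tidy CSV + JSON summary
#'
#' @param study A [run_simulation_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sem_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aic <- dplyr::mutate(study$aic, metric = "aic") |>
    dplyr::rename(value = "aic")
  auc <- dplyr::mutate(study$auc, metric = "auc") |>
    dplyr::rename(value = "auc", model = "method")
  readr::write_csv(dplyr::bind_rows(aic, auc), file.path(dir, "study.csv"))
  sm <- summary(study)
  jsonlite::write_json(
    list(aic = sm$aic, auc = sm$auc,
         n_failures = nrow(study$failures),
         n_replicates = study$n_replicates, seed = study$seed),
    file.path(dir, "summary.json"), digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
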