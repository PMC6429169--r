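#' Load and align the tabular study inputs
#'
#' Reads the genotype, region, grouping and (optionally) covariate and
#' diagnosis tables, inner-joins the sample tables on their first column
#' (`sample_id`), and drops region columns that have no entry in the
#' grouping table (with a logged count). CSV and TSV are distinguished by
#' file extension.
#'
#' @param paths Named list of file paths: `genotypes`, `regions`,
#'   `grouping`, and optionally `covariates`, `diagnosis`. Sample tables
#'   must have a `sample_id` first column; the grouping table has
#'   `region_id`, `group_code`.
#' @return A list of class `study_tables`: tibbles `genotypes`, `regions`,
#'   `grouping`, `covariates`/`diagnosis` (or `NULL`), a `sample_id`
#'   vector, and `dropped` (counts of dropped regions/samples).
#' @export
load_study <- function(paths) {
  need <- c("genotypes", "regions", "grouping")
  if (!all(need %in% names(paths)))
    abort("`paths` must name at least genotypes, regions and grouping files.")

  read_table_file <- function(path) {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  check_samples <- function(tab, what) {
    if (names(tab)[1] != "sample_id")
      abort(sprintf("First column of the %s table must be `sample_id`.", what))
    if (anyDuplicated(tab$sample_id))
      abort(sprintf("Duplicate sample ids in the %s table.", what))
    tab
  }
  check_numeric <- function(tab, what) {
    for (cn in setdiff(names(tab), "sample_id")) {
      if (!is.numeric(tab[[cn]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(tab[[cn]]))))[1]
        abort(sprintf("Non-numeric value in %s table, column %s, row %s.",
                      what, cn, bad %||% "?"))
      }
    }
    tab
  }

  gt <- check_numeric(check_samples(read_table_file(paths$genotypes),
                                    "genotype"), "genotype")
  rt <- check_numeric(check_samples(read_table_file(paths$regions),
                                    "region"), "region")
  grouping <- read_table_file(paths$grouping)
  if (!all(c("region_id", "group_code") %in% names(grouping)))
    abort("Grouping table must have columns `region_id` and `group_code`.")

  ids <- intersect(gt$sample_id, rt$sample_id)
  cov <- diag_tab <- NULL
  if (!is.null(paths$covariates)) {
    cov <- check_numeric(check_samples(read_table_file(paths$covariates),
                                       "covariate"), "covariate")
    ids <- intersect(ids, cov$sample_id)
  }
  if (!is.null(paths$diagnosis)) {
    diag_tab <- check_samples(read_table_file(paths$diagnosis), "diagnosis")
    ids <- intersect(ids, diag_tab$sample_id)
  }
  if (length(ids) == 0) abort("No overlapping sample ids across tables.")
  n_dropped_samples <- max(nrow(gt), nrow(rt)) - length(ids)

  region_cols <- setdiff(names(rt), "sample_id")
  linked <- intersect(region_cols, grouping$region_id)
  n_dropped_regions <- length(region_cols) - length(linked)
  if (n_dropped_regions > 0) {
    inform(sprintf("Dropped %d region column(s) without a group entry.",
                   n_dropped_regions))
  }
  if (length(linked) == 0) abort("No region column has a group entry.")

  align <- function(tab) tab[match(ids, tab$sample_id), , drop = FALSE]
  structure(
    list(
      genotypes = align(gt),
      regions = align(rt)[, c("sample_id", linked)],
      grouping = grouping[grouping$region_id %in% linked, ],
      covariates = if (!is.null(cov)) align(cov) else NULL,
      diagnosis = if (!is.null(diag_tab)) align(diag_tab) else NULL,
      sample_id = ids,
      dropped = list(regions = n_dropped_regions,
                     samples = n_dropped_samples)
    ),
    class = "study_tables"
  )
}

#' @export
print.study_tables <- function(x, ...) {
  cat("<study_tables>", length(x$sample_id), "samples,",
      ncol(x$genotypes) - 1, "SNPs,", ncol(x$regions) - 1, "regions\n")
  cat("  dropped:", x$dropped$regions, "region(s),",
      x$dropped$samples, "sample(s)\n")
  invisible(x)
}

#' End-to-end pipeline on user-supplied (or synthetic) study tables
#'
#' Runs the full downstream analysis: optional covariate residualization,
#' centring/scaling, SEM fit with robust p values, Bartlett scores,
#' Bonferroni-adjusted SNP-to-latent association table, and (when diagnosis
#' labels are present) a per-latent one-way ANOVA across diagnosis groups.
#'
#' @param tables A [load_study()] result.
#' @param alpha Significance level for Bonferroni flags and ANOVA.
#' @param options Passed to [fit_sem()].
#' @return A list with `fit` (robust-adjusted `sem_fit`), `scores`,
#'   `bonferroni` (see [bonferroni_adjust()]), and `anova` (tibble or
#'   `NULL`).
#' @export
run_study_pipeline <- function(tables, alpha = 0.05, options = list()) {
  stopifnot(inherits(tables, "study_tables"))
  g <- as.matrix(tables$genotypes[, -1, drop = FALSE])
  x <- as.matrix(tables$regions[, -1, drop = FALSE])
  if (!is.null(tables$covariates)) {
    x <- residualize_covariates(x, as.matrix(tables$covariates[, -1]))
  }
  std <- standardize(g, x)
  spec <- build_spec(tables$grouping, snp_ids = colnames(g),
                     region_order = colnames(x))
  fit <- fit_sem(std$g, std$x, spec, options = options)
  fit <- robust_adjust(fit, std$g, std$x)
  scores <- bartlett_scores(fit, std$x)
  bonf <- bonferroni_adjust(snp_weight_pvalues(fit), alpha = alpha)
  anova_tab <- NULL
  if (!is.null(tables$diagnosis)) {
    lab <- tables$diagnosis[[2]]
    anova_tab <- anova_by_group(scores, lab, alpha = alpha)
  }
  list(fit = fit, scores = scores, bonferroni = bonf, anova = anova_tab)
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys match
#'   the arguments of [sim_config()].
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("Reading YAML configs requires the yaml package.")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(sim_config, vals)
}
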