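#' Tidy a fitted grouped-latent SEM
#'
#' @param x A [fit_sem()] result.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `parameter`, `kind`
#'   (`loading`, `snp_weight`, `psi`, `theta`), `from`, `to`, `estimate`,
#'   `se_naive`, `se_robust`, `z_robust`, `p_robust`.
#' @export
tidy.sem_fit <- function(x, ...) {
  as_tibble(x$param_table)
}

#' Glance at a fitted grouped-latent SEM
#'
#' @inheritParams tidy.sem_fit
#' @return A one-row tibble: `n`, `n_free`, `discrepancy`, `loglik`,
#'   `converged`, `robust`, `n_restarts`.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble(n = x$n, n_free = x$n_free, discrepancy = x$discrepancy,
         loglik = x$loglik, converged = x$converged, robust = x$robust,
         n_restarts = x$n_restarts)
}

#' Serialize / read a fit result
#'
#' The parameter table is written as CSV (columns `parameter`, `from`, `to`,
#' `estimate`, `se_naive`, `se_robust`, `z_robust`, `p_robust`) and the
#' scalar header (`n`, `discrepancy`, `loglik`, `converged`) as a JSON
#' sidecar.
#'
#' @param fit A [fit_sem()] result.
#' @param path_csv Path for the parameter table.
#' @param path_json Path for the JSON header (default: `path_csv` with a
#'   `.json` extension).
#' @return `write_fit_result()` returns `path_csv` invisibly;
#'   `read_fit_result()` a list with `parameters` (tibble) and `header`
#'   (list).
#' @export
write_fit_result <- function(fit, path_csv,
                             path_json = sub("\\.[^.]*$", ".json", path_csv)) {
  stopifnot(inherits(fit, "sem_fit"))
  tab <- fit$param_table[, c("parameter", "from", "to", "estimate",
                             "se_naive", "se_robust", "z_robust", "p_robust")]
  readr::write_csv(tab, path_csv)
  jsonlite::write_json(
    list(n = fit$n, n_free = fit$n_free, discrepancy = fit$discrepancy,
         loglik = fit$loglik, converged = fit$converged,
         robust = fit$robust),
    path_json, auto_unbox = TRUE, digits = NA
  )
  invisible(path_csv)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path_csv,
                            path_json = sub("\\.[^.]*$", ".json", path_csv)) {
  list(
    parameters = readr::read_csv(path_csv, show_col_types = FALSE),
    header = jsonlite::read_json(path_json, simplifyVector = TRUE)
  )
}
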