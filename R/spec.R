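#' Build a grouped-latent SEM specification
#'
#' A model specification ties each brain region measurement to exactly one
#' region group; every group gets one latent variable. The first region of
#' each group (in `region_order`) is the anchor: its loading is fixed to 1,
#' which sets the scale and sign of the latent variable.
#'
#' @param grouping A data frame with columns `region_id` and `group_code`
#'   (the shape of a two-column region-to-group mapping table), mapping every
#'   region to the group whose latent variable loads on it.
#' @param snp_ids Character vector of SNP identifiers (may be empty for a
#'   measurement-only model).
#' @param region_order Optional character vector giving the order of regions;
#'   defaults to the order of appearance in `grouping`. The first region per
#'   group in this order becomes the group's anchor.
#'
#' @return An object of class `sem_spec`: a list with `snp_ids`, `region_ids`,
#'   `group_ids`, `membership` (named character vector region -> group),
#'   `anchor_region` (named character vector group -> region), and the counts
#'   `p`, `q`, `m`.
#'
#' @details Groups with a single region are rejected: with one indicator the
#'   free loading and the residual variance of that region are not separately
#'   identifiable.
#'
#' @examples
#' grouping <- data.frame(
#'   region_id = c("r1", "r2", "r3", "r4", "r5"),
#'   group_code = c("G1", "G1", "G1", "G2", "G2")
#' )
#' spec <- build_spec(grouping, snp_ids = c("s1", "s2"))
#' spec$m # 2 latent variables
#' @export
build_spec <- function(grouping, snp_ids = character(), region_order = NULL) {
  grouping <- as.data.frame(grouping)
  need <- c("region_id", "group_code")
  if (!all(need %in% names(grouping))) {
    abort("`grouping` must have columns `region_id` and `group_code`.")
  }
  grouping$region_id <- as.character(grouping$region_id)
  grouping$group_code <- as.character(grouping$group_code)
  if (anyNA(grouping$region_id) || anyNA(grouping$group_code) ||
      any(grouping$group_code == "")) {
    abort("Every region must be mapped to a non-missing group code.")
  }
  if (anyDuplicated(grouping$region_id)) {
    abort("Duplicate region ids in `grouping`.")
  }

  region_order <- region_order %||% grouping$region_id
  region_order <- as.character(region_order)
  if (!setequal(region_order, grouping$region_id) ||
      length(region_order) != nrow(grouping)) {
    abort("`region_order` must be a permutation of `grouping$region_id`.")
  }

  membership <- setNames(grouping$group_code, grouping$region_id)[region_order]
  group_ids <- unique(unname(membership))

  sizes <- table(membership)
  if (any(sizes < 2)) {
    abort(paste0(
      "Region group(s) with a single region: ",
      paste(names(sizes)[sizes < 2], collapse = ", "),
      ". One indicator cannot identify both its loading and the group ",
      "residual variance."
    ))
  }

  anchor <- vapply(group_ids, function(g) {
    region_order[membership == g][1L]
  }, character(1))

  structure(
    list(
      snp_ids = as.character(snp_ids),
      region_ids = region_order,
      group_ids = group_ids,
      membership = membership,
      anchor_region = anchor,
      p = length(snp_ids),
      q = length(region_order),
      m = length(group_ids)
    ),
    class = "sem_spec"
  )
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<sem_spec> ", x$p, " SNPs, ", x$q, " regions, ", x$m,
      " region groups\n", sep = "")
  sizes <- table(factor(x$membership, levels = x$group_ids))
  for (g in x$group_ids) {
    cat("  ", g, ": ", sizes[[g]], " regions (anchor ",
        x$anchor_region[[g]], ")\n", sep = "")
  }
  invisible(x)
}

#' Loading pattern implied by a specification
#'
#' Logical q x m matrix that is `TRUE` where the loading matrix may be
#' nonzero (each region loads only on its own group's latent variable).
#'
#' @param spec A [build_spec()] object.
#' @return Logical matrix with region rows and group columns.
#' @keywords internal
loading_pattern <- function(spec) {
  pat <- outer(spec$membership, setNames(spec$group_ids, spec$group_ids), "==")
  dimnames(pat) <- list(spec$region_ids, spec$group_ids)
  pat
}

#' Indices of the free (non-anchor) loadings, column-major over groups
#' @noRd
free_loading_table <- function(spec) {
  rows <- lapply(spec$group_ids, function(g) {
    members <- spec$region_ids[spec$membership == g]
    free <- setdiff(members, spec$anchor_region[[g]])
    if (length(free) == 0) return(NULL)
    data.frame(region_id = free, group_id = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_spec_grouping <- function(spec) {
  tibble(region_id = spec$region_ids,
         group_code = unname(spec$membership[spec$region_ids]))
}

#' Read / write a region-grouping table
#'
#' The on-disk shape is a two-column TSV (`region_id`, `group_code`), one row
#' per region.
#'
#' @param path File path.
#' @return `read_grouping()` returns a tibble; `write_grouping()` returns
#'   `path` invisibly.
#' @export
read_grouping <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    region_id = readr::col_character(),
    group_code = readr::col_character()
  ))
}

#' @rdname read_grouping
#' @param spec A `sem_spec` or a data frame with `region_id`, `group_code`.
#' @export
write_grouping <- function(spec, path) {
  tab <- if (inherits(spec, "sem_spec")) as_spec_grouping(spec) else
    as_tibble(spec)[, c("region_id", "group_code")]
  readr::write_tsv(tab, path)
  invisible(path)
}
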