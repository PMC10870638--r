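#' The 38-symptom survey item catalog
#'
#' Returns the item catalog of the modified Memorial Symptom Assessment
#' Scale (MSAS) used throughout the package: the 32 original MSAS symptoms
#' plus six additions (hot flashes, chest tightness, difficulty breathing,
#' abdominal cramps, increased appetite, weight gain). Codes are short,
#' stable identifiers used as column suffixes in patient-level files and as
#' row labels in correlation and loading matrices.
#'
#' @return A tibble with columns `code`, `label`, and `index` (position in
#'   the catalog, 1-based). Codes are unique.
#' @export
#' @examples
#' msas_items()
msas_items <- function() {
  path <- system.file("extdata", "msas_items.csv", package = "symclust")
  items <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  items$index <- seq_len(nrow(items))
  tibble::as_tibble(items)
}

#' Published per-group symptom occurrence rates
#'
#' Occurrence percentages of the 38 symptoms in a large two-group sample of
#' oncology patients receiving chemotherapy (741 younger, < 60 years; 602
#' older, >= 60 years), as printed in the source study's descriptive table.
#' These rates calibrate the synthetic-data generator's thresholds and serve
#' as worked-example inputs for the descriptive layer.
#'
#' @return A tibble with columns `code`, `pct_younger`, `pct_older`
#'   (percentages, 0-100), in descending order of the younger group's rate.
#' @export
reference_occurrence_rates <- function() {
  path <- system.file("extdata", "occurrence_rates.csv", package = "symclust")
  readr::read_csv(path, col_types = readr::cols(
    code = "c", pct_younger = "d", pct_older = "d"
  ))
}

#' Published rotated loading tables for the two age groups
#'
#' The per-group items-by-clusters loading tables from the source study's
#' eight-factor solutions (unweighted least squares extraction, geomin
#' rotation; loadings below the 0.40 reporting threshold printed as absent
#' are stored as 0). These tables drive the comparator stage's worked
#' examples and the default synthetic generating model.
#'
#' @param group `"younger"` or `"older"`.
#' @return A numeric matrix (38 items x 8 clusters) with item codes as row
#'   names and cluster labels as column names.
#' @export
reference_loading_matrix <- function(group = c("younger", "older")) {
  group <- match.arg(group)
  path <- system.file(
    "extdata", paste0("cluster_loadings_", group, ".tsv"),
    package = "symclust"
  )
  read_loading_table(path)
}

#' Read and write loading tables
#'
#' A loading table is a TSV with an item-code column `code` followed by one
#' numeric column per factor. The reader accepts both the tables written by
#' [fit_efa()] pipelines and transcriptions of published loading tables, so
#' printed solutions can be fed directly into [extract_clusters()] and the
#' cluster comparison stage.
#'
#' @param path File path.
#' @return `read_loading_table()`: a numeric matrix with item codes as row
#'   names; `write_loading_table()`: the path, invisibly.
#' @export
read_loading_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    code = readr::col_character(), .default = readr::col_double()
  ))
  stopifnot("code" %in% names(tbl), !anyDuplicated(tbl$code))
  m <- as.matrix(tbl[setdiff(names(tbl), "code")])
  rownames(m) <- tbl$code
  m
}

#' @rdname read_loading_table
#' @param loadings A numeric matrix with item codes as row names.
#' @export
write_loading_table <- function(loadings, path) {
  stopifnot(is.matrix(loadings), !is.null(rownames(loadings)))
  cols <- colnames(loadings)
  if (is.null(cols)) cols <- paste0("F", seq_len(ncol(loadings)))
  tbl <- tibble::as_tibble(loadings, .name_repair = ~cols)
  tbl <- dplyr::bind_cols(tibble::tibble(code = rownames(loadings)), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}
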