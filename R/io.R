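#' Read a patient-level symptom dataset
#'
#' Reads a comma-separated patient file with a header row and, per item code
#' in the catalog, columns `occ_<code>` (0/1 occurrence indicator),
#' `sev_<code>` (severity 1-4, defined only where the symptom occurred) and
#' `dis_<code>` (distress 0-4, likewise). Missing values are empty cells.
#' An `age` column (years, may be non-integer) is required; a `patient_id`
#' column is optional and synthesized from the row number when absent.
#'
#' Validation enforces the conditional-rating invariant of the instrument:
#' a severity or distress rating may only be present where the symptom's
#' occurrence is 1. Rows whose age cannot be parsed are dropped with a
#' warning reporting the count.
#'
#' @param path CSV file path.
#' @param items Item catalog tibble (see [msas_items()]); only its `code`
#'   column is used.
#' @return A validated symptom dataset tibble with attribute `"items"`.
#' @seealso [write_symptom_data()], [validate_symptom_data()]
#' @export
read_symptom_data <- function(path, items = msas_items()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  required <- c("age", paste0("occ_", items$code),
                paste0("sev_", items$code), paste0("dis_", items$code))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"patient_id" %in% names(raw)) {
    raw$patient_id <- sprintf("p%05d", seq_len(nrow(raw)))
  }
  age <- suppressWarnings(as.numeric(raw$age))
  bad_age <- is.na(age) | age < 0
  if (any(bad_age)) {
    warning(sum(bad_age), " row(s) with unparseable or negative age dropped")
    raw <- raw[!bad_age, , drop = FALSE]
    age <- age[!bad_age]
  }
  data <- tibble::tibble(patient_id = raw$patient_id, age = age)
  for (col in required[-1]) {
    data[[col]] <- suppressWarnings(as.integer(raw[[col]]))
  }
  validate_symptom_data(data, items)
}

#' Validate a symptom dataset
#'
#' Checks the dataset against the instrument's invariants: occurrence in
#' \{0, 1, NA\}, severity in 1-4, distress in 0-4, and no severity/distress
#' rating where occurrence is not 1. Offending cells are reported by row
#' and column.
#'
#' @param data A symptom dataset tibble.
#' @param items Item catalog tibble.
#' @return `data` invisibly coerced to a tibble, with attribute `"items"`.
#' @export
validate_symptom_data <- function(data, items = msas_items()) {
  data <- tibble::as_tibble(data)
  problems <- character()
  cell_ref <- function(col, rows) {
    paste0(col, "[row ", paste(utils::head(rows, 5), collapse = ","),
           if (length(rows) > 5) ",..." else "", "]")
  }
  for (code in items$code) {
    occ <- data[[paste0("occ_", code)]]
    sev <- data[[paste0("sev_", code)]]
    dis <- data[[paste0("dis_", code)]]
    bad <- which(!is.na(occ) & !occ %in% c(0L, 1L))
    if (length(bad)) problems <- c(problems, cell_ref(paste0("occ_", code), bad))
    bad <- which(!is.na(sev) & !sev %in% 1:4)
    if (length(bad)) problems <- c(problems, cell_ref(paste0("sev_", code), bad))
    bad <- which(!is.na(dis) & !dis %in% 0:4)
    if (length(bad)) problems <- c(problems, cell_ref(paste0("dis_", code), bad))
    present <- !is.na(occ) & occ == 1L
    bad <- which(!present & !is.na(sev))
    if (length(bad)) {
      problems <- c(problems, paste0("severity without occurrence: ",
                                     cell_ref(paste0("sev_", code), bad)))
    }
    bad <- which(!present & !is.na(dis))
    if (length(bad)) {
      problems <- c(problems, paste0("distress without occurrence: ",
                                     cell_ref(paste0("dis_", code), bad)))
    }
  }
  if (length(problems) > 0) {
    stop("symptom data validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  attr(data, "items") <- items
  invisible(data)
}

#' @rdname read_symptom_data
#' @param data A symptom dataset tibble.
#' @export
write_symptom_data <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::starts_with(c("occ_", "sev_", "dis_")), as.integer
  ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Split a symptom dataset into younger and older groups
#'
#' Dichotomizes the sample at an age cutoff, following the WHO convention
#' that the older population is >= 60 years: records with `age >= cutoff` go
#' to the older group (the boundary is inclusive on the older side). The
#' partition is exhaustive and disjoint.
#'
#' @param data A symptom dataset tibble with an `age` column.
#' @param cutoff Age cutoff in years (default 60).
#' @param min_group_factor Warn when a group has fewer than
#'   `min_group_factor` times the item count of records (factor-analysis
#'   sample-size heuristic); set to 0 to disable.
#' @return A list of class `"age_split"` with elements `younger`, `older`
#'   (tibbles) and `cutoff`.
#' @export
split_by_age <- function(data, cutoff = 60, min_group_factor = 5) {
  stopifnot(all(!is.na(data$age)))
  younger <- dplyr::filter(data, .data$age < cutoff)
  older <- dplyr::filter(data, .data$age >= cutoff)
  n_items <- sum(startsWith(names(data), "occ_"))
  for (nm in c("younger", "older")) {
    g <- if (nm == "younger") younger else older
    if (nrow(g) == 0) {
      warning("empty ", nm, " group at cutoff ", cutoff)
    } else if (nrow(g) < min_group_factor * n_items) {
      warning(nm, " group has ", nrow(g), " records, fewer than ",
              min_group_factor, "x the item count (", n_items,
              "); factor analysis may be unstable")
    }
  }
  structure(
    list(younger = younger, older = older, cutoff = cutoff),
    class = "age_split"
  )
}

#' @export
print.age_split <- function(x, ...) {
  n <- nrow(x$younger) + nrow(x$older)
  cat("Age split at ", x$cutoff, " years: ",
      nrow(x$younger), " younger (", round(100 * nrow(x$younger) / n, 1),
      "%), ", nrow(x$older), " older (", round(100 * nrow(x$older) / n, 1),
      "%)\n", sep = "")
  invisible(x)
}

# Binary occurrence matrix (n x p, 0/1/NA) from a dataset tibble.
occurrence_matrix <- function(data, items = attr(data, "items") %||% msas_items()) {
  cols <- paste0("occ_", items$code)
  m <- as.matrix(data[cols])
  colnames(m) <- items$code
  storage.mode(m) <- "integer"
  m
}
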