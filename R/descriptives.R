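#' Per-item occurrence rates
#'
#' The occurrence rate of a symptom is the share of patients reporting it
#' among those with a non-missing occurrence indicator for that item
#' (missing indicators are excluded item by item).
#'
#' @param data A symptom dataset tibble.
#' @return A tibble with `code`, `n_present`, `n_absent`, `rate` (proportion
#'   in \[0, 1\], `NA` if no non-missing observations, with a warning).
#' @export
occurrence_rates <- function(data) {
  stopifnot(nrow(data) > 0)
  m <- occurrence_matrix(data)
  n_present <- colSums(m == 1L, na.rm = TRUE)
  n_absent <- colSums(m == 0L, na.rm = TRUE)
  rate <- ifelse(n_present + n_absent > 0,
                 n_present / (n_present + n_absent), NA_real_)
  if (anyNA(rate)) {
    warning("item(s) with no non-missing occurrence: ",
            paste(colnames(m)[is.na(rate)], collapse = ", "))
  }
  tibble::tibble(code = colnames(m), n_present = unname(n_present),
                 n_absent = unname(n_absent), rate = unname(rate))
}

#' Mean number of symptoms per patient
#'
#' Counts each patient's present symptoms and returns the sample mean and
#' standard deviation. On complete data the mean equals the sum of the
#' per-item occurrence rates.
#'
#' @param data A symptom dataset tibble.
#' @return A tibble with `n`, `mean`, `sd` of the per-patient symptom count.
#' @export
mean_symptom_count <- function(data) {
  stopifnot(nrow(data) > 0)
  counts <- rowSums(occurrence_matrix(data) == 1L, na.rm = TRUE)
  tibble::tibble(n = length(counts), mean = mean(counts),
                 sd = stats::sd(counts))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value of independence in a 2x2 table, computed by summing
#' hypergeometric probabilities (at fixed margins) of all tables no more
#' probable than the observed one.
#'
#' @param a,b,c,d Nonnegative integer counts: `a`, `b` are
#'   present/absent in group 1, `c`, `d` in group 2.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5) # 1
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("Fisher's exact test needs both margins positive")
  }
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum test for a location difference between two ordinal samples:
#' U from midranks, two-sided p from the normal approximation with
#' tie-corrected variance and continuity correction -- appropriate for the
#' group sizes this package targets (hundreds per group).
#'
#' @param x,y Numeric/ordinal samples (missing values dropped).
#' @return A tibble with `u` (U statistic for `x`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical across both samples; p = 1")
    return(tibble::tibble(u = length(x) * length(y) / 2, p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-sample t test
#'
#' Welch (default) or pooled-variance Student t test. `two_sample_t()` works
#' on raw samples; `two_sample_t_summary()` on summary statistics
#' (mean, SD, n per group), which lets published table rows be re-tested.
#'
#' @param x,y Numeric samples (missing values dropped).
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return A tibble with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("zero variance in both samples")
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' @rdname two_sample_t
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Per-group summary statistics.
#' @export
two_sample_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                                 pooled = FALSE) {
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0)
  if (pooled) {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  } else {
    vx <- sd_x^2 / n_x
    vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  t <- (mean_x - mean_y) / se
  tibble::tibble(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Compare symptom occurrence, severity, and distress between two groups
#'
#' Reproduces the descriptive comparison layer for an age-dichotomized
#' sample: per symptom, occurrence rates in both groups with a Fisher's
#' exact test on the 2x2 occurrence table, and severity/distress means, SDs
#' and Mann-Whitney tests computed over the patients who reported the
#' symptom (ratings exist only where the symptom occurred). P-values are
#' unadjusted, matching the source analysis; pass `adjust = "bonferroni"`
#' to correct them.
#'
#' @param split An `"age_split"` from [split_by_age()] (or any list with
#'   `younger` and `older` dataset tibbles).
#' @param alpha Significance level for the summary count.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return A tibble with one row per symptom and attribute
#'   `"n_significant_occurrence"` (items with occurrence `fisher_p < alpha`).
#' @export
compare_groups <- function(split, alpha = 0.05, adjust = "none") {
  younger <- split$younger
  older <- split$older
  stopifnot(nrow(younger) > 0, nrow(older) > 0)
  items <- attr(younger, "items") %||% msas_items()
  rows <- purrr::map(items$code, function(code) {
    oy <- younger[[paste0("occ_", code)]]
    oo <- older[[paste0("occ_", code)]]
    a <- sum(oy == 1L, na.rm = TRUE); b <- sum(oy == 0L, na.rm = TRUE)
    cc <- sum(oo == 1L, na.rm = TRUE); dd <- sum(oo == 0L, na.rm = TRUE)
    rate_test <- function(xs, ys) {
      xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
      if (length(xs) == 0 || length(ys) == 0) {
        return(list(my = NA_real_, sy = NA_real_, mo = NA_real_,
                    so = NA_real_, p = NA_real_))
      }
      mw <- suppressWarnings(mann_whitney_u(xs, ys))
      list(my = mean(xs), sy = stats::sd(xs), mo = mean(ys),
           so = stats::sd(ys), p = mw$p_value)
    }
    sev <- rate_test(younger[[paste0("sev_", code)]],
                     older[[paste0("sev_", code)]])
    dis <- rate_test(younger[[paste0("dis_", code)]],
                     older[[paste0("dis_", code)]])
    tibble::tibble(
      code = code,
      rate_younger = a / (a + b), rate_older = cc / (cc + dd),
      fisher_p = fisher_exact_2x2(a, b, cc, dd),
      severity_mean_younger = sev$my, severity_sd_younger = sev$sy,
      severity_mean_older = sev$mo, severity_sd_older = sev$so,
      severity_p = sev$p,
      distress_mean_younger = dis$my, distress_sd_younger = dis$sy,
      distress_mean_older = dis$mo, distress_sd_older = dis$so,
      distress_p = dis$p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust != "none") {
    out <- dplyr::mutate(out, dplyr::across(
      c("fisher_p", "severity_p", "distress_p"),
      ~stats::p.adjust(.x, method = adjust)
    ))
  }
  attr(out, "n_significant_occurrence") <- sum(out$fisher_p < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Top-k ranking with ties
#'
#' Ranks items by value in descending order using dense ranks, so tied
#' values share a rank and the list of items with rank <= k may exceed k
#' entries (as published ranking tables do).
#'
#' @param values A tibble with columns `code` and `value`, or a named
#'   numeric vector.
#' @param k Number of ranks to keep (default 10).
#' @return A tibble `code`, `value`, `rank`, sorted by rank then catalog
#'   order, containing every item whose dense rank is <= `k`.
#' @export
rank_top_symptoms <- function(values, k = 10) {
  stopifnot(k >= 1)
  if (!is.data.frame(values)) {
    values <- tibble::tibble(code = names(values), value = unname(values))
  }
  values |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$value))) |>
    dplyr::filter(.data$rank <= k) |>
    dplyr::arrange(.data$rank)
}
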