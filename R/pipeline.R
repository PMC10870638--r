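#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one validated list.
#' Seeds are mandatory: runs are reproducible by construction, and the run
#' log written by [run_symptom_pipeline()] records every setting in effect.
#'
#' @param age_cutoff Years; records at or above it form the older group.
#' @param alpha Significance level for the descriptive tests.
#' @param threshold Loading threshold for cluster membership.
#' @param k_min,k_max Factor-count range to fit.
#' @param k_younger,k_older Factor count whose solution is carried into the
#'   cluster comparison, per group (default 8 for both).
#' @param epsilon Geomin smoothing constant.
#' @param n_starts Random rotation starts.
#' @param seed Integer seed for the rotation starts.
#' @param min_shared Stability threshold (shared symptoms).
#' @param top_k Ranking depth for the top-symptom lists.
#' @param labels Optional named vector of cluster display labels.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(age_cutoff = 60, alpha = 0.05, threshold = 0.40,
                            k_min = 2, k_max = 8, k_younger = 8, k_older = 8,
                            epsilon = 0.01, n_starts = 30, seed,
                            min_shared = 2, top_k = 10, labels = NULL) {
  stopifnot(k_min >= 2, k_min <= k_max, threshold > 0,
            alpha > 0, alpha < 1,
            k_younger >= k_min, k_younger <= k_max,
            k_older >= k_min, k_older <= k_max)
  if (missing(seed)) stop("a seed is required (no wall-clock default)")
  structure(
    list(age_cutoff = age_cutoff, alpha = alpha, threshold = threshold,
         k_min = k_min, k_max = k_max, k_younger = k_younger,
         k_older = k_older, epsilon = epsilon, n_starts = n_starts,
         seed = as.integer(seed), min_shared = min_shared, top_k = top_k,
         labels = labels),
    class = "pipeline_config"
  )
}

#' Run the full two-group symptom cluster analysis
#'
#' End-to-end orchestration: split the sample by age, compare the groups
#' descriptively, rank the top symptoms, estimate a tetrachoric matrix per
#' group, fit the configured range of factor solutions, extract clusters
#' from the chosen per-group solution, and classify cluster stability and
#' consistency. All artifacts are written to `out_dir` at full precision
#' (rounding is a rendering concern): `descriptives.tsv`, `rankings.json`,
#' `loadings_<group>.tsv`, `phi_<group>.tsv`, `diagnostics.json`,
#' `stability_report.json`, and `run_log.json`. Runs are deterministic given
#' the config, so a rerun reproduces every artifact byte for byte.
#'
#' @param data A symptom dataset tibble.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `split`,
#'   `descriptives`, `rankings`, `tetrachoric`, `solutions`, `clusters`,
#'   `report`, `out_dir`.
#' @export
run_symptom_pipeline <- function(data, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  split <- stage("split", split_by_age(data, cutoff = config$age_cutoff))
  desc <- stage("descriptives", compare_groups(split, alpha = config$alpha))
  rankings <- stage("rankings", {
    ry <- occurrence_rates(split$younger)
    ro <- occurrence_rates(split$older)
    list(
      occurrence_younger = rank_top_symptoms(
        dplyr::select(ry, "code", value = "rate"), k = config$top_k),
      occurrence_older = rank_top_symptoms(
        dplyr::select(ro, "code", value = "rate"), k = config$top_k)
    )
  })
  groups <- c("younger", "older")
  tetra <- stage("tetrachoric", purrr::map(
    stats::setNames(groups, groups), ~tetrachoric_matrix(split[[.x]])
  ))
  sols <- stage("efa", purrr::map(stats::setNames(groups, groups), function(g) {
    fit_solutions(tetra[[g]]$rho, k_min = config$k_min, k_max = config$k_max,
                  threshold = config$threshold, epsilon = config$epsilon,
                  n_starts = config$n_starts, seed = config$seed)
  }))
  clusters <- stage("clusters", purrr::map(
    stats::setNames(groups, groups), function(g) {
      k <- if (g == "younger") config$k_younger else config$k_older
      extract_clusters(sols[[g]]$solutions[[paste0("k", k)]],
                       threshold = config$threshold, group = g,
                       labels = config$labels)
    }
  ))
  report <- stage("compare", compare_cluster_sets(
    clusters$younger, clusters$older, min_shared = config$min_shared
  ))

  write_json <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  readr::write_tsv(desc, file.path(out_dir, "descriptives.tsv"))
  write_json(purrr::map(rankings, ~.x), "rankings.json")
  for (g in groups) {
    k <- if (g == "younger") config$k_younger else config$k_older
    sol <- sols[[g]]$solutions[[paste0("k", k)]]
    write_loading_table(sol$loadings, file.path(out_dir, paste0("loadings_", g, ".tsv")))
    phi_tbl <- tibble::as_tibble(sol$phi, .name_repair = "minimal")
    readr::write_tsv(phi_tbl, file.path(out_dir, paste0("phi_", g, ".tsv")))
  }
  write_json(purrr::map(sols, "diagnostics"), "diagnostics.json")
  write_json(list(
    pairs = dplyr::select(report$pairs, -"shared", -"top_a", -"top_b"),
    shared = purrr::map(report$pairs$shared, ~.x),
    top_a = purrr::map(report$pairs$top_a, ~.x),
    top_b = purrr::map(report$pairs$top_b, ~.x),
    unmatched_a = report$unmatched_a,
    unmatched_b = report$unmatched_b,
    summary = report$summary
  ), "stability_report.json")
  write_json(list(
    package_version = as.character(utils::packageVersion("symclust")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_records = nrow(data),
    n_younger = nrow(split$younger),
    n_older = nrow(split$older),
    n_significant_occurrence = attr(desc, "n_significant_occurrence"),
    config = unclass(config)
  ), "run_log.json")

  invisible(list(split = split, descriptives = desc, rankings = rankings,
                 tetrachoric = tetra, solutions = sols, clusters = clusters,
                 report = report, out_dir = out_dir))
}

#' Render a run directory as a markdown summary
#'
#' Produces a human-readable markdown report from the artifacts of a
#' completed [run_symptom_pipeline()] run: sample sizes, the significant
#' descriptive comparisons, and one block per matched cluster pair with its
#' stability flag and consistency verdict.
#'
#' @param out_dir A run directory.
#' @param file Optional path to also write the report to.
#' @return The markdown text, invisibly a character scalar.
#' @export
render_report <- function(out_dir, file = NULL) {
  need <- function(f) {
    path <- file.path(out_dir, f)
    if (!file.exists(path)) stop("missing artifact: ", f)
    path
  }
  log <- jsonlite::read_json(need("run_log.json"), simplifyVector = TRUE)
  rep <- jsonlite::read_json(need("stability_report.json"),
                             simplifyVector = TRUE)
  desc <- readr::read_tsv(need("descriptives.tsv"),
                          show_col_types = FALSE)
  lines <- c(
    "# Symptom cluster comparison",
    "",
    sprintf("Sample: %d records (%d younger, %d older; cutoff %s years).",
            log$n_records, log$n_younger, log$n_older,
            log$config$age_cutoff),
    sprintf("Symptoms with occurrence differing at alpha = %s: %d of %d.",
            log$config$alpha, log$n_significant_occurrence, nrow(desc)),
    "",
    sprintf("## Matched clusters (%d stable, %d consistent, %d not consistent)",
            rep$summary$n_stable, rep$summary$n_consistent,
            rep$summary$n_inconsistent),
    ""
  )
  pairs <- rep$pairs
  for (i in seq_len(nrow(pairs))) {
    lines <- c(lines, sprintf(
      "- **%s / %s**: %d shared symptom(s) [%s], %s, consistency %s%s",
      pairs$cluster_a[i], pairs$cluster_b[i], pairs$n_shared[i],
      paste(unlist(rep$shared[[i]]), collapse = ", "),
      if (isTRUE(pairs$stable[i])) "stable" else "not stable",
      pairs$verdict[i],
      if (isTRUE(pairs$consistent[i])) "" else " — **not consistent**"
    ))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(text, file)
  invisible(text)
}
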