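#' Tidy a factor solution
#'
#' @param x A `"factor_solution"`.
#' @param ... Unused.
#' @return A long tibble: `code`, `factor`, `loading` (rotated),
#'   `communality`.
#' @export
tidy.factor_solution <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    code = rep(rownames(L), ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L),
    communality = rep(unname(x$communalities), ncol(L))
  )
}

#' Glance at a factor solution
#'
#' @param x A `"factor_solution"`.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics.
#' @export
glance.factor_solution <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    residual_rmsr = x$residual_rmsr,
    criterion = x$criterion,
    n_starts_agreeing = x$n_starts_agreeing,
    n_heywood = length(x$heywood),
    converged = x$converged
  )
}

#' Tidy a tetrachoric matrix estimate
#'
#' @param x A `"tetrachoric_matrix"`.
#' @param ... Unused.
#' @return A tibble of the lower-triangle pairs: `item_row`, `item_col`,
#'   `rho`.
#' @export
tidy.tetrachoric_matrix <- function(x, ...) {
  m <- x$rho
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    item_row = rownames(m)[idx[, 1]],
    item_col = colnames(m)[idx[, 2]],
    rho = m[idx]
  )
}

#' Tidy a stability report
#'
#' @param x A `"stability_report"`.
#' @param ... Unused.
#' @return The per-pair tibble without the list columns.
#' @export
tidy.stability_report <- function(x, ...) {
  dplyr::select(x$pairs, -"shared", -"top_a", -"top_b")
}

#' Glance at a stability report
#'
#' @param x A `"stability_report"`.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
glance.stability_report <- function(x, ...) {
  x$summary
}

#' Loading heatmap of a factor solution
#'
#' Tile plot of the rotated loadings, items on the y axis in catalog order,
#' with the cluster-membership threshold marked by tile outlines.
#'
#' @param object A `"factor_solution"`.
#' @param threshold |loading| at which tiles are outlined.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.factor_solution <- function(object, threshold = 0.40, ...) {
  df <- tidy(object)
  df$code <- factor(df$code, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$code,
                                   fill = .data$loading)) +
    ggplot2::geom_tile(
      colour = ifelse(abs(df$loading) >= threshold, "black", NA)
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1) *
                                    max(1, max(abs(df$loading)))) +
    ggplot2::labs(x = "Factor", y = NULL, fill = "Loading") +
    ggplot2::theme_minimal()
}

#' Side-by-side cluster loading plot for a stability report
#'
#' Dot plot of the member loadings of each matched cluster pair, one facet
#' per pair, colored by group, so consistency of the top loadings is visible
#' at a glance.
#'
#' @param report A `"stability_report"`.
#' @param set_a,set_b The `"cluster_set"` objects the report was built from.
#' @return A ggplot.
#' @export
plot_cluster_comparison <- function(report, set_a, set_b) {
  ga <- set_a$group %||% "group A"
  gb <- set_b$group %||% "group B"
  rows <- purrr::pmap(
    dplyr::select(report$pairs, "cluster_a", "cluster_b"),
    function(cluster_a, cluster_b) {
      dplyr::bind_rows(
        dplyr::mutate(
          dplyr::filter(set_a$clusters, .data$cluster == cluster_a),
          group = ga, pair = paste(cluster_a, "/", cluster_b)),
        dplyr::mutate(
          dplyr::filter(set_b$clusters, .data$cluster == cluster_b),
          group = gb, pair = paste(cluster_a, "/", cluster_b))
      )
    }
  ) |> dplyr::bind_rows()
  ggplot2::ggplot(rows, ggplot2::aes(x = abs(.data$loading), y = .data$code,
                                     colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = set_a$threshold, linetype = 2) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "|loading|", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Occurrence-rate comparison plot
#'
#' Dumbbell-style plot of per-item occurrence rates in the two groups from
#' a [compare_groups()] table, items ordered by the first group's rate,
#' significant differences emphasized.
#'
#' @param comparison A tibble from [compare_groups()].
#' @param alpha Significance level used for emphasis.
#' @return A ggplot.
#' @export
plot_occurrence_comparison <- function(comparison, alpha = 0.05) {
  df <- comparison |>
    dplyr::mutate(code = stats::reorder(.data$code, .data$rate_younger),
                  significant = .data$fisher_p < alpha) |>
    tidyr::pivot_longer(c("rate_younger", "rate_older"),
                        names_to = "group", values_to = "rate",
                        names_prefix = "rate_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$code,
                                   colour = .data$group,
                                   alpha = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "Occurrence rate", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
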