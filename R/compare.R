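# Per-cluster list of member tibbles (ordered by member_rank) from a
# cluster_set.
cluster_list <- function(set) {
  stopifnot(inherits(set, "cluster_set"))
  cl <- split(set$clusters, set$clusters$cluster)
  purrr::map(cl, ~dplyr::arrange(.x, .data$member_rank))
}

#' Match clusters across two groups
#'
#' Pairs the clusters of two groups one-to-one so that the total number of
#' shared symptoms is maximal (exhaustive optimal assignment over the
#' overlap matrix; ties broken by the larger summed |loading| of the shared
#' symptoms on both sides, then by cluster order). When the sets have
#' different sizes, the leftover clusters are reported unmatched.
#'
#' @param set_a,set_b `"cluster_set"` objects (see [extract_clusters()]).
#' @return A tibble with one row per pair: `cluster_a`, `cluster_b`,
#'   `n_shared`, `shared` (list column of shared codes); unmatched clusters
#'   appear with `NA` on the other side.
#' @export
match_clusters <- function(set_a, set_b) {
  la <- cluster_list(set_a)
  lb <- cluster_list(set_b)
  stopifnot(length(la) > 0, length(lb) > 0)
  overlap <- matrix(0, length(la), length(lb),
                    dimnames = list(names(la), names(lb)))
  loadsum <- overlap
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      shared <- intersect(la[[i]]$code, lb[[j]]$code)
      overlap[i, j] <- length(shared)
      loadsum[i, j] <-
        sum(abs(la[[i]]$loading[la[[i]]$code %in% shared])) +
        sum(abs(lb[[j]]$loading[lb[[j]]$code %in% shared]))
    }
  }
  asg <- best_assignment(overlap, tiebreak = loadsum)
  rows <- purrr::map(seq_along(la), function(i) {
    j <- asg$assignment[i]
    if (is.na(j)) {
      return(tibble::tibble(cluster_a = names(la)[i], cluster_b = NA_character_,
                            n_shared = 0L, shared = list(character())))
    }
    shared <- intersect(la[[i]]$code, lb[[j]]$code)
    tibble::tibble(cluster_a = names(la)[i], cluster_b = names(lb)[j],
                   n_shared = length(shared), shared = list(shared))
  })
  out <- dplyr::bind_rows(rows)
  leftover_b <- setdiff(names(lb), out$cluster_b)
  if (length(leftover_b) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      cluster_a = NA_character_, cluster_b = leftover_b,
      n_shared = 0L, shared = purrr::map(leftover_b, ~character())
    ))
  }
  out
}

#' Stability of a matched cluster pair
#'
#' A matched pair is called stable when the two clusters share at least
#' `min_shared` at-threshold symptoms -- the default 2 being the minimum
#' number of symptoms that defines a cluster at all. A pair with a missing
#' side is not stable.
#'
#' @param n_shared Number of shared symptoms (or a row of
#'   [match_clusters()] output via the other arguments).
#' @param both_present Are both sides of the pair present?
#' @param min_shared Minimum shared symptoms for stability.
#' @return Logical.
#' @export
is_stable <- function(n_shared, both_present = TRUE, min_shared = 2) {
  both_present & n_shared >= min_shared
}

#' Size of the top set used by the consistency rule
#'
#' Clusters totalling two or three symptoms (judged by the larger of the
#' two matched clusters) are compared on their top two loadings; clusters of
#' four or more on their top three.
#'
#' @param size_a,size_b Member counts of the matched clusters (each >= 2).
#' @return 2 or 3.
#' @export
consistency_k <- function(size_a, size_b) {
  stopifnot(size_a >= 2, size_b >= 2)
  ifelse(pmax(size_a, size_b) <= 3, 2L, 3L)
}

#' Top-k consistency of a matched cluster pair
#'
#' Applies the shared-top-symptom rule: with k from [consistency_k()], the
#' pair is consistent when the k symptoms with the highest |loading| are the
#' same set on both sides (shared count = k). Ties at the k-th loading
#' expand the top set and flag the verdict. The verdict is symmetric in the
#' two clusters.
#'
#' @param cluster_a,cluster_b Member tibbles ordered by |loading| descending
#'   (columns `code`, `loading`), e.g. from [cluster_list()] internals or a
#'   [match_clusters()] join.
#' @return A tibble: `k`, `shared_top`, `consistent`, `tie_affected`,
#'   `top_a`, `top_b` (list columns of the top sets).
#' @export
assess_consistency <- function(cluster_a, cluster_b) {
  size_a <- nrow(cluster_a)
  size_b <- nrow(cluster_b)
  k <- consistency_k(size_a, size_b)
  top_set <- function(cl) {
    kk <- min(k, nrow(cl))
    absv <- abs(cl$loading)
    cut <- sort(absv, decreasing = TRUE)[kk]
    sel <- which(absv >= cut - 1e-12)
    list(codes = cl$code[sel], tie = length(sel) > kk)
  }
  ta <- top_set(cluster_a)
  tb <- top_set(cluster_b)
  shared_top <- length(intersect(ta$codes, tb$codes))
  tibble::tibble(
    k = k,
    shared_top = shared_top,
    consistent = shared_top >= k,
    tie_affected = ta$tie || tb$tie,
    top_a = list(ta$codes),
    top_b = list(tb$codes)
  )
}

#' Compare two cluster sets: stability and consistency report
#'
#' End-to-end comparator: matches the clusters of the two groups
#' ([match_clusters()]), flags each matched pair as stable or not
#' ([is_stable()]) and applies the top-k consistency rule
#' ([assess_consistency()]).
#'
#' @param set_a,set_b `"cluster_set"` objects.
#' @param min_shared Stability threshold (shared symptoms).
#' @return An object of class `"stability_report"`: `pairs` (tibble with
#'   one row per matched pair: sizes, shared symptoms, `stable`, `k`,
#'   `shared_top`, `verdict` such as `"2/3"`, `consistent`, `tie_affected`,
#'   top sets), `unmatched_a`, `unmatched_b`, `summary` (tibble with
#'   `n_pairs`, `n_stable`, `n_consistent`, `n_inconsistent`).
#' @export
compare_cluster_sets <- function(set_a, set_b, min_shared = 2) {
  matches <- match_clusters(set_a, set_b)
  la <- cluster_list(set_a)
  lb <- cluster_list(set_b)
  matched <- dplyr::filter(matches, !is.na(.data$cluster_a) &
                             !is.na(.data$cluster_b))
  pairs <- purrr::pmap(matched, function(cluster_a, cluster_b, n_shared, shared) {
    ca <- la[[cluster_a]]
    cb <- lb[[cluster_b]]
    vd <- assess_consistency(ca, cb)
    tibble::tibble(
      cluster_a = cluster_a, cluster_b = cluster_b,
      size_a = nrow(ca), size_b = nrow(cb),
      n_shared = n_shared, shared = list(shared),
      stable = is_stable(n_shared, TRUE, min_shared),
      k = vd$k, shared_top = vd$shared_top,
      verdict = paste0(vd$shared_top, "/", vd$k),
      consistent = vd$consistent,
      tie_affected = vd$tie_affected,
      top_a = vd$top_a, top_b = vd$top_b
    )
  }) |> dplyr::bind_rows()
  structure(
    list(
      pairs = pairs,
      unmatched_a = matches$cluster_a[is.na(matches$cluster_b)],
      unmatched_b = matches$cluster_b[is.na(matches$cluster_a)],
      summary = tibble::tibble(
        n_pairs = nrow(pairs),
        n_stable = sum(pairs$stable),
        n_consistent = sum(pairs$consistent),
        n_inconsistent = sum(!pairs$consistent)
      ),
      min_shared = min_shared,
      groups = c(set_a$group, set_b$group)
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  s <- x$summary
  cat("Stability report: ", s$n_pairs, " matched pair(s), ",
      s$n_stable, " stable, ", s$n_consistent, " consistent, ",
      s$n_inconsistent, " not consistent\n", sep = "")
  cat("(stability = matched clusters sharing >= ", x$min_shared,
      " at-threshold symptoms)\n", sep = "")
  for (i in seq_len(nrow(x$pairs))) {
    r <- x$pairs[i, ]
    cat(sprintf("  %-18s ~ %-18s shared %d, %s, consistency %s%s\n",
                r$cluster_a, r$cluster_b, r$n_shared,
                if (r$stable) "stable" else "NOT stable", r$verdict,
                if (r$consistent) "" else " (not consistent)"))
  }
  if (length(x$unmatched_a) > 0) {
    cat("  unmatched in group A:", paste(x$unmatched_a, collapse = ", "), "\n")
  }
  if (length(x$unmatched_b) > 0) {
    cat("  unmatched in group B:", paste(x$unmatched_b, collapse = ", "), "\n")
  }
  invisible(x)
}
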