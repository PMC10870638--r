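#' Unweighted least squares factor extraction
#'
#' Minimizes the sum of squared off-diagonal residuals between the
#' correlation matrix and the model-implied `L %*% t(L)` by iterated
#' principal axis: communalities are seeded from squared multiple
#' correlations, the reduced matrix is eigen-decomposed, the top-k
#' components give the loadings, communalities are updated from them, and
#' the cycle repeats until the largest communality change is below `tol`.
#' Both half-steps are exact minimizers (Eckart-Young for the loadings,
#' diagonal replacement for the uniquenesses), so the objective descends
#' monotonically; its trajectory is returned. Communalities are capped at 1
#' and the affected items flagged as Heywood cases.
#'
#' @param R Correlation matrix: symmetric, unit diagonal, PSD after repair.
#' @param k Number of factors, `1 <= k < ncol(R)`.
#' @param tol Convergence tolerance on the max communality change.
#' @param max_iter Iteration cap; non-convergence is reported, not an error.
#' @return A list: `loadings` (unrotated, items x k), `communalities`,
#'   `residual_rmsr` (root-mean-square off-diagonal residual), `converged`,
#'   `iterations`, `heywood` (codes of capped items), `objective_trace`.
#' @export
uls_extract <- function(R, k, tol = 1e-6, max_iter = 1000) {
  p <- ncol(R)
  stopifnot(k >= 1, k < p, isTRUE(all.equal(R, t(R))),
            isTRUE(all.equal(unname(diag(R)), rep(1, p))))
  codes <- colnames(R) %||% paste0("item", seq_len(p))
  # squared multiple correlations; ridge keeps near-singular repairs usable
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) 1 - 1 / diag(solve(R + diag(1e-6, p))))
  h2 <- pmin(pmax(smc, 0), 1)
  off <- !diag(TRUE, p)
  objective <- function(L, h) {
    Rm <- tcrossprod(L)
    sum((R[off] - Rm[off])^2)
  }
  trace <- numeric(0)
  converged <- FALSE
  L <- NULL
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
    h2_new <- pmin(rowSums(L^2), 1)
    trace <- c(trace, objective(L, h2_new))
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  heywood <- codes[rowSums(L^2) >= 1 - 1e-10]
  resid <- R - tcrossprod(L)
  rownames(L) <- codes
  colnames(L) <- paste0("F", seq_len(k))
  list(
    loadings = L,
    communalities = stats::setNames(h2, codes),
    residual_rmsr = sqrt(mean(resid[off]^2)),
    converged = converged,
    iterations = iter,
    heywood = heywood,
    objective_trace = trace
  )
}

# Geomin criterion and its gradient at loadings L:
# Q = sum_i (prod_j (L_ij^2 + eps))^(1/k)
geomin_vgq <- function(L, eps) {
  k <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / k)
  list(f = sum(pro), Gq = (2 / k) * (L / L2) * pro)
}

# Gradient-projection oblique rotation (Jennrich's GP algorithm) of A by the
# geomin criterion, from oblique rotation matrix start Tmat (unit columns).
gp_oblique_geomin <- function(A, Tmat, eps, max_iter = 1000, tol = 1e-6) {
  Ti <- Tmat
  al <- 1
  Tinv <- solve(Ti)
  L <- A %*% t(Tinv)
  vg <- geomin_vgq(L, eps)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Tinv)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Ti %*% diag(colSums(Ti * G), ncol(Ti))
    s <- sqrt(sum(Gp^2))
    if (s < tol) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in seq_len(30)) {
      X <- Ti - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Tinv_t <- solve(Tt)
      Lt <- A %*% t(Tinv_t)
      vgt <- geomin_vgq(Lt, eps)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Ti <- Tt
    Tinv <- Tinv_t
    L <- Lt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Tinv)
  }
  list(loadings = L, phi = crossprod(Ti), f = f, converged = converged,
       iterations = iter)
}

#' Geomin oblique rotation
#'
#' Rotates an unrotated loading matrix to minimize the geomin criterion
#' `sum_i (prod_j (lambda_ij^2 + epsilon))^(1/k)` over oblique rotations by
#' gradient projection. Geomin is multi-modal, so the optimization is run
#' from `n_starts` random orthonormal starts (plus the identity) and the
#' best criterion value kept; the number of starts whose converged criterion
#' agrees with the best within 1e-5 is reported as a local-minimum
#' diagnostic. Each factor's sign is fixed so its largest-magnitude loading
#' is positive. Rotated loadings are regression coefficients on correlated
#' factors and may legitimately exceed 1.
#'
#' @param unrotated Items-by-factors unrotated loading matrix.
#' @param epsilon Geomin smoothing constant (default 0.01, the convention
#'   for instruments of this length).
#' @param n_starts Number of random starts (default 30).
#' @param seed Integer seed controlling the random starts.
#' @return A list: `loadings` (rotated), `phi` (factor correlations),
#'   `criterion`, `n_starts_agreeing`, `converged`.
#' @export
geomin_rotate <- function(unrotated, epsilon = 0.01, n_starts = 30, seed = 1) {
  A <- as.matrix(unrotated)
  k <- ncol(A)
  if (k == 1) {
    return(list(loadings = A, phi = matrix(1, 1, 1), criterion = NA_real_,
                n_starts_agreeing = NA_integer_, converged = TRUE))
  }
  starts <- withr::with_seed(seed, {
    c(list(diag(k)), purrr::map(seq_len(n_starts), function(i) {
      qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    }))
  })
  fits <- purrr::map(starts, ~gp_oblique_geomin(A, .x, eps = epsilon))
  fs <- purrr::map_dbl(fits, "f")
  best <- fits[[which.min(fs)]]
  L <- best$loadings
  phi <- best$phi
  # sign convention: largest-|loading| entry of each factor positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      phi[j, ] <- -phi[j, ]
      phi[, j] <- -phi[, j]
    }
  }
  rownames(L) <- rownames(A)
  colnames(L) <- colnames(A)
  dimnames(phi) <- list(colnames(A), colnames(A))
  list(
    loadings = L, phi = phi, criterion = best$f,
    n_starts_agreeing = sum(fs <= min(fs) + 1e-5),
    converged = best$converged
  )
}

#' Fit one exploratory factor solution
#'
#' ULS extraction ([uls_extract()]) followed by geomin rotation
#' ([geomin_rotate()]) of a correlation matrix for a fixed factor count.
#'
#' @param R Correlation matrix (e.g. `tetrachoric_matrix(...)$rho`).
#' @param k Number of factors.
#' @param epsilon,n_starts,seed Passed to [geomin_rotate()].
#' @param ... Passed to [uls_extract()].
#' @return An object of class `"factor_solution"`: fields `n_factors`,
#'   `unrotated`, `loadings` (rotated), `phi`, `communalities`,
#'   `residual_rmsr`, `converged`, `criterion`, `n_starts_agreeing`,
#'   `heywood`, `objective_trace`.
#' @export
fit_efa <- function(R, k, epsilon = 0.01, n_starts = 30, seed = 1, ...) {
  if (inherits(R, "tetrachoric_matrix")) R <- R$rho
  ext <- uls_extract(R, k, ...)
  rot <- geomin_rotate(ext$loadings, epsilon = epsilon,
                       n_starts = n_starts, seed = seed)
  structure(
    list(
      n_factors = k,
      unrotated = ext$loadings,
      loadings = rot$loadings,
      phi = rot$phi,
      communalities = ext$communalities,
      residual_rmsr = ext$residual_rmsr,
      converged = ext$converged && rot$converged,
      criterion = rot$criterion,
      n_starts_agreeing = rot$n_starts_agreeing,
      heywood = ext$heywood,
      objective_trace = ext$objective_trace
    ),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("Factor solution: ", x$n_factors, " factors, RMSR ",
      signif(x$residual_rmsr, 3),
      if (!x$converged) " (NOT converged)" else "",
      if (length(x$heywood) > 0) {
        paste0(", Heywood: ", paste(x$heywood, collapse = ", "))
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Fit a range of factor solutions with diagnostics
#'
#' Fits one solution per factor count from `k_min` to `k_max` and tabulates
#' the diagnostics on which a factor count is chosen by inspection:
#' residual RMSR, number of adequately defined factors (at least two
#' members at the loading threshold), number of unassigned items, and
#' Heywood count. The substantive selection ("greatest interpretability")
#' is a human judgement; the table makes it explicit.
#'
#' @param R Correlation matrix or `"tetrachoric_matrix"`.
#' @param k_min,k_max Factor-count range (defaults 2 and 8).
#' @param threshold Loading threshold for the adequacy count.
#' @param ... Passed to [fit_efa()].
#' @return A list: `solutions` (named list of `"factor_solution"`),
#'   `diagnostics` (tibble, one row per k).
#' @export
fit_solutions <- function(R, k_min = 2, k_max = 8, threshold = 0.40, ...) {
  if (inherits(R, "tetrachoric_matrix")) R <- R$rho
  stopifnot(k_min >= 1, k_max < ncol(R), k_min <= k_max)
  ks <- seq(k_min, k_max)
  solutions <- purrr::map(ks, ~fit_efa(R, .x, ...))
  names(solutions) <- paste0("k", ks)
  diagnostics <- purrr::map2(solutions, ks, function(sol, k) {
    cs <- extract_clusters(sol, threshold = threshold)
    tibble::tibble(
      k = k,
      residual_rmsr = sol$residual_rmsr,
      n_adequate_factors = length(unique(cs$clusters$cluster)),
      n_unassigned = length(cs$unassigned),
      n_heywood = length(sol$heywood),
      converged = sol$converged,
      n_starts_agreeing = sol$n_starts_agreeing
    )
  }) |> dplyr::bind_rows()
  list(solutions = solutions, diagnostics = diagnostics)
}

#' Extract symptom clusters from a rotated solution
#'
#' A symptom belongs to a factor's cluster when the magnitude of its rotated
#' loading meets the threshold (inclusive; 0.40 by convention). Members are
#' ordered by |loading| descending, ties broken by catalog order (and
#' flagged). Symptoms may cross-load into several clusters. Factors with
#' fewer than two members are not adequately defined: they are dropped and
#' their items counted as unassigned unless captured by another cluster.
#'
#' @param solution A `"factor_solution"` from [fit_efa()], or a rotated
#'   items-by-factors loading matrix with item codes as row names.
#' @param threshold Minimum |loading| for cluster membership.
#' @param group Optional group tag carried into the result.
#' @param labels Optional named vector mapping factor column names to
#'   display labels for the clusters.
#' @return An object of class `"cluster_set"`: `clusters` (tibble with
#'   `cluster`, `code`, `loading`, `member_rank`, `tie_flag`), `unassigned`
#'   (character), `group`, `threshold`, `n_factors_dropped`.
#' @export
extract_clusters <- function(solution, threshold = 0.40, group = NA_character_,
                             labels = NULL) {
  L <- if (inherits(solution, "factor_solution")) solution$loadings
       else as.matrix(solution)
  stopifnot(threshold > 0)
  codes <- rownames(L) %||% paste0("item", seq_len(nrow(L)))
  factor_names <- colnames(L) %||% paste0("F", seq_len(ncol(L)))
  clusters <- purrr::map(seq_len(ncol(L)), function(j) {
    lo <- L[, j]
    keep <- which(abs(lo) >= threshold)
    if (length(keep) < 2) return(NULL)
    ord <- keep[order(-abs(lo[keep]), keep)]
    absv <- abs(lo[ord])
    tie <- duplicated(absv) | duplicated(absv, fromLast = TRUE)
    lbl <- factor_names[j]
    if (!is.null(labels) && lbl %in% names(labels)) lbl <- labels[[lbl]]
    tibble::tibble(
      cluster = lbl,
      code = codes[ord],
      loading = unname(lo[ord]),
      member_rank = seq_along(ord),
      tie_flag = tie
    )
  })
  dropped <- sum(purrr::map_lgl(clusters, is.null)) -
    sum(colSums(abs(L) >= threshold) == 0)
  clusters <- dplyr::bind_rows(clusters)
  if (nrow(clusters) == 0) {
    clusters <- tibble::tibble(
      cluster = character(), code = character(), loading = double(),
      member_rank = integer(), tie_flag = logical()
    )
  }
  assigned <- unique(clusters$code)
  structure(
    list(
      clusters = clusters,
      unassigned = setdiff(codes, assigned),
      group = group,
      threshold = threshold,
      n_factors_dropped = max(dropped, 0L)
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cl <- split(x$clusters, x$clusters$cluster)
  cat("Cluster set", if (!is.na(x$group)) paste0(" (", x$group, ")"),
      ": ", length(cl), " cluster(s) at |loading| >= ", x$threshold,
      ", ", length(x$unassigned), " unassigned item(s)\n", sep = "")
  for (nm in names(cl)) {
    cat("  ", nm, ": ",
        paste0(cl[[nm]]$code, " (", sprintf("%.3f", cl[[nm]]$loading), ")",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
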