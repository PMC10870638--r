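# Gauss-Legendre nodes on [0, 1], cached per session. 96 nodes give the
# tetrachoric integral well beyond 1e-7 absolute accuracy over |rho| < 1.
gl_nodes <- local({
  cache <- NULL
  function(n = 96) {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(n, 0, 1)
    cache
  }
})

#' Upper tail of the standard bivariate normal
#'
#' `P(X > h, Y > k)` for standard bivariate normal `(X, Y)` with correlation
#' `rho`, by Gauss-Legendre quadrature of the tetrachoric integral
#' `P = Phi(-h) Phi(-k) + (1/2pi) * int_0^asin(rho) exp(-(h^2 - 2hk sin t
#' + k^2) / (2 cos^2 t)) dt`, whose integrand is smooth and bounded for all
#' `|rho| < 1` (absolute accuracy well below 1e-7). Vectorized over `rho`.
#' The degenerate limits `rho = +/-1` are handled analytically.
#'
#' @param h,k Scalar thresholds.
#' @param rho Correlation(s) in \[-1, 1\].
#' @return Probability vector, same length as `rho`.
#' @export
#' @examples
#' pbvn_upper(0, 0, 0.5) # 1/4 + asin(0.5)/(2*pi) = 1/3
pbvn_upper <- function(h, k, rho) {
  stopifnot(length(h) == 1, length(k) == 1, all(abs(rho) <= 1))
  out <- numeric(length(rho))
  hi <- rho >= 1
  lo <- rho <= -1
  mid <- !hi & !lo
  if (any(hi)) out[hi] <- stats::pnorm(max(h, k), lower.tail = FALSE)
  if (any(lo)) out[lo] <- max(0, stats::pnorm(-k) - stats::pnorm(h))
  if (any(mid)) {
    gl <- gl_nodes()
    a <- asin(rho[mid]) # integral endpoint per rho
    theta <- outer(a, gl$x) # n_rho x n_nodes
    s <- sin(theta)
    c2 <- 1 - s^2
    integrand <- exp(-(h^2 - 2 * h * k * s + k^2) / (2 * c2))
    out[mid] <- stats::pnorm(-h) * stats::pnorm(-k) +
      a * as.vector(integrand %*% gl$w) / (2 * pi)
  }
  out
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum-likelihood tetrachoric estimate: the two thresholds are
#' fixed at normal quantiles of the table margins, then the latent
#' correlation maximizes the multinomial log-likelihood of the four cells
#' under the bivariate-normal threshold model, by bracketed scalar search to
#' |delta rho| < 1e-6. If any cell is zero, 0.5 is added to all four cells
#' first and the correction recorded.
#'
#' @param n11,n10,n01,n00 Cell counts: joint presence, row-only, column-only,
#'   joint absence.
#' @return A tibble with `rho`, `tau_row`, `tau_col`, `corrected` (logical),
#'   `loglik`.
#' @export
#' @examples
#' tetrachoric_from_table(25, 25, 25, 25)$rho # 0
tetrachoric_from_table <- function(n11, n10, n01, n00) {
  counts <- c(n11, n10, n01, n00)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  n <- sum(counts)
  p_row <- (counts[1] + counts[2]) / n
  p_col <- (counts[1] + counts[3]) / n
  if (p_row %in% c(0, 1) || p_col %in% c(0, 1)) {
    warning("degenerate margin even after correction; estimate undefined")
    return(tibble::tibble(rho = NA_real_, tau_row = NA_real_,
                          tau_col = NA_real_, corrected = corrected,
                          loglik = NA_real_))
  }
  tau_row <- stats::qnorm(1 - p_row)
  tau_col <- stats::qnorm(1 - p_col)
  negll <- function(rho) -tetrachoric_loglik(counts, tau_row, tau_col, rho)
  opt <- stats::optimize(negll, interval = c(-0.9999, 0.9999), tol = 1e-7)
  tibble::tibble(rho = opt$minimum, tau_row = tau_row, tau_col = tau_col,
                 corrected = corrected, loglik = -opt$objective)
}

# Multinomial log-likelihood of a 2x2 table under the bivariate-normal
# threshold model with fixed thresholds. Vectorized over rho.
tetrachoric_loglik <- function(counts, tau_row, tau_col, rho) {
  p11 <- pbvn_upper(tau_row, tau_col, rho)
  p1. <- stats::pnorm(-tau_row)
  p.1 <- stats::pnorm(-tau_col)
  p10 <- p1. - p11
  p01 <- p.1 - p11
  p00 <- 1 - p1. - p01
  eps <- 1e-12
  counts[1] * log(pmax(p11, eps)) + counts[2] * log(pmax(p10, eps)) +
    counts[3] * log(pmax(p01, eps)) + counts[4] * log(pmax(p00, eps))
}

#' Tetrachoric correlation matrix of a symptom dataset
#'
#' Estimates all pairwise tetrachoric correlations of the binary occurrence
#' items (the "matrix of associations" feeding the factor analysis), using
#' pairwise-complete observations, then symmetrizes and, if the pairwise
#' estimates yield an indefinite matrix, repairs it with [nearest_psd()].
#'
#' @param data A symptom dataset tibble (or a 0/1/NA matrix with item codes
#'   as column names).
#' @return A list of class `"tetrachoric_matrix"`: `rho` (the matrix),
#'   `corrections` (tibble of pairs where a zero-cell correction applied),
#'   `psd_adjusted`, `min_eigenvalue_before`, `frobenius_distance`.
#' @export
tetrachoric_matrix <- function(data) {
  m <- if (is.matrix(data)) data else occurrence_matrix(data)
  p <- ncol(m)
  stopifnot(p >= 2)
  codes <- colnames(m) %||% paste0("item", seq_len(p))
  pres <- (m == 1L) * 1
  abse <- (m == 0L) * 1
  pres[is.na(m)] <- 0
  abse[is.na(m)] <- 0
  N11 <- crossprod(pres)
  N10 <- crossprod(pres, abse)
  N00 <- crossprod(abse)
  rho <- diag(1, p)
  corrections <- list()
  undefined <- character()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      est <- suppressWarnings(
        tetrachoric_from_table(N11[i, j], N10[i, j], N10[j, i], N00[i, j])
      )
      if (is.na(est$rho)) {
        undefined <- c(undefined, paste0(codes[i], ":", codes[j]))
        next
      }
      rho[i, j] <- rho[j, i] <- est$rho
      if (est$corrected) {
        corrections[[length(corrections) + 1]] <-
          tibble::tibble(item_row = codes[i], item_col = codes[j])
      }
    }
  }
  if (length(undefined) > 0) {
    stop("tetrachoric undefined for pair(s): ",
         paste(undefined, collapse = ", "))
  }
  dimnames(rho) <- list(codes, codes)
  ev_min <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  psd_adjusted <- ev_min < -1e-8
  frob <- 0
  if (psd_adjusted) {
    fixed <- nearest_psd(rho)
    frob <- sqrt(sum((fixed - rho)^2))
    rho <- fixed
  }
  structure(
    list(
      rho = rho,
      corrections = dplyr::bind_rows(corrections),
      psd_adjusted = psd_adjusted,
      min_eigenvalue_before = ev_min,
      frobenius_distance = frob
    ),
    class = "tetrachoric_matrix"
  )
}

#' @export
print.tetrachoric_matrix <- function(x, ...) {
  cat("Tetrachoric correlation matrix: ", ncol(x$rho), " items, ",
      nrow(x$corrections), " zero-cell correction(s), ",
      if (x$psd_adjusted) {
        paste0("PSD-repaired (min eigenvalue was ",
               signif(x$min_eigenvalue_before, 3), ")")
      } else "already PSD", "\n", sep = "")
  invisible(x)
}

#' Nearest positive semidefinite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below 1e-8 are raised to 1e-8, the
#' matrix is reassembled and rescaled to unit diagonal. Inputs that are
#' already PSD are returned unchanged (the repair is idempotent).
#'
#' @param m A symmetric matrix with unit diagonal.
#' @return A PSD correlation matrix.
#' @export
nearest_psd <- function(m) {
  stopifnot(isTRUE(all.equal(m, t(m))),
            isTRUE(all.equal(unname(diag(m)), rep(1, ncol(m)))))
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-8) return(m)
  vals <- pmax(e$values, 1e-8)
  out <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}
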