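#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# All permutations of 1..n as a list (n <= 9 guarded; used for optimal
# assignment over at most 8 clusters/factors).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

# Optimal one-to-one assignment maximizing sum(score[i, assignment[i]]) by
# exhaustive enumeration over permutations (at most 8 factors/clusters here).
# When nrow > ncol, unassigned rows get NA. `tiebreak` (same dim) resolves
# equal totals; remaining ties fall to enumeration order (first wins).
best_assignment <- function(score, tiebreak = NULL) {
  nr <- nrow(score)
  nc <- ncol(score)
  if (is.null(tiebreak)) tiebreak <- matrix(0, nr, nc)
  if (nr > nc) {
    sub <- best_assignment(t(score), t(tiebreak))
    assignment <- rep(NA_integer_, nr)
    assignment[sub$assignment] <- seq_len(nc)
    return(list(assignment = assignment, total = sub$total))
  }
  perms <- all_permutations(nc)
  best <- NULL
  best_total <- -Inf
  best_tb <- -Inf
  for (p in perms) {
    cols <- p[seq_len(nr)]
    total <- sum(score[cbind(seq_len(nr), cols)])
    if (total < best_total - 1e-12) next
    tb <- sum(tiebreak[cbind(seq_len(nr), cols)])
    if (total > best_total + 1e-12 ||
        (tb > best_tb + 1e-12 && total >= best_total - 1e-12)) {
      best_total <- max(total, best_total)
      best_tb <- tb
      best <- cols
    }
  }
  list(assignment = best, total = best_total)
}

#' Tucker congruence between loading columns
#'
#' The Tucker coefficient of congruence between two loading vectors is their
#' cosine similarity, `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`. Given two
#' loading matrices it returns the full column-by-column congruence matrix.
#'
#' @param x,y Numeric vectors or item-by-factor matrices with matching rows.
#' @return A scalar (vector input) or matrix of congruence coefficients.
#' @export
factor_congruence <- function(x, y) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  stopifnot(nrow(x) == nrow(y))
  cross <- crossprod(x, y)
  norm <- tcrossprod(sqrt(colSums(x^2)), sqrt(colSums(y^2)))
  out <- cross / norm
  if (length(out) == 1) out <- drop(out)
  out
}

#' Match factors of one loading matrix to another
#'
#' Finds the one-to-one column assignment (with sign flips) that maximizes
#' total absolute Tucker congruence between an estimated and a target
#' loading matrix -- the standard step before judging factor recovery, since
#' factor order and sign are arbitrary.
#'
#' @param estimated,target Item-by-factor matrices with equal row counts
#'   and `ncol(estimated) >= ncol(target)`.
#' @return A tibble with one row per target factor: `target_factor`,
#'   `matched_column`, `sign`, `congruence` (signed, after the flip).
#' @export
match_factors <- function(estimated, target) {
  cg <- factor_congruence(target, estimated) # targets x estimated
  if (is.vector(cg)) cg <- matrix(cg, nrow = ncol(target))
  asg <- best_assignment(abs(cg))
  cols <- asg$assignment
  sign_flip <- ifelse(cg[cbind(seq_len(ncol(target)), cols)] < 0, -1, 1)
  tibble::tibble(
    target_factor = colnames(target) %||% paste0("F", seq_len(ncol(target))),
    matched_column = cols,
    sign = sign_flip,
    congruence = cg[cbind(seq_len(ncol(target)), cols)] * sign_flip
  )
}
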