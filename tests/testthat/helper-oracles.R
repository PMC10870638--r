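# Independent oracles and fixture builders used across the suite.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # group-1 total
  n <- c + d          # group-2 total
  k <- a + c          # successes total
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (midranks; statistic = rank sum of x). Feasible for small samples only.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  ex <- nx * (length(pooled) + 1) / 2
  sets <- utils::combn(length(pooled), nx)
  stat <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(abs(stat - ex) >= abs(obs - ex) - 1e-9)
}

# Grid-search ML tetrachoric oracle: thresholds from margins, rho on a fixed
# grid over (-0.999, 0.999) at the given step.
oracle_tetrachoric_grid <- function(n11, n10, n01, n00, step = 1e-4) {
  counts <- c(n11, n10, n01, n00)
  if (any(counts == 0)) counts <- counts + 0.5
  n <- sum(counts)
  tau_r <- qnorm(1 - (counts[1] + counts[2]) / n)
  tau_c <- qnorm(1 - (counts[1] + counts[3]) / n)
  grid <- seq(-0.999, 0.999, by = step)
  p11 <- symclust::pbvn_upper(tau_r, tau_c, grid)
  p1. <- pnorm(-tau_r)
  p.1 <- pnorm(-tau_c)
  ll <- counts[1] * log(pmax(p11, 1e-12)) +
    counts[2] * log(pmax(p1. - p11, 1e-12)) +
    counts[3] * log(pmax(p.1 - p11, 1e-12)) +
    counts[4] * log(pmax(1 - p1. - p.1 + p11, 1e-12))
  grid[which.max(ll)]
}

# Tiny symptom dataset with the full column layout for a custom catalog.
toy_dataset <- function(occ, sev = NULL, dis = NULL, age = NULL,
                        codes = paste0("s", seq_len(ncol(occ)))) {
  n <- nrow(occ)
  if (is.null(age)) age <- rep(50, n)
  d <- tibble::tibble(patient_id = sprintf("t%03d", seq_len(n)), age = age)
  for (j in seq_along(codes)) {
    d[[paste0("occ_", codes[j])]] <- as.integer(occ[, j])
    s <- if (is.null(sev)) ifelse(occ[, j] == 1L, 1L, NA_integer_) else sev[, j]
    dd <- if (is.null(dis)) ifelse(occ[, j] == 1L, 0L, NA_integer_) else dis[, j]
    d[[paste0("sev_", codes[j])]] <- as.integer(s)
    d[[paste0("dis_", codes[j])]] <- as.integer(dd)
  }
  attr(d, "items") <- tibble::tibble(code = codes, label = codes,
                                     index = seq_along(codes))
  d
}

# Cluster set built directly from member/loading lists, for comparator tests.
toy_cluster_set <- function(members, group = NA_character_) {
  rows <- purrr::imap(members, function(m, nm) {
    tibble::tibble(
      cluster = nm,
      code = names(m),
      loading = unname(m),
      member_rank = seq_along(m),
      tie_flag = FALSE
    )
  })
  structure(
    list(clusters = dplyr::bind_rows(rows), unassigned = character(),
         group = group, threshold = 0.40, n_factors_dropped = 0L),
    class = "cluster_set"
  )
}

# Reconstruction of the published occurrence table as two binary datasets
# (counts = round(rate x n); the fixture convention for the worked examples).
reconstruct_occurrence_split <- function() {
  rates <- symclust::reference_occurrence_rates()
  build <- function(pct, n, age) {
    occ <- sapply(pct / 100, function(p) {
      k <- round(p * n)
      c(rep(1L, k), rep(0L, n - k))
    })
    colnames(occ) <- rates$code
    toy_dataset(occ, age = rep(age, n), codes = rates$code)
  }
  list(younger = build(rates$pct_younger, 741, 45),
       older = build(rates$pct_older, 602, 70))
}
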