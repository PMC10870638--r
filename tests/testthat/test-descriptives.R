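test_that("occurrence rates are present / (present + absent), missing excluded", {
  occ <- matrix(1L, 4, 3)
  d <- toy_dataset(occ)
  expect_equal(occurrence_rates(d)$rate, rep(1, 3))
  occ2 <- cbind(c(1L, 0L, NA, 1L), c(0L, 0L, 0L, 1L))
  d2 <- toy_dataset(occ2)
  expect_equal(occurrence_rates(d2)$rate, c(2 / 3, 1 / 4))
})

test_that("mean symptom count matches the sum-of-rates identity", {
  occ <- rbind(c(1L, 1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L))
  d <- toy_dataset(occ)
  expect_equal(mean_symptom_count(d)$mean, 4)
  cfg <- default_generating_model("older", n = 300)
  sim <- simulate_symptoms(cfg, seed = 31)
  expect_equal(mean_symptom_count(sim)$mean, sum(occurrence_rates(sim)$rate))
})

test_that("reconstructed published rates reproduce the published group means", {
  split <- reconstruct_occurrence_split()
  expect_equal(round(mean_symptom_count(split$younger)$mean, 1), 14.8)
  expect_equal(round(mean_symptom_count(split$older)$mean, 1), 12.9)
  ry <- occurrence_rates(split$younger)
  expect_equal(ry$rate[ry$code == "energy"], round(0.845 * 741) / 741)
})

test_that("Fisher's exact matches enumeration and its symmetries", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-7)
  tables <- withr::with_seed(7, replicate(
    20, rpois(4, lambda = sample(c(3, 10, 40), 1)) + 1, simplify = FALSE
  ))
  for (tb in tables) {
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, oracle_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-7)
    # invariant to simultaneous row and column swap
    expect_equal(p, fisher_exact_2x2(tb[4], tb[3], tb[2], tb[1]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins positive")
})

test_that("the vomiting occurrence reconstruction reproduces the printed p", {
  # reconstruction from rounded percentages recovers the published p-value
  # (computed from unrounded data) up to the rounding of the input rates
  a <- round(0.145 * 741)
  c_ <- round(0.097 * 602)
  expect_lt(abs(fisher_exact_2x2(a, 741 - a, c_, 602 - c_) - 0.009), 0.002)
})

test_that("Mann-Whitney U: statistic, approximation, and oracles agree", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  x <- c(1, 2, 2, 3, 4)
  expect_warning(res <- mann_whitney_u(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(res$p_value, 1)
  expect_gt(mann_whitney_u(x, x)$p_value, 0.95)

  # independently coded tie-corrected normal approximation with continuity
  # correction must agree to numerical precision
  mw_formula <- function(x, y) {
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- table(c(x, y))
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - nx * ny / 2) - 0.5) / sqrt(sigma2)
    2 * pnorm(-z)
  }
  xy <- withr::with_seed(8, list(x = sample(0:4, 200, TRUE),
                                 y = sample(0:4, 200, TRUE, prob = c(1, 1, 1, 2, 2))))
  got <- mann_whitney_u(xy$x, xy$y)
  expect_equal(got$p_value, mw_formula(xy$x, xy$y), tolerance = 1e-10)

  # exact-permutation oracle at tiny n bounds the approximation error
  # (the normal approximation is crude at n = 4 per group)
  sx <- c(1, 3, 3, 5)
  sy <- c(2, 2, 4, 6)
  expect_lt(abs(mann_whitney_u(sx, sy)$p_value - oracle_mw_exact_p(sx, sy)),
            0.1)
})

test_that("t tests: raw, summary-statistic, and published age row", {
  x <- withr::with_seed(3, rnorm(40))
  expect_equal(two_sample_t(x, x)$t, 0)
  expect_equal(two_sample_t(x, x)$p_value, 1)
  y <- withr::with_seed(4, rnorm(30, 0.4))
  raw <- two_sample_t(x, y)
  summ <- two_sample_t_summary(mean(x), sd(x), 40, mean(y), sd(y), 30)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  pooled <- two_sample_t(x, y, pooled = TRUE)
  expect_equal(pooled$df, 68)
  # published age comparison from summary statistics (Welch form)
  age <- two_sample_t_summary(48.4, 8.5, 741, 68.0, 6.2, 602)
  expect_equal(abs(age$t), 48.8, tolerance = 0.05)
  expect_lt(age$p_value, 0.001)
})

test_that("group comparison flags nothing when the groups are identical", {
  cfg <- default_generating_model("younger", n = 80)
  d <- simulate_symptoms(cfg, seed = 41)
  cg <- compare_groups(list(younger = d, older = d))
  expect_equal(attr(cg, "n_significant_occurrence"), 0)
  expect_true(all(cg$fisher_p > 1 - 1e-8))
  expect_equal(nrow(cg), 38)
})

test_that("reconstructed published table yields 18 significant occurrence items", {
  split <- reconstruct_occurrence_split()
  cg <- compare_groups(split)
  expect_equal(attr(cg, "n_significant_occurrence"), 18)
})

test_that("top-k ranking keeps ties and is label-equivariant", {
  v <- c(a = 5, b = 4, c = 3)
  expect_equal(rank_top_symptoms(v, k = 2)$code, c("a", "b"))

  rates <- reference_occurrence_rates()
  older <- rank_top_symptoms(
    tibble::tibble(code = rates$code, value = rates$pct_older), k = 10
  )
  expect_equal(nrow(older), 11)
  tied <- older$code[older$value == 45.6]
  expect_setequal(tied, c("concentration", "dry_mouth"))
  expect_equal(unique(older$rank[older$value == 45.6]), 9)

  younger <- rank_top_symptoms(
    tibble::tibble(code = rates$code, value = rates$pct_younger), k = 10
  )
  expect_equal(nrow(younger), 10)
  expect_length(intersect(younger$code, older$code), 8)
  expect_length(union(younger$code, older$code), 13)

  # permuting the items permutes only labels
  perm <- withr::with_seed(5, sample(nrow(rates)))
  rr <- rank_top_symptoms(
    tibble::tibble(code = rates$code[perm], value = rates$pct_older[perm]), k = 10
  )
  expect_setequal(rr$code, older$code)
  expect_equal(sort(rr$rank), sort(older$rank))
})
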