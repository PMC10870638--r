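test_that("ULS on an identity matrix finds no common variance", {
  ext <- uls_extract(diag(6), 1)
  expect_lt(max(abs(ext$loadings)), 1e-6)
  expect_lt(ext$residual_rmsr, 1e-6)
})

test_that("ULS recovers a known one-factor structure to 1e-4", {
  lam <- c(0.8, 0.7, 0.6)
  R <- tcrossprod(lam)
  diag(R) <- 1
  ext <- uls_extract(R, 1)
  expect_equal(abs(as.vector(ext$loadings)), lam, tolerance = 1e-4)
  expect_lt(ext$residual_rmsr, 1e-6)
  expect_true(ext$converged)
})

test_that("the ULS objective descends monotonically", {
  cfg <- default_generating_model("younger", n = 400)
  d <- simulate_symptoms(cfg, seed = 51)
  tm <- tetrachoric_matrix(d)
  ext <- uls_extract(tm$rho, 8)
  expect_true(all(diff(ext$objective_trace) <= 1e-10))
})

test_that("geomin rotation preserves an already-perfect simple structure", {
  L <- rbind(
    c(0.8, 0), c(0.7, 0), c(0.6, 0),
    c(0, 0.75), c(0, 0.65), c(0, 0.55)
  )
  rot <- geomin_rotate(L, n_starts = 10, seed = 2)
  mf <- match_factors(rot$loadings, L)
  expect_true(all(mf$congruence > 1 - 1e-6))
  expect_equal(sort(abs(rot$loadings[abs(rot$loadings) > 0.1])),
               sort(abs(L[abs(L) > 0.1])), tolerance = 1e-3)
})

test_that("oblique rotation preserves the model-implied matrix", {
  cfg <- default_generating_model("older", n = 400)
  d <- simulate_symptoms(cfg, seed = 52)
  ext <- uls_extract(tetrachoric_matrix(d)$rho, 8)
  rot <- geomin_rotate(ext$loadings, n_starts = 10, seed = 3)
  implied_rot <- rot$loadings %*% rot$phi %*% t(rot$loadings)
  implied_unrot <- tcrossprod(ext$loadings)
  expect_equal(implied_rot, implied_unrot, tolerance = 1e-8,
               ignore_attr = TRUE)
  # factor correlations: symmetric, unit diagonal
  expect_equal(rot$phi, t(rot$phi))
  expect_equal(unname(diag(rot$phi)), rep(1, 8))
})

test_that("a two-factor oblique structure is recovered from simulated data", {
  L <- rbind(
    c(0.8, 0), c(0.7, 0), c(0.6, 0),
    c(0, 0.8), c(0, 0.7), c(0, 0.6)
  )
  rownames(L) <- paste0("s", 1:6)
  phi <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  cfg <- generator_config(L, phi, rep(0, 6), n = 5000)
  d <- simulate_symptoms(cfg, seed = 53)
  sol <- fit_efa(tetrachoric_matrix(d), 2, n_starts = 10, seed = 4)
  mf <- match_factors(sol$loadings, L)
  expect_true(all(mf$congruence > 0.98))
  i <- mf$matched_column[1]
  j <- mf$matched_column[2]
  expect_equal(abs(sol$phi[i, j]), 0.3, tolerance = 0.05)
})

test_that("k=1 rotation is the identity", {
  ext <- uls_extract(tcrossprod(c(0.8, 0.7, 0.6)) + diag(c(0.36, 0.51, 0.64)), 1)
  rot <- geomin_rotate(ext$loadings)
  expect_identical(rot$loadings, ext$loadings)
})

test_that("population matrices are recovered nearly exactly", {
  for (g in c("younger", "older")) {
    cfg <- default_generating_model(g)
    R <- population_correlations(cfg)
    sol <- fit_efa(R, 8, n_starts = 20, seed = 5, max_iter = 10000)
    expect_lt(sol$residual_rmsr, 0.01)
    mf <- match_factors(sol$loadings, cfg$loadings)
    expect_true(all(mf$congruence >= 0.98))
    expect_gte(sol$n_starts_agreeing, 1)
  }
})

test_that("fit_solutions diagnostics identify the generating rank", {
  lam <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0, 0, 0, 0),
               c(0, 0, 0, 0.8, 0.7, 0.6, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0, 0.8, 0.7, 0.6))
  rownames(lam) <- paste0("s", 1:9)
  R <- tcrossprod(lam)
  diag(R) <- 1
  fits <- fit_solutions(R, k_min = 2, k_max = 4, n_starts = 5, seed = 6)
  dg <- fits$diagnostics
  expect_lt(dg$residual_rmsr[dg$k == 3], 0.01)
  expect_gt(dg$residual_rmsr[dg$k == 2], dg$residual_rmsr[dg$k == 3])
  expect_equal(dg$n_adequate_factors[dg$k == 3], 3)
  # identity matrix: no adequately defined factors at any k
  fits0 <- fit_solutions(diag(9), k_min = 2, k_max = 3, n_starts = 3, seed = 7)
  expect_true(all(fits0$diagnostics$n_adequate_factors == 0))
})

test_that("cluster extraction applies the inclusive 0.40 rule with cross-loading", {
  L <- rbind(
    a = c(0.40, 0.00),
    b = c(0.55, 0.45),
    c = c(0.00, 0.80),
    d = c(0.10, 0.39)
  )
  colnames(L) <- c("F1", "F2")
  cs <- extract_clusters(L, threshold = 0.40)
  f1 <- cs$clusters[cs$clusters$cluster == "F1", ]
  expect_setequal(f1$code, c("a", "b"))      # 0.40 exactly is included
  f2 <- cs$clusters[cs$clusters$cluster == "F2", ]
  expect_setequal(f2$code, c("b", "c"))      # b cross-loads; d at 0.39 is out
  expect_true("d" %in% cs$unassigned)
  expect_equal(f1$code, c("b", "a"))         # ordered by |loading| descending
})

test_that("published loading tables yield the printed cluster memberships", {
  cy <- extract_clusters(reference_loading_matrix("younger"), group = "younger")
  resp <- cy$clusters[cy$clusters$cluster == "respiratory", ]
  expect_equal(resp$code, c("diff_breathing", "short_breath", "chest_tight"))
  expect_equal(resp$loading, c(1.049, 0.824, 0.611))
  co <- extract_clusters(reference_loading_matrix("older"), group = "older")
  epi <- co$clusters[co$clusters$cluster == "epithelial", ]
  expect_equal(nrow(epi), 6)
  expect_true("dizziness" %in% epi$code)
  expect_equal(epi$loading[epi$code == "dizziness"], 0.479)
})

test_that("factors with fewer than two members are dropped into unassigned", {
  L <- rbind(a = c(0.9, 0), b = c(0.8, 0), c = c(0, 0.7), d = c(0.1, 0.2))
  colnames(L) <- c("F1", "F2")
  cs <- extract_clusters(L, threshold = 0.40)
  expect_equal(unique(cs$clusters$cluster), "F1")
  expect_setequal(cs$unassigned, c("c", "d"))
  expect_equal(cs$n_factors_dropped, 1L)
})
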