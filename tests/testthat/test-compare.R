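ref_sets <- function() {
  list(
    younger = extract_clusters(reference_loading_matrix("younger"),
                               group = "younger"),
    older = extract_clusters(reference_loading_matrix("older"),
                             group = "older")
  )
}

test_that("identical cluster sets match themselves with full overlap", {
  s <- ref_sets()$younger
  m <- match_clusters(s, s)
  expect_true(all(m$cluster_a == m$cluster_b))
  sizes <- table(s$clusters$cluster)
  expect_equal(m$n_shared, as.integer(sizes[m$cluster_a]), ignore_attr = TRUE)
  rep <- compare_cluster_sets(s, s)
  expect_true(all(rep$pairs$stable))
  expect_true(all(rep$pairs$consistent))
})

test_that("optimal matching beats greedy on an adversarial overlap matrix", {
  # overlap matrix [[2,1,0],[2,0,1],[0,2,1]]: optimum is 5
  a <- toy_cluster_set(list(
    A1 = c(a = 0.9, b = 0.8, x1 = 0.5),
    A2 = c(c = 0.9, d = 0.8, x2 = 0.5),
    A3 = c(e = 0.9, f = 0.8, x3 = 0.5)
  ))
  b <- toy_cluster_set(list(
    B1 = c(a = 0.7, b = 0.6, c = 0.5, d = 0.45),
    B2 = c(x1 = 0.7, e = 0.6, f = 0.5),
    B3 = c(x2 = 0.7, x3 = 0.6)
  ))
  m <- match_clusters(a, b)
  expect_equal(sum(m$n_shared), 5)
  # brute-force permutation oracle
  la <- list(c("a","b","x1"), c("c","d","x2"), c("e","f","x3"))
  lb <- list(c("a","b","c","d"), c("x1","e","f"), c("x2","x3"))
  best <- max(sapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                          c(3,1,2), c(3,2,1)), function(p) {
    sum(sapply(1:3, function(i) length(intersect(la[[i]], lb[[p[i]]]))))
  }))
  expect_equal(sum(m$n_shared), best)
})

test_that("unmatched clusters are reported when set sizes differ", {
  a <- toy_cluster_set(list(A1 = c(a = 0.9, b = 0.8)))
  b <- toy_cluster_set(list(B1 = c(a = 0.9, b = 0.8),
                            B2 = c(c = 0.9, d = 0.8)))
  m <- match_clusters(a, b)
  expect_equal(m$cluster_b[is.na(m$cluster_a)], "B2")
  rep <- compare_cluster_sets(a, b)
  expect_equal(rep$unmatched_b, "B2")
  expect_equal(rep$summary$n_pairs, 1)
})

test_that("published cluster sets match row for row", {
  s <- ref_sets()
  m <- match_clusters(s$younger, s$older)
  expect_equal(nrow(m), 8)
  expect_true(all(m$cluster_a == m$cluster_b))
})

test_that("stability rule: at least two shared at-threshold symptoms", {
  expect_true(is_stable(2))
  expect_false(is_stable(1))
  expect_false(is_stable(5, both_present = FALSE))
  a <- toy_cluster_set(list(A = c(hot_flashes = 0.807, sweats = 0.788)))
  b <- toy_cluster_set(list(B = c(hot_flashes = 0.728, sweats = 0.783)))
  expect_true(compare_cluster_sets(a, b)$pairs$stable)
  d <- toy_cluster_set(list(B = c(p = 0.7, q = 0.6)))
  expect_false(compare_cluster_sets(a, d)$pairs$stable)
})

test_that("consistency k follows the larger cluster's size", {
  expect_equal(consistency_k(2, 2), 2L)
  expect_equal(consistency_k(4, 3), 3L)
  expect_equal(consistency_k(3, 3), 2L)
  expect_equal(consistency_k(3, 5), 3L)
  expect_error(consistency_k(1, 3))
})

test_that("consistency verdicts are symmetric and respect ordering", {
  ca <- tibble::tibble(code = c("a", "b", "c", "d"),
                       loading = c(0.9, 0.8, 0.7, 0.6))
  cb <- tibble::tibble(code = c("b", "a", "e", "c"),
                       loading = c(0.85, 0.75, 0.65, 0.55))
  v1 <- assess_consistency(ca, cb)
  v2 <- assess_consistency(cb, ca)
  expect_equal(v1$k, 3L)
  expect_equal(v1$shared_top, 2L)
  expect_false(v1$consistent)
  expect_equal(v2$shared_top, v1$shared_top)
  expect_equal(v2$consistent, v1$consistent)
  # identical ordering: k/k
  v3 <- assess_consistency(ca, ca)
  expect_true(v3$consistent)
  expect_equal(v3$shared_top, v3$k)
})

test_that("ties at the k-th loading expand the top set and are flagged", {
  ca <- tibble::tibble(code = c("a", "b", "c"), loading = c(0.9, 0.5, 0.5))
  cb <- tibble::tibble(code = c("a", "c", "b"), loading = c(0.9, 0.8, 0.2))
  v <- assess_consistency(ca, cb)
  expect_true(v$tie_affected)
  expect_setequal(v$top_a[[1]], c("a", "b", "c"))
})

test_that("shared top count is bounded by k and the cluster sizes", {
  sets <- withr::with_seed(17, replicate(10, {
    codes <- sample(letters, 12)
    list(
      a = tibble::tibble(code = codes[1:sample(2:6, 1)],
                         loading = sort(runif(length(code), 0.4, 1),
                                        decreasing = TRUE)),
      b = tibble::tibble(code = sample(codes, sample(2:6, 1)),
                         loading = sort(runif(length(code), 0.4, 1),
                                        decreasing = TRUE))
    )
  }, simplify = FALSE))
  for (s in sets) {
    v <- assess_consistency(s$a, s$b)
    expect_lte(v$shared_top, min(v$k, nrow(s$a), nrow(s$b)))
  }
})

test_that("the comparator reproduces all eight published consistency cells", {
  s <- ref_sets()
  rep <- compare_cluster_sets(s$younger, s$older)
  verdicts <- setNames(rep$pairs$verdict, rep$pairs$cluster_a)
  expect_equal(verdicts[["fatigue"]], "2/3")
  expect_equal(verdicts[["respiratory"]], "3/3")
  expect_equal(verdicts[["psychological"]], "3/3")
  expect_equal(verdicts[["hormonal"]], "2/2")
  expect_equal(verdicts[["toxicity"]], "1/2")
  expect_equal(verdicts[["weight_gain"]], "2/2")
  expect_equal(verdicts[["gastrointestinal"]], "0/2")
  expect_equal(verdicts[["epithelial"]], "3/3")
  expect_equal(rep$summary$n_stable, 8)
  expect_equal(rep$summary$n_consistent, 5)
  expect_equal(rep$summary$n_inconsistent, 3)
  expect_false(any(rep$pairs$tie_affected))
})
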