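rand_dyad_matrix <- function(n, ids = sprintf("i%02d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- ids
  dyad_matrix(m)
}

test_that("mantel r is 1 for identical matrices and errors on zero variance", {
  a <- withr::with_seed(1, rand_dyad_matrix(8))
  res <- mantel_test(a, a, n_permutations = 99, seed = 2)
  expect_equal(res$observed, 1)
  expect_equal(res$n_dyads, 28)

  const <- dyad_matrix(matrix(1, 4, 4, dimnames = list(letters[1:4],
                                                       letters[1:4])))
  expect_error(mantel_test(a, a * 0), "zero variance")
})

test_that("exact mantel p equals exhaustive enumeration on 5 individuals", {
  withr::with_seed(7, {
    a <- rand_dyad_matrix(5)
    b <- rand_dyad_matrix(5, ids = rownames(a))
  })
  res <- mantel_test(a, b, exact = TRUE, alternative = "greater")
  expect_equal(res$n_permutations, 120)

  # oracle: enumerate all 120 reorderings of b by hand
  va <- oracle_upper(unclass(a))
  stats <- vapply(oracle_perms(1:5), function(p) {
    bp <- unclass(b)[p, p]
    cor(va, oracle_upper(bp))
  }, numeric(1))
  p_oracle <- mean(stats >= res$observed - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # two-sided variant against the same enumeration
  res2 <- mantel_test(a, b, exact = TRUE, alternative = "two.sided")
  expect_equal(res2$p_value,
               mean(abs(stats) >= abs(res2$observed) - 1e-12),
               tolerance = 1e-12)
})

test_that("mantel is symmetric in its arguments for the free scheme", {
  withr::with_seed(8, {
    a <- rand_dyad_matrix(5)
    b <- rand_dyad_matrix(5, ids = rownames(a))
  })
  r_ab <- mantel_test(a, b, exact = TRUE)
  r_ba <- mantel_test(b, a, exact = TRUE)
  expect_equal(r_ab$observed, r_ba$observed, tolerance = 1e-12)
  expect_equal(r_ab$p_value, r_ba$p_value, tolerance = 1e-12)
})

test_that("mantel agrees with vegan on observed r and approximate p", {
  skip_if_not_installed("vegan")
  withr::with_seed(9, {
    n <- 12
    base <- rand_dyad_matrix(n)
    noise <- rand_dyad_matrix(n, ids = rownames(base))
    b <- dyad_matrix(unclass(base) * 0.7 + unclass(noise) * 0.7,
                     ids = rownames(base))
  })
  res <- mantel_test(base, b, n_permutations = 999, seed = 10)
  veg <- vegan::mantel(as.dist(unclass(base)), as.dist(unclass(b)),
                       permutations = 999)
  expect_equal(res$observed, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(abs(res$p_value - veg$signif), 0.05)
})

test_that("restricted permutations never move labels across blocks", {
  labels <- c("p1", "p2", "p3", "p4")
  blocks <- c("A", "A", "B", "B")
  draws <- withr::with_seed(11, replicate(1000, restricted_permute(labels, blocks)))
  expect_true(all(draws[1:2, ] %in% c("p1", "p2")))
  expect_true(all(draws[3:4, ] %in% c("p3", "p4")))
  # within-block label multisets conserved on every draw
  expect_true(all(apply(draws, 2, function(d)
    setequal(d[1:2], c("p1", "p2")) && setequal(d[3:4], c("p3", "p4")))))
  # both within-block arrangements actually occur
  expect_gt(mean(draws[1, ] == "p2"), 0.4)
  # one block = plain permutation reachable everywhere
  free <- withr::with_seed(12, replicate(500, restricted_permute(labels)))
  expect_gt(mean(free[1, ] == "p4"), 0.15)
})

test_that("categorical mantel: constant values give zero difference, p = 1", {
  s <- build_structure(list(c(3, 3), c(3, 3)))
  const <- dyad_matrix(matrix(2, 12, 12,
                              dimnames = list(s$individual, s$individual)))
  ct <- categorical_mantel(const, s, "gang", n_permutations = 99, seed = 1)
  expect_equal(ct$test$observed, 0)
  expect_equal(ct$test$p_value, 1)
})

test_that("exact categorical p matches exhaustive label enumeration", {
  s <- build_structure(list(3, 3))   # 6 males, 2 gangs of 3
  withr::with_seed(13, {
    vals <- rand_dyad_matrix(6, ids = s$individual)
  })
  res <- categorical_mantel(vals, s, "gang", exact = TRUE,
                            alternative = "greater")
  v <- oracle_upper(unclass(vals))
  idx <- which(upper.tri(unclass(vals)), arr.ind = TRUE)
  labs <- s$gang
  stats <- vapply(oracle_perms(1:6), function(p) {
    lab <- labs[p]
    same <- lab[idx[, 1]] == lab[idx[, 2]]
    mean(v[!same]) - mean(v[same])
  }, numeric(1))
  expect_equal(res$test$p_value,
               mean(stats >= res$test$observed - 1e-12),
               tolerance = 1e-12)
})

test_that("party-level contrasts only use same-gang dyads and restricted permutation", {
  s <- default_structure()
  withr::with_seed(14, {
    vals <- rand_dyad_matrix(27, ids = s$individual)
  })
  ct <- categorical_mantel(vals, s, "party", n_permutations = 99, seed = 15)
  expect_equal(ct$n_same + ct$n_different, 169)
  expect_equal(ct$test$scheme, "party_within_gang")

  ct_gang <- categorical_mantel(vals, s, "gang", n_permutations = 99, seed = 15)
  expect_equal(ct_gang$n_same + ct_gang$n_different, 351)
  expect_equal(ct_gang$n_same, 169)
  expect_equal(ct_gang$test$scheme, "free")
})

test_that("quartile contrast sizes and guards behave as specified", {
  s <- default_structure()
  withr::with_seed(16, {
    w <- rand_dyad_matrix(27, ids = s$individual)
    d <- rand_dyad_matrix(27, ids = s$individual)
  })
  qc <- quartile_contrast(w, d, q = 0.25, n_permutations = 199, seed = 17)
  # strict > / < at type-7 quartiles of 351 distinct values: 88 + 88
  expect_equal(qc$n_high, 88)
  expect_equal(qc$n_low, 88)
  expect_equal(qc$n_total, 176)
  expect_gte(qc$test$p_value, 1 / 200)

  const <- dyad_matrix(matrix(1, 27, 27,
                              dimnames = list(s$individual, s$individual)))
  expect_error(quartile_contrast(const, d), "Empty quartile side")
  expect_error(quartile_contrast(w, d, q = 0.6), "q")
})

test_that("quartile contrast p is uniform when D is independent of W", {
  reps <- 200
  ps <- withr::with_seed(18, vapply(seq_len(reps), function(i) {
    w <- rand_dyad_matrix(12)
    d <- rand_dyad_matrix(12, ids = rownames(w))
    quartile_contrast(w, d, n_permutations = 99)$test$p_value
  }, numeric(1)))
  rate <- mean(ps <= 0.1)
  expect_gt(rate, 0.1 - 3 * sqrt(0.1 * 0.9 / reps))
  expect_lt(rate, 0.1 + 3 * sqrt(0.1 * 0.9 / reps))
})
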