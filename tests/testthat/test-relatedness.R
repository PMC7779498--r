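test_that("allele frequencies are direct counts over typed individuals", {
  g <- make_genotypes(list(
    a = matrix(c(1L, 1L), 2, 1),
    b = matrix(c(1L, 2L), 2, 1)
  ))
  af <- allele_frequencies(g)
  expect_equal(af$freq[af$allele == 1], 0.75)
  expect_equal(af$freq[af$allele == 2], 0.25)

  mono <- make_genotypes(list(a = matrix(c(2L, 2L), 2, 1),
                              b = matrix(c(2L, 2L), 2, 1)))
  expect_equal(allele_frequencies(mono)$freq, 1)

  all_missing <- tibble::tibble(individual = c("a", "b"),
                                L01_a1 = c(NA_integer_, NA_integer_),
                                L01_a2 = c(NA_integer_, NA_integer_))
  expect_error(allele_frequencies(all_missing), "no typed")
})

test_that("estimated frequencies recover the simulating values", {
  s <- build_structure(list(c(250, 250)))
  sim <- simulate_genotypes(s, n_loci = 4, n_alleles = 5, missing_rate = 0,
                            fullsib_prop = 0, halfsib_prop = 0, seed = 17)
  af <- allele_frequencies(sim$genotypes)
  for (l in names(sim$founder_freqs)) {
    est <- af[af$locus == l, ]
    truth <- sim$founder_freqs[[l]]
    expect_lt(max(abs(est$freq - truth[as.character(est$allele)])), 0.05)
  }
})

test_that("the exact HWE p equals a brute-force allele-shuffle enumeration", {
  # 3 individuals, allele counts {2, 4}: enumerate all 6! shuffles
  cases <- list(
    list(g = list(a = matrix(c(1L, 1L), 2, 1), b = matrix(c(2L, 2L), 2, 1),
                  c = matrix(c(2L, 2L), 2, 1))),
    list(g = list(a = matrix(c(1L, 2L), 2, 1), b = matrix(c(1L, 2L), 2, 1),
                  c = matrix(c(2L, 2L), 2, 1)))
  )
  for (case in cases) {
    tbl <- make_genotypes(case$g)
    pool <- c(sapply(case$g, function(m) m[, 1]))
    arr_key <- function(al) {
      pairs <- matrix(al, 2)
      paste(sort(paste(pmin(pairs[1, ], pairs[2, ]),
                       pmax(pairs[1, ], pairs[2, ]))), collapse = "|")
    }
    keys <- vapply(oracle_perms(pool), arr_key, character(1))
    tab <- table(keys) / length(keys)
    obs_key <- arr_key(as.vector(sapply(case$g, function(m) m[, 1])))
    p_oracle <- sum(tab[tab <= tab[[obs_key]] + 1e-12])
    p_pkg <- hwe_exact_test(tbl, method = "exact")$p_value
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  }
})

test_that("HWE test behaves at the boundaries", {
  # perfect biallelic HWE proportions: clearly non-significant
  g <- make_genotypes(c(
    setNames(replicate(8, matrix(c(1L, 1L), 2, 1), simplify = FALSE),
             sprintf("aa%02d", 1:8)),
    setNames(replicate(16, matrix(c(1L, 2L), 2, 1), simplify = FALSE),
             sprintf("ab%02d", 1:16)),
    setNames(replicate(8, matrix(c(2L, 2L), 2, 1), simplify = FALSE),
             sprintf("bb%02d", 1:8))
  ))
  res <- hwe_exact_test(g, method = "exact")
  expect_gt(res$p_value, 0.5)
  expect_lte(res$p_value, 1)

  mono <- make_genotypes(list(a = matrix(c(1L, 1L), 2, 1),
                              b = matrix(c(1L, 1L), 2, 1)))
  res_mono <- hwe_exact_test(mono)
  expect_equal(res_mono$p_value, 1)
  expect_equal(res_mono$method, "monomorphic")

  # exact and Monte-Carlo paths agree on the same locus
  het_def <- make_genotypes(c(
    setNames(replicate(10, matrix(c(1L, 1L), 2, 1), simplify = FALSE),
             sprintf("h%02d", 1:10)),
    setNames(replicate(10, matrix(c(2L, 2L), 2, 1), simplify = FALSE),
             sprintf("k%02d", 1:10))
  ))
  p_exact <- hwe_exact_test(het_def, method = "exact")$p_value
  p_mc <- hwe_exact_test(het_def, method = "mc", n_mc = 20000,
                         seed = 1)$p_value
  expect_lt(abs(p_exact - p_mc), 0.01)
  expect_lt(p_exact, 0.001)
})

test_that("HWE type-I error is near alpha for loci simulated in equilibrium", {
  reps <- 200
  ps <- withr::with_seed(77, vapply(seq_len(reps), function(i) {
    freq <- rgamma(6, 1); freq <- freq / sum(freq)
    alleles <- matrix(sample(1:6, 100, replace = TRUE, prob = freq), 2)
    g <- make_genotypes(setNames(
      lapply(seq_len(50), function(j) alleles[, j, drop = FALSE]),
      sprintf("i%02d", 1:50)))
    hwe_exact_test(g, method = "mc", n_mc = 999)$p_value
  }, numeric(1)))
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.01)   # exact conditional tests are mildly conservative
  expect_lte(rate, 0.09)
})

test_that("the null-allele estimator matches its closed form", {
  # Ho = He = 0.5 -> estimate 0
  g0 <- make_genotypes(list(a = matrix(c(1L, 1L), 2, 1),
                            b = matrix(c(1L, 2L), 2, 1),
                            c = matrix(c(1L, 2L), 2, 1),
                            d = matrix(c(2L, 2L), 2, 1)))
  expect_equal(null_allele_screen(g0)$null_freq, 0)

  # He = 0.5, Ho = 0.25 -> r = 0.25 / 1.5
  g1 <- make_genotypes(c(
    setNames(replicate(3, matrix(c(1L, 1L), 2, 1), simplify = FALSE),
             c("a", "b", "c")),
    setNames(replicate(3, matrix(c(2L, 2L), 2, 1), simplify = FALSE),
             c("d", "e", "f")),
    list(h1 = matrix(c(1L, 2L), 2, 1), h2 = matrix(c(1L, 2L), 2, 1))
  ))
  expect_equal(null_allele_screen(g1)$null_freq, 0.25 / 1.5, tolerance = 1e-12)

  # monomorphic: He = 0 -> 0 by convention
  mono <- make_genotypes(list(a = matrix(c(1L, 1L), 2, 1),
                              b = matrix(c(1L, 1L), 2, 1)))
  expect_equal(null_allele_screen(mono)$null_freq, 0)
})

test_that("a simulated true null allele is recovered within tolerance", {
  est <- withr::with_seed(88, {
    n <- 300
    vis_freq <- c(0.25, 0.2, 0.2, 0.15)        # visible alleles 1..4, sum 0.8
    p <- c(vis_freq, 0.2)                       # allele 5 is the null
    draw <- function() sample(1:5, 2, replace = TRUE, prob = p)
    genos <- lapply(seq_len(n), function(i) {
      al <- draw()
      if (all(al == 5)) return(matrix(c(NA_integer_, NA_integer_), 2, 1))
      if (any(al == 5)) {
        vis <- al[al != 5]
        return(matrix(c(vis, vis), 2, 1))       # null hides as a homozygote
      }
      matrix(as.integer(al), 2, 1)
    })
    names(genos) <- sprintf("i%03d", seq_len(n))
    null_allele_screen(make_genotypes(genos))$null_freq
  })
  expect_lt(abs(est - 0.2), 0.1)
})

test_that("locus screening excludes a null-allele locus by the joint rule", {
  # 23 clean loci constructed with a heterozygote EXCESS (HWE-deviant but
  # null-allele estimate negative: the conjunction rule must retain them),
  # plus one locus with a complete heterozygote deficit (both flags fire).
  n_ind <- 27
  ids <- sprintf("m%02d", seq_len(n_ind))
  tbl <- tibble::tibble(individual = ids)
  for (l in 1:23) {
    tbl[[sprintf("L%02d_a1", l)]] <- rep(1L, n_ind)   # every male heterozygous
    tbl[[sprintf("L%02d_a2", l)]] <- rep(2L, n_ind)
  }
  tbl$L24_a1 <- c(rep(1L, 14), rep(2L, 13))           # no heterozygotes at all
  tbl$L24_a2 <- tbl$L24_a1

  rep24 <- locus_report(tbl, n_mc = 2000, seed = 3)
  expect_equal(nrow(rep24), 24)
  expect_true(rep24$excluded[rep24$locus == "L24"])
  expect_true(all(rep24$null_freq[rep24$locus != "L24"] < 0))
  retained <- filter_loci(rep24)
  expect_equal(length(retained), 23)                  # 24 screened -> 23 kept
  expect_false("L24" %in% retained)

  # loci in (approximate) HWE proportions: nothing flagged, identity
  hwe_tbl <- tibble::tibble(individual = ids)
  genos <- c(rep(list(c(1L, 1L)), 7), rep(list(c(1L, 2L)), 13),
             rep(list(c(2L, 2L)), 7))
  for (l in 1:3) {
    hwe_tbl[[sprintf("L%02d_a1", l)]] <- vapply(genos, `[`, 1L, 1)
    hwe_tbl[[sprintf("L%02d_a2", l)]] <- vapply(genos, `[`, 1L, 2)
  }
  rep_clean <- locus_report(hwe_tbl, n_mc = 2000, seed = 3)
  expect_false(any(rep_clean$excluded))
  expect_identical(as.character(filter_loci(rep_clean)), rep_clean$locus)

  only_bad <- tbl[, c("individual", "L24_a1", "L24_a2")]
  names(only_bad) <- c("individual", "L01_a1", "L01_a2")
  expect_error(filter_loci(locus_report(only_bad, seed = 3)),
               "All loci were excluded")
})

test_that("identical homozygous genotypes give relatedness exactly 1", {
  n_loci <- 10
  # both individuals homozygous (i, i) with i varying over loci
  hom <- matrix(rep(1:n_loci %% 4 + 1L, each = 2), 2)
  geno <- make_genotypes(list(a = hom, b = hom))
  freqs <- dplyr::bind_rows(lapply(sprintf("L%02d", 1:n_loci), function(l)
    tibble::tibble(locus = l, allele = 1:4, freq = 0.25)))
  w <- wang_relatedness(geno, freqs = freqs)
  expect_equal(w["a", "b"], 1, tolerance = 1e-8)
})

test_that("Wang recovers parent-offspring and unrelated expectations", {
  po <- simulate_dyads_oracle(120, 80, 6, "parent_offspring", seed = 301)
  freqs_tbl <- dplyr::bind_rows(lapply(seq_along(po$freqs), function(l)
    tibble::tibble(locus = sprintf("L%02d", l),
                   allele = as.integer(names(po$freqs[[l]])),
                   freq = unname(po$freqs[[l]]))))
  w_po <- wang_relatedness(po$genotypes, dyads = po$dyads, freqs = freqs_tbl)
  expect_lt(abs(mean(w_po$w) - 0.5), 0.08)

  un <- simulate_dyads_oracle(120, 80, 6, "unrelated", seed = 302)
  freqs_un <- dplyr::bind_rows(lapply(seq_along(un$freqs), function(l)
    tibble::tibble(locus = sprintf("L%02d", l),
                   allele = as.integer(names(un$freqs[[l]])),
                   freq = unname(un$freqs[[l]]))))
  w_un <- wang_relatedness(un$genotypes, dyads = un$dyads, freqs = freqs_un)
  expect_lt(abs(mean(w_un$w)), 0.05)
})

test_that("simulated kin classes are rank-ordered by mean W", {
  s <- build_structure(list(c(20, 20), c(20, 20)))
  sim <- simulate_genotypes(s, n_loci = 23, fullsib_prop = 0.5,
                            halfsib_prop = 0.25, missing_rate = 0, seed = 19)
  W <- wang_relatedness(sim$genotypes)
  k <- unclass(sim$true_kinship)
  ut <- upper.tri(k)
  w <- unclass(W)
  m_fs <- mean(w[ut & k == 0.5])
  m_hs <- mean(w[ut & k == 0.25])
  m_un <- mean(w[ut & k == 0])
  expect_gt(m_fs, m_hs)
  expect_gt(m_hs, m_un)
  # estimator validity on a realistic table: symmetric, finite, in [-1, 1]
  expect_true(isSymmetric(w))
  offdiag <- w[ut]
  expect_true(all(is.finite(offdiag)))
  expect_true(all(offdiag >= -1 & offdiag <= 1))
})

test_that("estimator variance shrinks as loci are added (paired seeds)", {
  un30 <- simulate_dyads_oracle(150, 30, 6, "unrelated", seed = 401)
  un120 <- simulate_dyads_oracle(150, 120, 6, "unrelated", seed = 401)
  w30 <- wang_relatedness(un30$genotypes, dyads = un30$dyads)
  w120 <- wang_relatedness(un120$genotypes, dyads = un120$dyads)
  expect_lt(var(w120$w), var(w30$w))
})

test_that("dyads without shared typed loci are missing, not fabricated", {
  tbl <- tibble::tibble(
    individual = c("a", "b", "c"),
    L01_a1 = c(1L, NA, 1L), L01_a2 = c(2L, NA, 1L),
    L02_a1 = c(NA, 1L, 2L), L02_a2 = c(NA, 2L, 2L),
    L03_a1 = c(1L, 1L, 1L), L03_a2 = c(1L, 1L, 1L)   # monomorphic: skipped
  )
  W <- wang_relatedness(tbl)
  expect_true(is.na(W["a", "b"]))
  expect_equal(attr(W, "n_missing_dyads"), 1L)
  expect_equal(attr(W, "skipped_loci"), "L03")
  expect_equal(unname(diag(unclass(W))), rep(1, 3))
})
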