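# Locus screening and pairwise relatedness from diploid microsatellites.

# Split a genotype tibble (individual + <locus>_a1/<locus>_a2 columns) into
# two allele matrices. 0 is accepted as an explicit missing code.
genotype_matrices <- function(genotypes, loci = NULL) {
  if (!is.data.frame(genotypes) || !"individual" %in% names(genotypes)) {
    abort("`genotypes` must be a data frame with an `individual` column.")
  }
  a1_cols <- grep("_a1$", names(genotypes), value = TRUE)
  all_loci <- sub("_a1$", "", a1_cols)
  missing_a2 <- setdiff(paste0(all_loci, "_a2"), names(genotypes))
  if (length(a1_cols) == 0L || length(missing_a2)) {
    abort("Genotype columns must come in `<locus>_a1`, `<locus>_a2` pairs.")
  }
  loci <- loci %||% all_loci
  if (!all(loci %in% all_loci)) abort("Unknown locus requested.")
  ids <- as.character(genotypes$individual)
  grab <- function(suffix) {
    m <- as.matrix(genotypes[paste0(loci, suffix)])
    mode(m) <- "integer"
    m[!is.na(m) & m <= 0] <- NA_integer_
    dimnames(m) <- list(ids, loci)
    m
  }
  a1 <- grab("_a1"); a2 <- grab("_a2")
  # A half-missing genotype is treated as missing.
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  list(a1 = a1, a2 = a2, ids = ids, loci = loci)
}

#' Allele frequencies per locus
#'
#' Counts alleles over the typed individuals at each locus and normalises.
#'
#' @param genotypes A genotype table (`individual` plus `<locus>_a1`,
#'   `<locus>_a2` integer columns; `NA` or 0 = missing).
#' @param loci Optional subset of locus names.
#' @return A tibble with columns `locus`, `allele`, `count`, `freq`
#'   (frequencies sum to 1 within each locus).
#' @export
allele_frequencies <- function(genotypes, loci = NULL) {
  gm <- genotype_matrices(genotypes, loci)
  out <- purrr::map(gm$loci, function(l) {
    alleles <- c(gm$a1[, l], gm$a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) {
      abort(sprintf("Locus %s has no typed genotypes.", l))
    }
    tab <- table(alleles)
    tibble::tibble(locus = l,
                   allele = as.integer(names(tab)),
                   count = as.integer(tab),
                   freq = as.integer(tab) / length(alleles))
  })
  dplyr::bind_rows(out)
}

# ---- Hardy-Weinberg exact test ---------------------------------------------

# log conditional probability of a genotype array given allele counts
# (Levene/Haldane): log P = log n! + H log2 + sum log m_i! - log (2n)! -
# sum log n_ij!.
hwe_array_logp <- function(n_het, pair_counts, allele_counts) {
  n <- sum(pair_counts)
  lfactorial(n) + n_het * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(pair_counts))
}

# Complete enumeration of genotype arrays with the observed allele counts.
# Returns the exact p: total probability of arrays no more probable than
# the observed one.
hwe_exact_enum <- function(allele_counts, obs_logp) {
  k <- length(allele_counts)
  n <- sum(allele_counts) / 2
  total <- 0
  hit <- 0
  lfact <- lfactorial(0:(2 * n))
  const <- lfact[n + 1] + sum(lfact[allele_counts + 1]) - lfact[2 * n + 1]
  # DFS over rows: for allele i choose n_ii and the off-diagonal counts
  # n_ij (j > i) consuming the remaining margins.
  rec <- function(i, rem, acc_lp, acc_het) {
    if (i > k) {
      if (all(rem == 0)) {
        lp <- const + acc_lp + acc_het * log(2)
        total <<- total + exp(lp)
        if (lp <= obs_logp + 1e-9) hit <<- hit + exp(lp)
      }
      return(invisible())
    }
    mi <- rem[i]
    # distribute mi over 2*n_ii + sum_j>i n_ij
    rec_row <- function(j, left, acc_lp2, acc_het2, rem2) {
      if (j > k) {
        if (left %% 2 == 0) {
          nii <- left %/% 2
          rec(i + 1L, rem2,
              acc_lp + acc_lp2 - lfact[nii + 1],
              acc_het + acc_het2)
        }
        return(invisible())
      }
      max_ij <- min(left, rem2[j])
      for (nij in 0:max_ij) {
        rem3 <- rem2
        rem3[j] <- rem3[j] - nij
        rec_row(j + 1L, left - nij,
                acc_lp2 - lfact[nij + 1], acc_het2 + nij, rem3)
      }
    }
    if (i == k) {
      if (mi %% 2 == 0) {
        nii <- mi %/% 2
        rem2 <- rem; rem2[i] <- 0
        rec(i + 1L, rem2, acc_lp - lfact[nii + 1], acc_het)
      }
    } else {
      rem2 <- rem; rem2[i] <- 0
      rec_row(i + 1L, mi, 0, 0, rem2)
    }
    invisible()
  }
  rec(1L, allele_counts, 0, 0)
  # `total` should be 1 up to float error; normalise defensively.
  min(max(hit / total, 0), 1)
}

# Monte-Carlo exact test: random re-pairings of the observed allele vector
# sample genotype arrays from the exact conditional distribution.
hwe_exact_mc <- function(a1, a2, n_mc) {
  k <- max(c(a1, a2))
  key <- function(x, y) (pmin(x, y) - 1L) * k + pmax(x, y)
  stat <- function(x, y) {
    counts <- tabulate(key(x, y), nbins = k * k)
    sum(x != y) * log(2) - sum(lfactorial(counts))
  }
  obs <- stat(a1, a2)
  pool <- c(a1, a2)
  n <- length(a1)
  odd <- seq(1L, 2L * n, 2L)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(pool)
    if (stat(perm[odd], perm[odd + 1L]) <= obs + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (n_mc + 1)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test given the observed allele counts: the p-value is
#' the total probability (under random union of gametes) of genotype arrays
#' no more probable than the observed one. The full array space is
#' enumerated when small; otherwise the conditional distribution is sampled
#' by Monte-Carlo re-pairings of the allele vector (seeded, with the add-one
#' correction).
#'
#' @param genotypes A genotype table.
#' @param loci Optional subset of loci (default: all).
#' @param method `"auto"` (enumerate when the array space is below
#'   `enum_limit` states, else Monte-Carlo), `"exact"` or `"mc"`.
#' @param n_mc Monte-Carlo re-pairings.
#' @param enum_limit Upper bound on the estimated enumeration size for the
#'   auto rule.
#' @param seed Optional seed for the Monte-Carlo path.
#' @return A tibble with columns `locus`, `n_typed`, `n_alleles`,
#'   `p_value`, `method`. Monomorphic loci get `p = 1` by convention; loci
#'   typed in fewer than 5 individuals are still tested but flagged
#'   `low_power`.
#' @export
hwe_exact_test <- function(genotypes, loci = NULL,
                           method = c("auto", "exact", "mc"),
                           n_mc = 1e5, enum_limit = 2e5, seed = NULL) {
  method <- rlang::arg_match(method)
  n_mc <- check_count(n_mc, "n_mc")
  gm <- genotype_matrices(genotypes, loci)
  with_seed_if(seed, {
    rows <- purrr::map(gm$loci, function(l) {
      a1 <- gm$a1[, l]; a2 <- gm$a2[, l]
      typed <- !is.na(a1)
      a1 <- a1[typed]; a2 <- a2[typed]
      if (length(a1) == 0L) abort(sprintf("Locus %s has no typed genotypes.", l))
      alleles <- sort(unique(c(a1, a2)))
      k <- length(alleles)
      if (k == 1L) {
        return(tibble::tibble(locus = l, n_typed = length(a1), n_alleles = 1L,
                              p_value = 1, method = "monomorphic",
                              low_power = length(a1) < 5L))
      }
      # recode alleles to 1..k
      a1r <- match(a1, alleles); a2r <- match(a2, alleles)
      counts <- tabulate(c(a1r, a2r), nbins = k)
      pair_counts <- tabulate((pmin(a1r, a2r) - 1L) * k + pmax(a1r, a2r),
                              nbins = k * k)
      obs_logp <- hwe_array_logp(sum(a1r != a2r),
                                 pair_counts[pair_counts > 0], counts)
      space <- prod(pmin(outer(counts, counts, pmin)[upper.tri(diag(k))] + 1,
                         length(a1) + 1))
      use_exact <- method == "exact" ||
        (method == "auto" && space <= enum_limit)
      if (use_exact) {
        p <- hwe_exact_enum(counts, obs_logp)
        meth <- "exact"
      } else {
        p <- hwe_exact_mc(a1r, a2r, n_mc)
        meth <- "mc"
      }
      tibble::tibble(locus = l, n_typed = length(a1), n_alleles = k,
                     p_value = p, method = meth,
                     low_power = length(a1) < 5L)
    })
    dplyr::bind_rows(rows)
  })
}

#' Null-allele screen by heterozygote deficit
#'
#' Estimates the null-allele frequency at each locus with the
#' heterozygote-deficit estimator `r = (He - Ho) / (1 + He)` (Chakraborty
#' form), where `Ho` is the observed and `He` the expected (Hardy-Weinberg)
#' heterozygosity. A slight excess of heterozygotes yields a negative
#' estimate; a locus with `He = 0` scores 0.
#'
#' @param genotypes A genotype table.
#' @param loci Optional subset of loci.
#' @return A tibble with columns `locus`, `ho`, `he`, `null_freq`.
#' @export
null_allele_screen <- function(genotypes, loci = NULL) {
  gm <- genotype_matrices(genotypes, loci)
  rows <- purrr::map(gm$loci, function(l) {
    a1 <- gm$a1[, l]; a2 <- gm$a2[, l]
    typed <- !is.na(a1)
    a1 <- a1[typed]; a2 <- a2[typed]
    if (length(a1) == 0L) abort(sprintf("Locus %s has no typed genotypes.", l))
    ho <- mean(a1 != a2)
    p <- as.vector(table(c(a1, a2))) / (2 * length(a1))
    he <- 1 - sum(p^2)
    tibble::tibble(locus = l, ho = ho, he = he,
                   null_freq = if (he == 0) 0 else (he - ho) / (1 + he))
  })
  dplyr::bind_rows(rows)
}

#' Per-locus quality report
#'
#' Combines allele counts, heterozygosities, the exact Hardy-Weinberg test
#' and the null-allele screen into one report, flagging loci for exclusion.
#' Mirroring the common practice of excluding a locus only on joint
#' evidence, a locus is flagged when BOTH its null-allele estimate exceeds
#' `null_threshold` AND its HWE p-value falls below `hwe_alpha`.
#'
#' @inheritParams hwe_exact_test
#' @param null_threshold Null-allele frequency above which a locus is
#'   suspect.
#' @param hwe_alpha Significance level for the HWE deviation flag.
#' @return A tibble with one row per locus: `locus`, `n_typed`,
#'   `n_alleles`, `ho`, `he`, `null_freq`, `hwe_p`, `hwe_method`,
#'   `excluded`, `reason`.
#' @export
locus_report <- function(genotypes, loci = NULL, null_threshold = 0.05,
                         hwe_alpha = 0.05, method = c("auto", "exact", "mc"),
                         n_mc = 1e5, seed = NULL) {
  hwe <- hwe_exact_test(genotypes, loci, method = method, n_mc = n_mc,
                        seed = seed)
  nulls <- null_allele_screen(genotypes, loci)
  rep <- dplyr::left_join(hwe, nulls, by = "locus")
  rep <- dplyr::mutate(
    rep,
    excluded = .data$null_freq > null_threshold & .data$p_value < hwe_alpha,
    reason = dplyr::if_else(
      .data$excluded,
      sprintf("null-allele estimate %.3f > %.2f and HWE p %.4f < %.2f",
              .data$null_freq, null_threshold, .data$p_value, hwe_alpha),
      NA_character_)
  )
  dplyr::select(rep, "locus", "n_typed", "n_alleles", "ho", "he",
                "null_freq", hwe_p = "p_value", hwe_method = "method",
                "excluded", "reason")
}

#' Retain loci that pass the screening rules
#'
#' @param report A [locus_report()] tibble.
#' @return Character vector of retained locus names (with the excluded
#'   rows attached as attribute `"excluded"`). Errors if every locus is
#'   excluded.
#' @export
filter_loci <- function(report) {
  retained <- report$locus[!report$excluded]
  if (length(retained) == 0L) {
    abort("All loci were excluded by the screening rules; nothing to analyse.")
  }
  attr(retained, "excluded") <- report[report$excluded, , drop = FALSE]
  retained
}

#' Subset a genotype table to a set of loci
#'
#' @param genotypes A genotype table.
#' @param loci Locus names to keep.
#' @return The genotype table with only `individual` and the kept loci's
#'   allele columns.
#' @export
keep_loci <- function(genotypes, loci) {
  cols <- c("individual", paste0(rep(loci, each = 2), c("_a1", "_a2")))
  missing <- setdiff(cols, names(genotypes))
  if (length(missing)) abort(sprintf("Missing genotype columns: %s",
                                     paste(missing, collapse = ", ")))
  genotypes[cols]
}

# ---- Wang moment estimator --------------------------------------------------

# Per-locus coefficients of the category moment equations, from allele
# counts (falling-factorial unbiased estimates of sum p^m) or from given
# frequencies (raw moments).
wang_locus_coefs <- function(counts = NULL, freqs = NULL) {
  if (!is.null(freqs)) {
    a2 <- sum(freqs^2); a3 <- sum(freqs^3); a4 <- sum(freqs^4)
  } else {
    n <- sum(counts)
    a2 <- sum(counts * (counts - 1)) / (n * (n - 1))
    a3 <- sum(counts * (counts - 1) * (counts - 2)) /
      (n * (n - 1) * (n - 2))
    a4 <- sum(counts * (counts - 1) * (counts - 2) * (counts - 3)) /
      (n * (n - 1) * (n - 2) * (n - 3))
  }
  b <- 2 * a2^2 - a4
  list(
    b = b,
    cc = a2 - b,
    d = 4 * (a3 - a4),
    e = 2 * (a2 - 3 * a3 + 2 * a4),
    f = 4 * (a2 - a2^2 - 2 * a3 + 2 * a4),
    g = 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4,
    u = 2 * a2 - a3
  )
}

# Solve the weighted category moment equations for one dyad.
# y/m coefficient rows: (P1-b | 1-b, c), (P2-d | -d, e), (P3-f | -f, g).
wang_solve <- function(P1, P2, P3, cf, w) {
  w <- w / sum(w)
  y <- c(sum(w * (P1 - cf$b)), sum(w * (P2 - cf$d)), sum(w * (P3 - cf$f)))
  X <- rbind(c(sum(w * (1 - cf$b)), sum(w * cf$cc)),
             c(-sum(w * cf$d),      sum(w * cf$e)),
             c(-sum(w * cf$f),      sum(w * cf$g)))
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-14) return(NA_real_)
  beta <- solve(XtX, crossprod(X, y))
  # relatedness = P(2 pairs IBD) + P(1 pair IBD)/2
  beta[1] + beta[2] / 2
}

#' Pairwise relatedness by the Wang moment estimator
#'
#' Estimates the relatedness of every dyad (or a requested set of dyads)
#' from multilocus codominant genotypes. For each locus the two genotypes
#' fall into one of four similarity categories (identical; one shared
#' allele with a homozygote; one shared allele between heterozygotes; no
#' shared allele). The expected category probabilities are linear in the
#' dyad's probabilities of sharing two (`Phi`) or one (`phi`) pair of
#' alleles identical by descent, with coefficients that are polynomial in
#' the locus's allele-frequency moments. The two coefficients are
#' estimated by least squares from the three moment equations, combining
#' loci with weights proportional to `1/u`, `u = 2*a2 - a3` (less
#' polymorphic loci are down-weighted); relatedness is `Phi + phi/2`.
#' Frequency moments use small-sample (falling-factorial) corrections.
#'
#' The estimate ranges over \[-1, 1\] for informative data: negative values
#' mean a dyad shares fewer alleles than expected for random members of the
#' sample. Estimates are NOT clamped. Dyads sharing no typed locus get
#' `NA` (their count is attached as attribute `"n_missing_dyads"`).
#'
#' @param genotypes A genotype table.
#' @param loci Optional subset of loci (e.g. the output of
#'   [filter_loci()]). Loci with fewer than 2 observed alleles are skipped
#'   (attribute `"skipped_loci"`).
#' @param dyads Optional two-column data frame (`id1`, `id2`) of dyads to
#'   estimate; default: all pairs, returned as a matrix.
#' @param freqs Optional known allele frequencies (a tibble as returned by
#'   [allele_frequencies()]); default: estimated from the full sample,
#'   including the focal dyad.
#' @param frequency_scope `"all"` (default: frequencies from the full
#'   sample, including the focal dyad) or `"leave_two_out"` (the focal
#'   dyad's alleles are removed from the counts before computing the
#'   frequency moments for that dyad). Ignored when `freqs` is supplied.
#' @return A [dyad_matrix()] of kind `"relatedness_W"` (unit diagonal) when
#'   `dyads` is `NULL`; otherwise a tibble `id1`, `id2`, `w`, `n_loci`.
#' @export
wang_relatedness <- function(genotypes, loci = NULL, dyads = NULL,
                             freqs = NULL,
                             frequency_scope = c("all", "leave_two_out")) {
  frequency_scope <- rlang::arg_match(frequency_scope)
  gm <- genotype_matrices(genotypes, loci)
  n_ind <- length(gm$ids)
  if (n_ind < 2L) abort("Need at least two individuals.")

  # Per-locus coefficients.
  coefs <- vector("list", length(gm$loci))
  names(coefs) <- gm$loci
  skipped <- character(0)
  for (l in gm$loci) {
    if (!is.null(freqs)) {
      fl <- freqs$freq[freqs$locus == l]
      if (length(fl) == 0L) abort(sprintf("No frequencies given for locus %s.", l))
      if (length(fl) < 2L) {
        skipped <- c(skipped, l)
        next
      }
      coefs[[l]] <- wang_locus_coefs(freqs = fl)
    } else {
      obs <- c(gm$a1[, l], gm$a2[, l])
      obs <- obs[!is.na(obs)]
      if (length(unique(obs)) < 2L) {
        skipped <- c(skipped, l)
        next
      }
      coefs[[l]] <- wang_locus_coefs(counts = as.vector(table(obs)))
    }
  }
  loci_use <- setdiff(gm$loci, skipped)
  if (length(loci_use) == 0L) abort("No informative (polymorphic) locus available.")
  cf <- list(
    b = vapply(coefs[loci_use], `[[`, 0, "b"),
    cc = vapply(coefs[loci_use], `[[`, 0, "cc"),
    d = vapply(coefs[loci_use], `[[`, 0, "d"),
    e = vapply(coefs[loci_use], `[[`, 0, "e"),
    f = vapply(coefs[loci_use], `[[`, 0, "f"),
    g = vapply(coefs[loci_use], `[[`, 0, "g"),
    u = vapply(coefs[loci_use], `[[`, 0, "u")
  )
  A1 <- gm$a1[, loci_use, drop = FALSE]
  A2 <- gm$a2[, loci_use, drop = FALSE]
  counts_by_locus <- lapply(loci_use, function(l) {
    obs <- c(A1[, l], A2[, l])
    table(obs[!is.na(obs)])
  })
  names(counts_by_locus) <- loci_use

  estimate_dyad <- function(i, j) {
    a <- A1[i, ]; b <- A2[i, ]; c2 <- A1[j, ]; d2 <- A2[j, ]
    ok <- !is.na(a) & !is.na(c2)
    if (!any(ok)) return(c(w = NA_real_, n_loci = 0))
    a <- a[ok]; b <- b[ok]; c2 <- c2[ok]; d2 <- d2[ok]
    ident <- pmin(a, b) == pmin(c2, d2) & pmax(a, b) == pmax(c2, d2)
    shared <- (a == c2) | (a == d2) | (b == c2) | (b == d2)
    hom_i <- a == b; hom_j <- c2 == d2
    P1 <- as.numeric(ident)
    P2 <- as.numeric(!ident & shared & (hom_i | hom_j))
    P3 <- as.numeric(!ident & shared & !hom_i & !hom_j)
    if (is.null(freqs) && frequency_scope == "leave_two_out") {
      loci_ok <- loci_use[ok]
      sub <- list(b = 0, cc = 0, d = 0, e = 0, f = 0, g = 0, u = 0)
      drop_ok <- logical(length(loci_ok))
      cl <- vector("list", length(loci_ok))
      for (s in seq_along(loci_ok)) {
        l <- loci_ok[s]
        cnt <- counts_by_locus[[l]]
        dyad_alleles <- table(c(a[s], b[s], c2[s], d2[s]))
        cnt[names(dyad_alleles)] <- cnt[names(dyad_alleles)] - dyad_alleles
        cnt <- cnt[cnt > 0]
        drop_ok[s] <- length(cnt) < 2L || sum(cnt) < 4
        if (!drop_ok[s]) cl[[s]] <- wang_locus_coefs(counts = as.vector(cnt))
      }
      if (all(drop_ok)) return(c(w = NA_real_, n_loci = 0))
      cl <- cl[!drop_ok]
      sub <- lapply(setNames(nm = names(cf)),
                    function(nm) vapply(cl, `[[`, 0, nm))
      P1 <- P1[!drop_ok]; P2 <- P2[!drop_ok]; P3 <- P3[!drop_ok]
      w <- wang_solve(P1, P2, P3, sub, 1 / sub$u)
      return(c(w = w, n_loci = sum(!drop_ok)))
    }
    sub <- lapply(cf, function(v) v[ok])
    w <- wang_solve(P1, P2, P3, sub, 1 / sub$u)
    c(w = w, n_loci = sum(ok))
  }

  if (is.null(dyads)) {
    W <- matrix(NA_real_, n_ind, n_ind, dimnames = list(gm$ids, gm$ids))
    n_missing <- 0L
    for (i in seq_len(n_ind - 1)) {
      for (j in (i + 1):n_ind) {
        est <- estimate_dyad(i, j)
        W[i, j] <- W[j, i] <- est[["w"]]
        if (is.na(est[["w"]])) n_missing <- n_missing + 1L
      }
    }
    diag(W) <- 1
    out <- dyad_matrix(W, ids = gm$ids, kind = "relatedness_W")
    attr(out, "skipped_loci") <- skipped
    attr(out, "n_missing_dyads") <- n_missing
    out
  } else {
    if (!all(c("id1", "id2") %in% names(dyads))) {
      abort("`dyads` must have columns id1, id2.")
    }
    i <- match(as.character(dyads$id1), gm$ids)
    j <- match(as.character(dyads$id2), gm$ids)
    if (anyNA(i) || anyNA(j)) abort("Unknown individual in `dyads`.")
    est <- t(mapply(estimate_dyad, i, j))
    out <- tibble::tibble(id1 = dyads$id1, id2 = dyads$id2,
                          w = est[, "w"], n_loci = as.integer(est[, "n_loci"]))
    attr(out, "skipped_loci") <- skipped
    out
  }
}
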