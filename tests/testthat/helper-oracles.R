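# Independent oracle utilities for the test suite. These deliberately
# re-derive quantities by brute force / closed form, without calling the
# package code paths they are used to check.

# All permutations of a vector, recursively (oracle-side enumeration,
# independent of the package's all_permutations()).
oracle_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Upper-triangle dyad values of a plain matrix.
oracle_upper <- function(m) m[upper.tri(m)]

# Pooled within-group covariance by explicit loops (oracle for DFA math).
oracle_pooled_cov <- function(X, grp) {
  grp <- as.factor(grp)
  p <- ncol(X)
  W <- matrix(0, p, p)
  for (g in levels(grp)) {
    Xg <- X[grp == g, , drop = FALSE]
    mu <- colMeans(Xg)
    for (r in seq_len(nrow(Xg))) {
      d <- Xg[r, ] - mu
      W <- W + outer(d, d)
    }
  }
  W / (nrow(X) - nlevels(grp))
}

# Two-sample Hotelling T^2-derived F statistic (closed form).
oracle_hotelling_f <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  d <- colMeans(X1) - colMeans(X2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(d %*% solve(S) %*% d)
  (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
}

# A minimal feature table: one row per call.
make_feature_table <- function(individuals, values) {
  tibble::tibble(
    call_id = sprintf("c%03d", seq_along(individuals)),
    individual = individuals,
    f1 = values
  )
}

# Genotype tibble from a list of per-individual allele-pair matrices
# (2 x n_loci integer matrices).
make_genotypes <- function(pairs_by_ind) {
  n_loci <- ncol(pairs_by_ind[[1]])
  loci <- sprintf("L%02d", seq_len(n_loci))
  out <- tibble::tibble(individual = names(pairs_by_ind))
  for (l in seq_len(n_loci)) {
    out[[paste0(loci[l], "_a1")]] <-
      vapply(pairs_by_ind, function(m) as.integer(m[1, l]), integer(1))
    out[[paste0(loci[l], "_a2")]] <-
      vapply(pairs_by_ind, function(m) as.integer(m[2, l]), integer(1))
  }
  out
}

# Simulate founder/parent-offspring genotype tables for the Wang oracle.
# Returns a genotype table of 2*n_dyads individuals plus the dyad list.
simulate_dyads_oracle <- function(n_dyads, n_loci, n_alleles, relationship,
                                  seed) {
  withr::with_seed(seed, {
    freqs <- lapply(seq_len(n_loci), function(l) {
      w <- stats::rgamma(n_alleles, 1)
      stats::setNames(w / sum(w), seq_len(n_alleles))
    })
    draw <- function() {
      vapply(freqs, function(p)
        sample(as.integer(names(p)), 2, replace = TRUE, prob = p),
        integer(2))
    }
    inds <- list()
    dyads <- list()
    for (k in seq_len(n_dyads)) {
      id1 <- sprintf("d%04da", k); id2 <- sprintf("d%04db", k)
      if (relationship == "unrelated") {
        inds[[id1]] <- draw(); inds[[id2]] <- draw()
      } else if (relationship == "parent_offspring") {
        parent <- draw(); mate <- draw()
        child <- rbind(
          ifelse(stats::runif(n_loci) < 0.5, parent[1, ], parent[2, ]),
          ifelse(stats::runif(n_loci) < 0.5, mate[1, ], mate[2, ])
        )
        inds[[id1]] <- parent; inds[[id2]] <- child
      } else if (relationship == "fullsib") {
        father <- draw(); mother <- draw()
        sib <- function() rbind(
          ifelse(stats::runif(n_loci) < 0.5, father[1, ], father[2, ]),
          ifelse(stats::runif(n_loci) < 0.5, mother[1, ], mother[2, ])
        )
        inds[[id1]] <- sib(); inds[[id2]] <- sib()
      } else stop("unknown relationship")
      dyads[[k]] <- tibble::tibble(id1 = id1, id2 = id2)
    }
    list(genotypes = make_genotypes(inds),
         dyads = dplyr::bind_rows(dyads),
         freqs = freqs)
  })
}
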