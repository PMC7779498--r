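# Internal helpers shared across modules.

# Run `expr` under a temporary seed when one is given; otherwise use the
# current RNG state (so callers can manage reproducibility themselves).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  as.numeric(x)
}

# Upper-triangle (i < j) values of a square matrix, column-major order.
upper_values <- function(m) m[upper.tri(m)]

# All permutations of seq_len(n) as a list of integer vectors (n! entries).
# Used for exhaustive permutation tests on small numbers of individuals.
all_permutations <- function(n, cap = 50000L) {
  if (factorial(n) > cap) {
    abort(sprintf("Exhaustive enumeration of %d! permutations exceeds the cap (%d).",
                  n, cap))
  }
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      k <<- k + 1L
      out[[k]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) {
      rec(c(prefix, rest[i]), rest[-i])
    }
  }
  rec(integer(0), seq_len(n))
  out
}

# All permutations of indices that keep every index inside its block:
# the cartesian product of per-block permutations.
all_block_permutations <- function(blocks, cap = 50000L) {
  blocks <- as.factor(blocks)
  idx_by_block <- split(seq_along(blocks), blocks)
  sizes <- vapply(idx_by_block, length, integer(1))
  total <- prod(factorial(sizes))
  if (total > cap) {
    abort(sprintf("Exhaustive within-block enumeration (%g permutations) exceeds the cap (%d).",
                  total, cap))
  }
  per_block <- lapply(idx_by_block, function(ix) {
    lapply(all_permutations(length(ix), cap = cap), function(p) ix[p])
  })
  combos <- list(integer(0))
  base <- seq_along(blocks)
  for (b in seq_along(per_block)) {
    combos <- unlist(lapply(combos, function(done) {
      lapply(per_block[[b]], function(p) c(done, p))
    }), recursive = FALSE)
  }
  lapply(combos, function(flat) {
    perm <- integer(length(blocks))
    perm[unlist(idx_by_block)] <- flat
    perm
  })
}

# Log-determinant of a symmetric PSD matrix; -Inf when singular.
logdet_psd <- function(m) {
  if (length(m) == 0L) return(0)
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

# Add-one (valid under exchangeability) permutation p-value.
perm_pvalue <- function(observed, null, alternative, tol = 1e-12) {
  n <- length(null)
  hits <- switch(alternative,
    greater   = sum(null >= observed - tol),
    less      = sum(null <= observed + tol),
    two.sided = sum(abs(null) >= abs(observed) - tol),
    abort("unknown alternative")
  )
  (hits + 1) / (n + 1)
}

# Exact p over a full enumeration that includes the identity permutation.
exact_pvalue <- function(observed, null_all, alternative, tol = 1e-12) {
  n <- length(null_all)
  hits <- switch(alternative,
    greater   = sum(null_all >= observed - tol),
    less      = sum(null_all <= observed + tol),
    two.sided = sum(abs(null_all) >= abs(observed) - tol),
    abort("unknown alternative")
  )
  hits / n
}
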