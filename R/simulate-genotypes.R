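#' Simulate pedigree-derived microsatellite genotypes
#'
#' Generates diploid codominant genotypes for the individuals of a social
#' structure, with elevated relatedness inside parties: a configurable
#' fraction of each party's males is grouped into full-sib families (shared
#' simulated father and mother) and another fraction into paternal half-sib
#' families (shared father, separate mothers). All remaining individuals and
#' all parents are founders with genotypes drawn from per-locus founder
#' allele frequencies, themselves drawn from a symmetric Dirichlet
#' distribution whose concentration controls how even the allele spectrum
#' is. Offspring genotypes are Mendelian samples from their parents.
#'
#' The pedigree expectation of each dyad's relatedness is recorded in
#' `true_kinship` (0.5 full sibs, 0.25 half sibs, 0 otherwise; unit
#' diagonal by convention). Missing genotypes are inserted completely at
#' random at `missing_rate` (both alleles of a locus are lost together, as
#' in failed amplifications).
#'
#' @param structure A social-structure table (see [build_structure()]).
#' @param n_loci Number of microsatellite loci.
#' @param n_alleles Alleles per locus (single count or per-locus vector).
#' @param founder_conc Positive Dirichlet concentration for founder allele
#'   frequencies (1 = uniform over the simplex; smaller = more skewed).
#' @param fullsib_prop,halfsib_prop Proportions of each party's members
#'   assigned to full-sib / half-sib families. Their sum must be <= 1 and
#'   the implied counts must fit the party sizes.
#' @param missing_rate Probability that an (individual, locus) genotype is
#'   missing.
#' @param seed Optional integer seed.
#' @return A list of class `genotype_sim` with elements `genotypes` (tibble:
#'   `individual` plus two integer columns `<locus>_a1`, `<locus>_a2` per
#'   locus, `NA` = missing), `true_kinship` (a [dyad_matrix()] of kind
#'   `"kinship"`), `founder_freqs` (list of per-locus frequency vectors),
#'   `pedigree` (tibble: individual, father, mother) and `parent_genotypes`
#'   (complete genotypes of the simulated parents, for provenance checks).
#' @export
simulate_genotypes <- function(structure,
                               n_loci = 23,
                               n_alleles = 8,
                               founder_conc = 1,
                               fullsib_prop = 0.3,
                               halfsib_prop = 0.3,
                               missing_rate = 0.02,
                               seed = NULL) {
  structure <- validate_structure(structure)
  n_loci <- check_count(n_loci, "n_loci")
  fullsib_prop <- check_prob(fullsib_prop, "fullsib_prop")
  halfsib_prop <- check_prob(halfsib_prop, "halfsib_prop")
  missing_rate <- check_prob(missing_rate, "missing_rate")
  if (fullsib_prop + halfsib_prop > 1) {
    abort("fullsib_prop + halfsib_prop must be <= 1.")
  }
  if (length(n_alleles) == 1L) n_alleles <- rep(n_alleles, n_loci)
  if (length(n_alleles) != n_loci || any(n_alleles < 2)) {
    abort("`n_alleles` must be >= 2 for every locus.")
  }
  if (founder_conc <= 0) abort("`founder_conc` must be positive.")

  ids <- structure$individual
  n_ind <- length(ids)
  loci <- sprintf("L%02d", seq_len(n_loci))

  with_seed_if(seed, {
    # Per-locus founder allele frequencies (symmetric Dirichlet).
    founder_freqs <- lapply(seq_len(n_loci), function(l) {
      w <- stats::rgamma(n_alleles[l], shape = founder_conc)
      p <- w / sum(w)
      names(p) <- seq_len(n_alleles[l])
      p
    })
    names(founder_freqs) <- loci

    # Assign family roles within each party: the first round(prop * size)
    # members form full-sib families (pairs; an odd leftover joins the last
    # family), the next block paternal half-sib families.
    chunk_families <- function(members) {
      n <- length(members)
      if (n < 2L) return(list())
      n_fam <- n %/% 2L
      fam <- rep(seq_len(n_fam), each = 2L)
      if (n %% 2L == 1L) fam <- c(fam, n_fam)
      split(members, fam)
    }

    father_of <- setNames(rep(NA_character_, n_ind), ids)
    mother_of <- setNames(rep(NA_character_, n_ind), ids)
    fam_type <- character(0)   # per family: "full" or "half"
    fam_members <- list()
    parties <- split(ids, structure$party[match(ids, structure$individual)])
    for (members in parties) {
      size <- length(members)
      n_f <- round(fullsib_prop * size)
      n_h <- round(halfsib_prop * size)
      if (n_f + n_h > size) {
        abort("Sib proportions are incompatible with a party size after rounding.")
      }
      full_ids <- members[seq_len(n_f)]
      half_ids <- members[n_f + seq_len(n_h)]
      for (fam in chunk_families(full_ids)) {
        fam_type <- c(fam_type, "full")
        fam_members <- c(fam_members, list(fam))
      }
      for (fam in chunk_families(half_ids)) {
        fam_type <- c(fam_type, "half")
        fam_members <- c(fam_members, list(fam))
      }
    }

    # Create parents: one father per family; full sibs share the mother,
    # half sibs get one mother each.
    parent_ids <- character(0)
    next_parent <- function() {
      pid <- sprintf("par%03d", length(parent_ids) + 1L)
      parent_ids <<- c(parent_ids, pid)
      pid
    }
    for (f in seq_along(fam_members)) {
      members <- fam_members[[f]]
      father <- next_parent()
      father_of[members] <- father
      if (fam_type[f] == "full") {
        mother <- next_parent()
        mother_of[members] <- mother
      } else {
        mother_of[members] <- vapply(members, function(m) next_parent(), "")
      }
    }

    sample_founder_alleles <- function(n) {
      vapply(seq_len(n_loci), function(l) {
        as.integer(sample(as.integer(names(founder_freqs[[l]])), n,
                          replace = TRUE, prob = founder_freqs[[l]]))
      }, integer(n))
    }
    n_par <- length(parent_ids)
    P1 <- P2 <- NULL
    if (n_par > 0L) {
      P1 <- matrix(sample_founder_alleles(n_par), n_par, n_loci,
                   dimnames = list(parent_ids, loci))
      P2 <- matrix(sample_founder_alleles(n_par), n_par, n_loci,
                   dimnames = list(parent_ids, loci))
    }

    A1 <- matrix(sample_founder_alleles(n_ind), n_ind, n_loci,
                 dimnames = list(ids, loci))
    A2 <- matrix(sample_founder_alleles(n_ind), n_ind, n_loci,
                 dimnames = list(ids, loci))
    offspring <- ids[!is.na(father_of[ids])]
    for (ind in offspring) {
      pick_f <- runif(n_loci) < 0.5
      pick_m <- runif(n_loci) < 0.5
      f <- father_of[ind]; m <- mother_of[ind]
      A1[ind, ] <- ifelse(pick_f, P1[f, ], P2[f, ])
      A2[ind, ] <- ifelse(pick_m, P1[m, ], P2[m, ])
    }

    # Pedigree-expected relatedness.
    kin <- matrix(0, n_ind, n_ind, dimnames = list(ids, ids))
    for (f in seq_along(fam_members)) {
      members <- fam_members[[f]]
      r <- if (fam_type[f] == "full") 0.5 else 0.25
      kin[members, members] <- r
    }
    diag(kin) <- 1

    # Missing completely at random, whole genotypes.
    if (missing_rate > 0) {
      miss <- matrix(runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
      A1[miss] <- NA_integer_
      A2[miss] <- NA_integer_
    }

    geno <- tibble::tibble(individual = ids)
    for (l in seq_len(n_loci)) {
      geno[[paste0(loci[l], "_a1")]] <- A1[, l]
      geno[[paste0(loci[l], "_a2")]] <- A2[, l]
    }

    parent_genotypes <- NULL
    if (n_par > 0L) {
      parent_genotypes <- list(a1 = P1, a2 = P2)
    }

    structure(
      list(
        genotypes = geno,
        true_kinship = dyad_matrix(kin, ids = ids, kind = "kinship"),
        founder_freqs = founder_freqs,
        pedigree = tibble::tibble(individual = ids,
                                  father = unname(father_of[ids]),
                                  mother = unname(mother_of[ids])),
        parent_genotypes = parent_genotypes,
        config = list(n_loci = n_loci, n_alleles = n_alleles,
                      founder_conc = founder_conc,
                      fullsib_prop = fullsib_prop,
                      halfsib_prop = halfsib_prop,
                      missing_rate = missing_rate, seed = seed)
      ),
      class = "genotype_sim"
    )
  })
}

#' Simulate a complete study (structure + calls + genotypes)
#'
#' Convenience wrapper producing every input the analysis pipeline needs,
#' with consistent individual ids across components.
#'
#' @param structure A social-structure table; defaults to
#'   [default_structure()].
#' @param feature_args Named list of arguments forwarded to
#'   [simulate_features()].
#' @param genotype_args Named list of arguments forwarded to
#'   [simulate_genotypes()].
#' @param seed Integer master seed; independent sub-seeds are derived for
#'   the two generators so each component is individually reproducible.
#' @return A list of class `simulated_study` with elements `structure`,
#'   `features`, `genotypes`, `true_kinship` and `config`.
#' @export
simulate_study <- function(structure = default_structure(),
                           feature_args = list(),
                           genotype_args = list(),
                           seed = 1L) {
  structure <- validate_structure(structure)
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max, 2L))
  features <- do.call(simulate_features,
                      c(list(structure = structure, seed = seeds[1]),
                        feature_args))
  gsim <- do.call(simulate_genotypes,
                  c(list(structure = structure, seed = seeds[2]),
                    genotype_args))
  structure(
    list(structure = structure,
         features = features,
         genotypes = gsim$genotypes,
         true_kinship = gsim$true_kinship,
         genotype_sim = gsim,
         config = list(seed = seed, feature_args = feature_args,
                       genotype_args = genotype_args)),
    class = "simulated_study"
  )
}
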