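#' Run the full vocal-convergence study
#'
#' Orchestrates the complete analysis on supplied tables or on a freshly
#' simulated study: locus screening and Wang relatedness; stepwise DFA,
#' classification (resubstitution and leave-one-out), pairwise-F and
#' ln(1+F) dissimilarity; the permuted DFA; the four same-level contrasts
#' (relatedness and acoustic dissimilarity, at gang and party-within-gang
#' level); the acoustic-vs-genetic Mantel test; the relatedness-quartile
#' contrast; and Cohen's d for each contrast.
#'
#' Directional alternatives follow the convergence hypotheses: same-level
#' dyads are expected to be MORE related (`"less"` on different - same for
#' relatedness) and LESS dissimilar (`"greater"` for the log-F
#' dissimilarity); the continuous Mantel test expects dissimilarity to
#' DECREASE with relatedness (`"less"` on r).
#'
#' A single master seed deterministically spawns per-stage seeds, so each
#' stage is individually reproducible and the whole report is a pure
#' function of its inputs and the seed.
#'
#' @param structure,features,genotypes Input tables; any that are `NULL`
#'   are simulated (see [simulate_study()]).
#' @param sim Named list forwarded to [simulate_study()]
#'   (`feature_args`, `genotype_args`) when simulating.
#' @param p_in,p_out Stepwise DFA entry/removal probabilities.
#' @param include_pdfa Run the (comparatively expensive) permuted DFA.
#' @param include_loo Run leave-one-out validation of the full-data DFA
#'   (exact refits per held-out call; the slowest classification step).
#' @param pdfa_args Named list forwarded to [pdfa()].
#' @param hwe_n_mc Monte-Carlo re-pairings for the HWE test.
#' @param null_threshold,hwe_alpha Locus-exclusion thresholds (see
#'   [locus_report()]).
#' @param n_perm_gang,n_perm_party,n_perm_mantel,n_perm_quartile
#'   Permutation counts for the gang-level contrasts, the restricted
#'   party-within-gang contrasts, the continuous Mantel test and the
#'   quartile contrast.
#' @param q Tail proportion for the quartile contrast.
#' @param seed Master seed.
#' @return A list of class `study_report`; see [write_report()].
#' @export
run_study <- function(structure = NULL, features = NULL, genotypes = NULL,
                      sim = list(),
                      p_in = 0.05, p_out = 0.10,
                      include_pdfa = TRUE, include_loo = TRUE,
                      pdfa_args = list(n_subsets = 5, n_permutations = 100),
                      hwe_n_mc = 1e4,
                      null_threshold = 0.05, hwe_alpha = 0.05,
                      n_perm_gang = 1000, n_perm_party = 10000,
                      n_perm_mantel = 1000, n_perm_quartile = 1000,
                      q = 0.25, seed = 1L) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 8L))
  partial <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            partial = partial)
    })
  }

  true_kinship <- NULL
  if (is.null(features) || is.null(genotypes) || is.null(structure)) {
    simdata <- stage("simulate", do.call(simulate_study, c(
      list(structure = structure %||% default_structure(), seed = seeds[1]),
      sim)))
    structure <- simdata$structure
    features <- features %||% simdata$features
    genotypes <- genotypes %||% simdata$genotypes
    true_kinship <- simdata$true_kinship
  }
  structure <- validate_structure(structure, require_full = TRUE)
  if (!setequal(structure$individual, unique(features$individual)) ||
      !setequal(structure$individual, genotypes$individual)) {
    abort("Individual ids differ between structure, features and genotypes.")
  }
  partial$structure <- structure

  # ---- genetics --------------------------------------------------------
  loci_rep <- stage("locus_screening",
                    locus_report(genotypes, null_threshold = null_threshold,
                                 hwe_alpha = hwe_alpha, n_mc = hwe_n_mc,
                                 seed = seeds[2]))
  retained <- stage("locus_screening", filter_loci(loci_rep))
  partial$locus_report <- loci_rep
  W <- stage("relatedness", wang_relatedness(genotypes, loci = retained))
  partial$relatedness <- W

  # ---- acoustics -------------------------------------------------------
  model <- stage("stepwise_dfa",
                 dfa_stepwise(features, p_in = p_in, p_out = p_out))
  partial$dfa <- model
  if (model$empty) abort("Stage 'stepwise_dfa' failed: empty selection.",
                         partial = partial)
  resub <- stage("classification", dfa_classify(model, features, "resubstitution"))
  loo <- if (include_loo) {
    stage("classification", dfa_classify(model, features, "leave_one_out"))
  } else NULL
  fmat <- stage("pairwise_f", pairwise_f_matrix(model))
  lnf <- stage("pairwise_f", dissimilarity_from_f(fmat))
  partial$dissimilarity <- lnf

  pdfa_res <- NULL
  if (include_pdfa) {
    pdfa_res <- stage("pdfa", do.call(pdfa, c(
      list(features = features, p_in = p_in, p_out = p_out, seed = seeds[3]),
      pdfa_args)))
  }

  # ---- dyadic tests ----------------------------------------------------
  rel_gang <- stage("contrasts", categorical_mantel(
    W, structure, "gang", n_permutations = n_perm_gang,
    alternative = "less", seed = seeds[4]))
  rel_party <- stage("contrasts", categorical_mantel(
    W, structure, "party", n_permutations = n_perm_party,
    alternative = "less", seed = seeds[5]))
  ac_gang <- stage("contrasts", categorical_mantel(
    lnf, structure, "gang", n_permutations = n_perm_gang,
    alternative = "greater", seed = seeds[6]))
  ac_party <- stage("contrasts", categorical_mantel(
    lnf, structure, "party", n_permutations = n_perm_party,
    alternative = "greater", seed = seeds[7]))
  mantel_ag <- stage("mantel", mantel_test(
    lnf, W, n_permutations = n_perm_mantel, alternative = "less",
    seed = seeds[8]))
  quart <- stage("quartile", quartile_contrast(
    W, lnf, q = q, n_permutations = n_perm_quartile,
    alternative = "less", seed = seeds[8]))

  # ---- effect sizes (same-level minus different-level convention) ------
  eff <- stage("effects", dplyr::bind_rows(
    dplyr::mutate(cohens_d(rel_gang$same_values, rel_gang$different_values),
                  contrast = "relatedness_gang", .before = 1),
    dplyr::mutate(cohens_d(rel_party$same_values, rel_party$different_values),
                  contrast = "relatedness_party", .before = 1),
    dplyr::mutate(cohens_d(ac_gang$same_values, ac_gang$different_values),
                  contrast = "dissimilarity_gang", .before = 1),
    dplyr::mutate(cohens_d(ac_party$same_values, ac_party$different_values),
                  contrast = "dissimilarity_party", .before = 1),
    dplyr::mutate(cohens_d(ac_party$same_values, ac_gang$different_values),
                  contrast = "dissimilarity_same_party_vs_other_gang",
                  .before = 1)
  ))

  gangs <- split(structure$individual, structure$gang)
  n <- nrow(structure)
  report <- structure(
    list(
      seed = seed, stage_seeds = seeds,
      config = list(p_in = p_in, p_out = p_out,
                    null_threshold = null_threshold, hwe_alpha = hwe_alpha,
                    hwe_n_mc = hwe_n_mc,
                    n_perm_gang = n_perm_gang, n_perm_party = n_perm_party,
                    n_perm_mantel = n_perm_mantel,
                    n_perm_quartile = n_perm_quartile, q = q,
                    include_pdfa = include_pdfa, pdfa_args = pdfa_args,
                    sim = sim),
      structure = structure,
      n_individuals = n,
      n_dyads_total = n * (n - 1) / 2,
      n_dyads_within_gang = sum(vapply(gangs, function(g)
        choose(length(g), 2), numeric(1))),
      calls = summarise_calls(features, structure),
      locus_report = loci_rep,
      retained_loci = retained,
      relatedness = W,
      true_kinship = true_kinship,
      dfa = model,
      classification = list(resubstitution = resub, leave_one_out = loo),
      pairwise_f = fmat,
      dissimilarity = lnf,
      pdfa = pdfa_res,
      contrasts = list(relatedness_gang = rel_gang,
                       relatedness_party = rel_party,
                       dissimilarity_gang = ac_gang,
                       dissimilarity_party = ac_party),
      mantel_acoustic_genetic = mantel_ag,
      quartile = quart,
      effects = eff,
      means = list(logF_same_party = ac_party$mean_same,
                   logF_same_gang = ac_gang$mean_same,
                   logF_different_gang = ac_gang$mean_different)
    ),
    class = "study_report"
  )
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Vocal convergence study report ==\n")
  cat(sprintf("%d individuals; %d dyads (%d within gangs); seed %d\n",
              x$n_individuals, x$n_dyads_total, x$n_dyads_within_gang, x$seed))
  cat(sprintf("Loci: %d screened, %d retained\n",
              nrow(x$locus_report), length(x$retained_loci)))
  loo_txt <- if (is.null(x$classification$leave_one_out)) "skipped" else
    sprintf("%.1f%%", x$classification$leave_one_out$percent_correct)
  cat(sprintf("DFA: %d features selected; correct %.1f%% (resub), %s (LOO); chance %.1f%%\n",
              x$dfa$p, x$classification$resubstitution$percent_correct,
              loo_txt, x$classification$resubstitution$chance_pct))
  if (!is.null(x$pdfa)) {
    cat(sprintf("pDFA: %.1f%% (n = %d balanced calls), p = %.4g\n",
                x$pdfa$observed, x$pdfa$n_calls_used, x$pdfa$p_value))
  }
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("%-22s diff-same = %8.4f  p = %.4g\n", nm,
                ct$test$observed, ct$test$p_value))
  }
  cat(sprintf("Mantel dissimilarity~relatedness: r = %.4f, p = %.4g\n",
              x$mantel_acoustic_genetic$observed,
              x$mantel_acoustic_genetic$p_value))
  cat(sprintf("Quartile contrast: high-low = %.4f (n = %d), p = %.4g\n",
              x$quartile$test$observed, x$quartile$n_total,
              x$quartile$test$p_value))
  invisible(x)
}

# Serialisable subset of a study report (scalars and small tables).
report_to_list <- function(x) {
  ct <- lapply(x$contrasts, function(c)
    as.list(glance(c)[, c("observed", "p_value", "n_permutations",
                          "alternative", "scheme", "level",
                          "mean_same", "mean_different",
                          "n_same", "n_different")]))
  list(
    seed = x$seed,
    config = x$config,
    n_individuals = x$n_individuals,
    n_dyads_total = x$n_dyads_total,
    n_dyads_within_gang = x$n_dyads_within_gang,
    n_calls_total = x$calls$n_calls_total,
    mean_calls = x$calls$mean_calls,
    loci = list(n_screened = nrow(x$locus_report),
                n_retained = length(x$retained_loci),
                retained = as.character(x$retained_loci)),
    dfa = as.list(glance(x$dfa)),
    classification = list(
      resubstitution_pct = x$classification$resubstitution$percent_correct,
      leave_one_out_pct = if (is.null(x$classification$leave_one_out))
        NULL else x$classification$leave_one_out$percent_correct,
      chance_pct = x$classification$resubstitution$chance_pct),
    pdfa = if (is.null(x$pdfa)) NULL else list(
      observed_pct = x$pdfa$observed,
      chance_pct = x$pdfa$chance_pct,
      p_value = x$pdfa$p_value,
      n_calls_used = x$pdfa$n_calls_used,
      n_permutations = x$pdfa$n_permutations),
    contrasts = ct,
    mantel_acoustic_genetic = list(
      r = x$mantel_acoustic_genetic$observed,
      p_value = x$mantel_acoustic_genetic$p_value,
      n_permutations = x$mantel_acoustic_genetic$n_permutations),
    quartile = list(
      high_minus_low = x$quartile$test$observed,
      p_value = x$quartile$test$p_value,
      n_high = x$quartile$n_high, n_low = x$quartile$n_low,
      lo_threshold = x$quartile$lo_threshold,
      hi_threshold = x$quartile$hi_threshold),
    effects = lapply(seq_len(nrow(x$effects)), function(i)
      as.list(x$effects[i, c("contrast", "d", "ci_low", "ci_high",
                             "n1", "n2")])),
    means = x$means
  )
}

#' Write a study report to disk
#'
#' Writes the machine-readable JSON report, a human-readable Markdown
#' summary, and all dyadic matrices plus the locus report as CSV. The
#' configuration and every seed are echoed into the JSON so the run can be
#' reproduced.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "study_report")) abort("`report` must be a study_report.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory %s.", dir))
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_dyad_matrix(report$relatedness, file.path(dir, "relatedness_W.csv"))
  write_dyad_matrix(report$pairwise_f, file.path(dir, "pairwise_F.csv"))
  write_dyad_matrix(report$dissimilarity, file.path(dir, "dissimilarity_lnF.csv"))
  if (!is.null(report$true_kinship)) {
    write_dyad_matrix(report$true_kinship, file.path(dir, "true_kinship.csv"))
  }
  readr::write_csv(report$locus_report, file.path(dir, "locus_report.csv"))
  md <- c("# Vocal convergence study report",
          "",
          utils::capture.output(print(report)))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
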