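---
title: "Testing vocal convergence in a nested society: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing vocal convergence in a nested society: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalconv)
```

## The question

In multi-level animal societies — the motivating case is the Guinea baboon,
where one-male units aggregate into *parties* and parties into *gangs* —
males that interact frequently may come to sound alike. Because males are
philopatric, frequent interaction partners are also more closely related, so
a naive acoustic comparison confounds social exposure with shared genes.
`vocalconv` implements the full analysis that separates the two: an acoustic
dissimilarity between every pair of males derived from a discriminant
analysis of their calls, a genetic relatedness between every pair estimated
from microsatellites, and a family of permutation tests that ask (i) whether
calls converge within social levels, (ii) whether relatedness is elevated
within those levels, and (iii) whether acoustic similarity tracks
relatedness once both are in hand.

All analyses work on *dyads*: with $n$ males there are $\binom{n}{2}$
unordered pairs, and every quantity of interest is a symmetric $n \times n$
matrix (`dyad_matrix`). With the default design of 27 males in two gangs of
two parties (6+7 and 5+9), there are 351 dyads in total and 169 dyads within
gangs.

## Acoustic dissimilarity from a stepwise DFA

Calls are rows of a feature table (dozens of spectral/temporal parameters
per call); individual identity is the grouping variable. Feature selection
uses the classical stepwise procedure on Wilks' lambda: for the current set
$S$ (size $p$), the F-to-enter of a candidate $x$ is

$$F = \frac{N - g - p}{g - 1}\left(\frac{\Lambda(S)}{\Lambda(S \cup x)} - 1\right),$$

with $N$ calls and $g$ groups; the candidate with the smallest
probability-of-F enters while $p < P_{in}$, and an entered feature leaves
when its probability-of-F exceeds $P_{out}$ (defaults $P_{in} = 0.05$,
$P_{out} = 0.10$; $P_{in} \le P_{out}$ is enforced because it guards
entry/removal cycles). Ties in the probability are broken by the larger
partial F, then by column order, so the procedure is deterministic.

Classification uses the linear rule with **equal priors**: a call is
assigned to the group whose mean is nearest in Mahalanobis distance under
the pooled within-group covariance of the selected features. Group sizes
are unbalanced in this design, but equal priors match the "chance = $1/g$"
framing used to judge the classifier ($100/27 \approx 3.7\%$).
Leave-one-out validation refits the group means and pooled covariance
exactly for every held-out call; no down-dating shortcuts are used, since
correctness matters more than speed at this scale. Individuals contributing
a single call cannot be held out and are excluded from the LOO set (their
call still trains the other folds) with a log entry.

The dyadic acoustic distance between males $i$ and $j$ is the pairwise
between-group F:

$$F_{ij} = \frac{N - g - p + 1}{p\,(N - g)} \cdot \frac{n_i n_j}{n_i + n_j} \cdot D^2_{ij},$$

where $D^2_{ij}$ is the squared Mahalanobis distance between the two group
means. For $g = 2$ this is exactly the two-sample Hotelling $T^2$ F
statistic, which the test suite verifies against an independent closed-form
oracle at $10^{-8}$ relative tolerance. The matrix is computed **from the
final fitted model** (not averaged over stepwise steps — the procedure's
description leaves this open; the final-model reading is the one that makes
the $g=2$ equivalence exact) and then transformed elementwise to
$\ln(1+F)$, which tames the long right tail while preserving dyad order.

## The permuted DFA

Raw classification rates are inflated when a few individuals contribute
most calls. The permuted DFA (`pdfa()`) controls for this: the observed
statistic is the mean, over `n_subsets` balanced subsets
(`calls_per_class` calls per male, default the minimum observed), of the
LOO correct-classification rate, with stepwise selection **re-run inside
every subset** so that feature selection cannot leak into the null. The
null distribution repeats the identical procedure on tables whose
individual labels were permuted across calls; the p-value uses the add-one
correction, $p = (\#\{null \ge obs\} + 1)/(B + 1)$, which is valid under
exchangeability and makes $1/(B+1)$ the attainable minimum. Defaults
(`n_subsets = 10`, `n_permutations = 100`; `run_study()` uses 5/100) are
desk-scale choices — the underlying method is usually run with more
permutations, and both are configurable. Cross-validation inside the pDFA
is leave-one-out, matching the headline validation mode. A subset on which
no feature qualifies for entry scores exactly the chance rate and is
counted in the result.

## Relatedness from microsatellites

### Locus screening

Each locus gets an exact Hardy–Weinberg test conditioned on its allele
counts: the p-value is the total probability, under random union of
gametes, of genotype arrays no more probable than the observed one. The
full array space is enumerated by depth-first search when its estimated
size is below `enum_limit` (2e5 states); otherwise the conditional
distribution is sampled by Monte-Carlo re-pairings of the allele vector
(default $10^5$, seeded, add-one corrected). Monomorphic loci get $p = 1$
by convention. The null-allele screen is the heterozygote-deficit
estimator $r = (H_e - H_o)/(1 + H_e)$; a locus is excluded only when
**both** flags fire — null-allele estimate above 0.05 *and* HWE $p < 0.05$
— mirroring the conjunctive practice of excluding a locus only on joint
evidence. Excluding on either flag alone would be too aggressive: related
individuals in the sample depress heterozygosity and perturb HWE even at
clean loci.

### The Wang moment estimator

For a dyad at one locus, the two genotypes fall into one of four
similarity categories: identical; one shared allele involving a homozygote
(AiAi–AiAj); one shared allele between heterozygotes (AiAj–AiAk); no
shared allele. Writing $\Phi$ and $\phi$ for the probabilities that the
dyad shares two, respectively exactly one, pair of alleles identical by
descent, the category probabilities are linear:

$$E(P_1) = b + (1-b)\Phi + c\,\phi,\quad
  E(P_2) = d - d\,\Phi + e\,\phi,\quad
  E(P_3) = f - f\,\Phi + g\,\phi,$$

with coefficients polynomial in the allele-frequency moments
$a_m = \sum_i p_i^m$:
$b = 2a_2^2 - a_4$, $c = a_2 - b$, $d = 4(a_3 - a_4)$,
$e = 2(a_2 - 3a_3 + 2a_4)$, $f = 4(a_2 - a_2^2 - 2a_3 + 2a_4)$,
$g = 1 - 7a_2 + 4a_2^2 + 10a_3 - 8a_4$. These were derived from first
principles for this package (the derivation is a direct conditional
enumeration of the category events given 0, 1 or 2 IBD pairs) and verified
against brute-force simulation. The two unknowns are estimated from the
three equations by least squares; relatedness is $\hat W = \hat\Phi +
\hat\phi/2$, so $\hat W \approx 0.5$ for first-degree relatives and
$\approx 0$ for non-relatives, with negative values meaning "shares fewer
alleles than random members of the sample". Estimates are never clamped.

Loci are combined by weighting both the category indicators and the
coefficient sets with $w_\ell \propto 1/u_\ell$, $u_\ell = 2a_2 - a_3$,
which down-weights weakly polymorphic loci; because each locus's moment
equations are individually unbiased, the weights affect variance only, not
consistency. Frequency moments use exact falling-factorial (small-sample)
corrections when estimated from allele counts. By default frequencies come
from the full sample including the focal dyad (the common default in
relatedness software); `frequency_scope = "leave_two_out"` removes the
dyad's four alleles first. Dyads are estimated over their mutually typed
loci with the weights renormalised, so missing genotypes reduce precision
rather than discard dyads; a dyad with no shared typed locus is `NA` and
counted.

Calibration is checked by pedigree simulation: 500 parent–offspring dyads
at 200 loci recover a mean within 0.05 of 0.5, 500 unrelated dyads a mean
within 0.03 of 0, and simulated full-sib / half-sib / unrelated classes are
rank-ordered.

## Dyadic permutation tests

`mantel_test()` correlates the upper triangles of two dyadic matrices and
builds the null by simultaneous row/column permutation of the second
matrix's individuals. `categorical_mantel()` contrasts mean dyadic values
between same-group and different-group dyads at a social level; the
statistic is the difference of means (different − same), which orders
permutations identically to the point-biserial Mantel r but is reported on
the scale of the data — the same contrast on which Cohen's d is computed.

Permutation schemes follow the exchangeability structure:

* **gang level** — individuals are freely permuted (default 1000
  permutations);
* **party level** — party labels are permuted only among males of the same
  gang (`restricted_permute()`), and the dyad universe is restricted to
  same-gang dyads (between-gang dyads are uninformative about party effects
  and cannot change membership under the restricted scheme). Default
  10 000 permutations, matching the higher resolution used for this test.

The restricted scheme is what keeps the party test honest when gangs
differ: the acceptance suite verifies that its type-I error stays at
$\alpha$ when the dyadic values carry a pure gang effect and no party
effect. For six or fewer individuals both tests can enumerate the full
permutation set (`exact = TRUE`), and the suite checks the enumerated
p-values against independent brute-force enumeration.

Tests are one-sided by default in the direction of the convergence
hypotheses — same-level dyads more related (`"less"` on different − same
for relatedness), less dissimilar (`"greater"` for $\ln(1+F)$), and
dissimilarity decreasing with relatedness (`"less"` on the Mantel r);
two-sided alternatives are a flag away. All p-values use the add-one
correction and every result records its scheme, permutation count and
seed.

`quartile_contrast()` implements the robustness check against noisy dyadic
relatedness: dyads strictly above the $1-q$ quantile of $\hat W$ versus
strictly below the $q$ quantile, contrasted on acoustic dissimilarity by
permuting the high/low labels. Strict inequalities mean ties at the
thresholds drop out; with 351 continuous values and $q = 0.25$ the two
sides hold 88 + 88 = 176 dyads. A constant $\hat W$ leaves both sides
empty and raises an error with a tie report rather than a silent fallback.

`cohens_d()` uses the $(n-1)$-weighted pooled SD and the large-sample
normal CI, treating dyadic values as independent. They are not; the
package reproduces the conventional effect-size computation and carries
the caveat in the output (`note` column) instead of correcting it, because
the permutation tests — not the CI — carry the inference. The reported
sign convention is first sample minus second; `run_study()` reports
contrasts as same-level minus different-level.

## The synthetic-data generator

No field recordings or genotypes ship with the package; the generator
produces data with the statistical structure the analysis assumes.

* **Calls** (`simulate_features()`): each feature value is gang effect +
  party effect + individual effect + residual, all zero-mean normal with
  per-level SDs shared across features (the simplest model that produces
  the nested signal). Call counts per male are uniform on an integer range
  — only the min/mean/max of the real design are known (5/28/127), not the
  distribution. Defaults: 82 features, calls 5–127, $\sigma_{gang} =
  \sigma_{party} = 0.4$, $\sigma_{ind} = 1$, $\sigma_{resid} = 2$ —
  individual signatures dominate the social-level effects, the regime the
  real data show (individual discriminability far above chance, small
  dyadic effect sizes at the social levels).
* **Genotypes** (`simulate_genotypes()`): founder allele frequencies are
  symmetric-Dirichlet per locus (microsatellite spectra are multiallelic
  and skewed); a configurable fraction of each party's males forms
  full-sib families and another fraction paternal half-sib families, with
  Mendelian sampling from simulated parents; everyone else is a founder.
  Defaults: 23 loci, 8 alleles, fullsib/halfsib proportions 0.3/0.3 —
  mean pedigree kinship within parties ≈ 0.03–0.05, the order reported for
  male philopatry. Missingness is completely at random (2%), whole
  genotypes at a time; nothing is known about the real missingness
  process. The pedigree expectation of every dyad is returned as
  `true_kinship` (0.5 / 0.25 / 0; unit diagonal), and the simulated
  parents' genotypes are kept for provenance checks.

What the generator does **not** emulate: call-context heterogeneity
(context tables for the real data are not public), temporal drift across
recording years, feature-specific variance components, genotyping-error
mechanisms (stutter, allelic dropout), mutation, or multi-generation
pedigrees. Passing tests therefore show that the *pipeline* recovers the
structure it assumes, not that real grunts satisfy those assumptions.

### An induced correlation, and the dissociation regime

One property of the generator deserves emphasis because it constrains what
"no acoustic–genetic coupling" can show. Acoustic effects are statistically
independent of the pedigree by construction, yet when *both* channels carry
social structure, the marginal Mantel correlation between $\ln(1+F)$ and
$\hat W$ is not zero in expectation: same-level dyads are simultaneously
less dissimilar and more related, which induces
$r \approx -\kappa\, d_F\, d_W$ (with $\kappa \approx p(1-p)$ for
within-level dyad share $p$, and $d_F$, $d_W$ the dyadic effect sizes of
the two channels). The dissociation the real study reports — within-level
convergence with $r \approx 0$ — is therefore only *visible* when the
dyadic effect sizes are modest, which is the regime field studies report
(d in the 0.15–0.5 range). The acceptance suite probes this with
$\sigma_{gang} = 0.35$, $\sigma_{party} = 0.45$, fullsib/halfsib
0.4/0.3: across seeds, both acoustic within-level contrasts fire while the
acoustic–genetic Mantel test stays null. Cranking both channels up instead
produces a clearly negative marginal correlation — not a bug, but the
confounding that motivates measuring both channels in the first place.

## Numerical choices

* Wilks' lambdas are computed from log-determinants; a singular
  within-group scatter for a candidate set maps to $\Lambda = 0$, i.e. an
  infinite partial F (a perfect discriminator enters immediately, and
  selection stops once separation is perfect).
* Candidate features whose within-group variance conditional on the
  selected set falls below $1/10^{12}$ of their marginal variance are
  skipped as rank deficient, and each skip is logged in the model's
  `skipped` field.
* The pairwise-F computation refuses a singular pooled covariance rather
  than regularising silently.
* Permutation p-values compare with a $10^{-12}$ tolerance so that exact
  ties (e.g. the all-equal case) count as "as extreme".
* Every stochastic function takes a `seed`; `run_study()` derives
  per-stage seeds from one master seed so stages are individually
  reproducible and the whole report is a pure function of inputs + seed.

## Problem sizes in the test suite

The suite runs the full pipeline at the real design size (27 males, 82
features, 23 loci) for the structural and dissociation checks, and scales
the Monte-Carlo calibrations to desk size as a deliberate choice: type-I
error of the permutation tests with 500 replicates at 99 (Mantel-type) or
39 (pDFA) permutations; estimator recovery with 500 dyads at 200 loci;
exhaustive enumerations at 5–6 individuals where the full permutation
group is small enough to enumerate. The acceptance script
(`scripts/acceptance.R`) runs one complete study at full
permutation resolution (1000, and 10 000 for the party-within-gang tests).

## Known limitations

* The stepwise criterion reproduces the classical probability-of-F
  procedure; other selection criteria (AIC-style, cross-validated) are out
  of scope.
* Only the Wang estimator is implemented; the estimator-comparison step of
  the original workflow (choosing among Wang, Queller–Goodnight, etc.) is
  not reproduced because the comparison table it relied on is not public.
* CIs for Cohen's d ignore dyadic non-independence (documented above).
* The pDFA implements the individual-identity design only, not crossed
  designs with a separate control factor.
* GenePop import is not provided; the genotype dialect is the two-column
  CSV written by the generator.
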