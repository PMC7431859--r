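---
title: "Methods: PHBR presentation scoring and immune-selection modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PHBR presentation scoring and immune-selection modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Tumors evolve under surveillance by T cells, which can only recognize a
somatic mutation if the mutant peptide is presented by the patient's own
MHC molecules. If surveillance eliminates well-presented driver mutations
(immunoediting), the drivers still observed at diagnosis should be biased
toward *poor* presentation — and if the strength of surveillance differs
between patient groups (females vs males, younger vs older), the size of
that bias should differ too. `immunosel` implements the full quantitative
machinery for asking that question: patient-specific presentation scores
for driver mutations, cohort statistics comparing observed-mutation scores
between groups with permutation controls, and mixed-effects logistic models
that estimate how presentation interacts with sex and age in shaping which
mutations occur. Because the real cohorts behind such analyses are
access-controlled, the package ships a synthetic-cohort generator whose
data-generating process is exactly the model the analysis fits, so every
stage is testable against known ground truth.

# The PHBR score

A patient's ability to present a mutated residue is summarized by the
harmonic-mean best rank. For one MHC class:

1. Enumerate all peptide windows over the mutant protein that contain at
   least one altered residue (class I lengths 8--11, class II length 15;
   both configurable). Windows are clipped at the protein termini, so an
   interior missense mutation has 38 class I and 15 class II windows.
2. For each of the patient's scoring molecules, take the *best* (minimum)
   percentile rank over those windows — the molecule's single best chance
   of presenting any mutation-covering peptide. Percentile ranks come from
   an affinity predictor; lower = better presentation.
3. Aggregate the per-molecule best ranks `s_1..s_n` by harmonic mean,
   `PHBR = n / sum(1/s_k)`.

The scoring slots are fixed per class: 6 class I slots (HLA-A/B/C, two
each; homozygous alleles occupy two slots and so weight the mean), and 12
class II slots — the 4 DPA1/DPB1 alpha–beta combinations, the 4 DQA1/DQB1
combinations, and each DRB1 allele twice (the DR alpha chain is invariant,
so doubling keeps DR on the same footing as DP and DQ). The harmonic mean
is dominated by the smallest slot value: one well-presenting molecule is
enough to make a mutation visible, which is the immunological rationale
for this aggregation. A *low* PHBR means good presentation; immunoediting
predicts observed drivers are biased toward *high* PHBR.

Binding-category thresholds on the percentile-rank scale are 0.5 (strong)
and 2 (weak) for class I, 2 and 10 for class II. The package assigns
boundary values to the poorer category (strict `<`); the cutoffs are
conventional and the convention at the boundary is declared rather than
standard, so it is tested explicitly.

# The affinity backend

External predictors are behind a one-function contract:
`backend(peptides, molecules) -> percentile ranks in (0, 100]`. Tables of
precomputed ranks from any real predictor can be served through
`make_table_backend()`. The in-repo `synthetic_rank_backend()` is a pure
hash of (peptide, molecule, seed): deterministic bit-for-bit, marginally
close to Uniform(0, 100] over random peptides, and molecule-specific. Each
molecule additionally carries a seeded anchor-residue preference at peptide
position 2 (about 10% of peptides match, and matching peptides have their
unit rank raised to the power 1.15, i.e. mildly better ranks). The
transform is deliberately mild so that the marginal distribution stays
within a Kolmogorov–Smirnov 1% band of uniform at n = 10,000 while still
giving different genotypes structurally different PHBR landscapes.

What the synthetic backend does *not* emulate: real binding-motif
structure, length preferences, or correlations between similar alleles.
Tests passing on it demonstrate the pipeline's correctness and statistical
calibration, not predictive accuracy on real peptide–MHC pairs.

# The occurrence models

Let `y_ij` indicate that patient `i` carries driver mutation `j`, and let
`x1_ij`, `x2_ij` be the centered natural logs of the patient's PHBR-I and
PHBR-II scores for that mutation. The sex model is

```
logit P(y_ij = 1) = b0 + b1 x1_ij + b2 x2_ij + b3 Sex_i
                    + b4 (x1_ij * Sex_i) + b5 (x2_ij * Sex_i) + eta_i
```

with sex coded 0/1 for males/females then centered, and
`eta_i ~ N(0, theta_eta)` a per-patient random intercept absorbing
patient-to-patient mutation-rate differences. The age model replaces sex
with centered age in years; two further models use a single score class
with both sex and age and both interactions. Positive `b1`/`b2` is the
immunoediting signature (poorly presented mutations are more likely to be
observed); positive score-by-sex interactions mean stronger selection in
females, negative score-by-age interactions stronger selection in the
young. An intercept is always included for identifiability and reported
alongside the printed terms.

Fitting uses a logistic GLMM with Laplace approximation (`lme4::glmer`,
bobyqa optimizer). The printed equations contain only linear terms plus
the random intercept, so a logistic GLMM is the exact parametric
counterpart; no smooth terms are involved. Wald z and two-sided p-values
come from the estimated coefficient covariance. Fits are cross-checked in
the test suite against two independent routes: an ordinary logistic
regression when `theta_eta = 0`, and a random-effect GAM
(`mgcv::gam` with `s(patient, bs = "re")`).

Effect sizes are reported as quartile odds ratios,
`exp(b * (q75 - q25))` with the empirical quartiles of the centered-log
score column, with CIs transformed from the Wald interval of `b`.

**Filters.** The modeling design keeps mutations whose expressed
occurrence count is at least 2, and patients with scores in both classes
and at least one observed, expressed driver. Centering constants are
computed on the retained cells and recorded with the design. For the
parameter-recovery and null-calibration simulations in the acceptance
tests, the design instead keeps all occurred cells (`min_occurrence = 0`,
all cells treated as expressed): those checks test estimator calibration
for the generative equation itself, and the expression thinning — a
selection the model does not describe — would confound pure estimator bias
with conditioning effects.

# Group comparisons and the permutation control

Observed-mutation comparisons pool the (patient, mutation) score pairs of
occurred and expressed drivers within each group — the pooling unit is the
pair, not a per-patient summary, matching the distribution-of-scores view
of the question. Groups are compared pairwise with a one-tailed
Mann–Whitney U test; the focal group (female before male, younger before
older) is tested for *higher* scores (worse presentation), and with that
orientation Cliff's d is positive when the focal group's presentation is
worse. The original analyses report negative d values for the same
comparisons, which implies the opposite operand order; both orientations
are computable and the convention here is declared in the function
documentation rather than silently matched. Benjamini–Hochberg adjustment
is applied across each comparison family. Age groups are the pan-cohort
30th/70th percentile tails by default (per-tumor-type thresholds
optional); the middle 40% is excluded.

The Mann–Whitney implementation computes U on midranks and switches
between exact enumeration of rank splits (n + m <= 12, valid under ties)
and the tie-corrected normal approximation with continuity correction.
The two paths agree within 0.008 absolute p at the boundary for untied
data. Cliff's d uses an O((n+m) log(n+m)) sorted-search identity verified
against the quadratic pair count.

The permutation control asks whether a group difference could arise
without any genotype–mutation interaction: each permutation redraws every
mutation's carrier set uniformly across patients (preserving each
mutation's occurrence count and the cohort's genotype multiset), re-reads
the reassigned carriers' PHBR scores, and recomputes the group statistic
(difference of group medians by default; means selectable, since the
original statistic is not specified). The 99% CI is the empirical
0.5%/99.5% quantile pair of 1000 permutations (count configurable; the
original count is unstated).

# The synthetic study

Generator defaults define the study conditions and are not tuned per
test:

- **Cohort**: 200 patients (pipeline default), sex ~ Bernoulli(0.5), age
  truncated-normal mean 60, sd 13, on [20, 90] years (typical of adult
  pan-cancer age-at-diagnosis distributions; the age distribution is
  config, not fixed, since no canonical one exists), four tumor-type
  labels, full 8-gene genotypes from a compact allele pool with identical
  frequencies in both sexes (`group_frequency_perturbation = 0`). At
  n = 2000 the between-sex allele-frequency Pearson R is ~0.99, the
  genotype-balance control the analysis assumes.
- **Catalog**: 100 mutations (pipeline default; the generator itself
  defaults to a 1018-mutation catalog emulating the scale of a recurrent
  driver set, with 18/1018 inframe indels), protein contexts i.i.d.
  uniform over the 20 standard residues (scoring is sequence-agnostic),
  substitution classes C>T 0.35 / T>C 0.15 / other 0.5, signature labels
  loosely tied to class (C>T favors S01, T>C favors S05).
- **Selection truth**: `beta2 = 0.31` and `beta5 = 0.15` (the PHBR-II
  main effect and sex interaction magnitudes the method is designed to
  detect), `beta1 = 0.05`, `beta4 = 0.07`, intercept -3 (about 5%
  baseline occurrence), `theta_eta = 0.3`.
- **Expression**: VAF ~ Beta(2, 5); mutant RNA reads negative binomial
  with mean `VAF * 60` and size 2 (the read model is a package choice —
  only the >= 5-read expression rule is fixed); within-patient VAF
  percentile ranks, with a single mutation ranking 100 (the "top rank"
  convention avoids undefined ranks).
- **Signatures**: gamma activities, shape 2; a configured sex bias scales
  the male mean.

Indel altered-residue convention: insertions mark all inserted residues
plus one flank on each side; deletions mark the single junction residue.
The original pipeline's exact convention is not recoverable from the
published description, so it is a declared, config-visible choice that
guarantees windows span novel sequence.

# Numerical and design notes

- All randomness flows from one root seed split into named per-stage
  streams (`stage_seed`), so stages can be rerun independently and the
  full pipeline is byte-identical across reruns.
- PHBR values are stored on the raw percentile-rank scale; the natural log
  is applied only in the model design. Ranks are strictly positive so no
  offset is needed.
- The harmonic mean is validated to 1e-12 relative error against a
  Neumaier-compensated summation reference on 10,000 random inputs.
- Patients incomplete for one class are excluded from that class's matrix
  only (no imputation); downstream modules work on the intersection.
- Peptides containing non-standard residues are excluded from scoring
  with a reported count.
- The expression classifier is a ridge-penalized logistic regression on
  (VAF, within-patient VAF percentile rank, one-hot gene) with the penalty
  chosen by inner cross-validation; outer 10-fold CV is stratified by
  label and the mean held-out AUROC is reported. Genes unseen at
  prediction time fall back to the no-gene-effect baseline.
- Mutational-signature attributions are consumed, not computed; the
  sex-ratio analysis uses group means (medians selectable) and takes the
  one-tailed test direction from the sign of the observed ratio, with BH
  across the whole tumor-type-by-signature family.

# Simulation sizes used by the automated checks

The acceptance checks run desk-scale replicates chosen for stable
Monte-Carlo behavior on a single CPU: null calibration of the Wald tests
uses 200 replicate fits at 120 patients x 50 mutations; interval coverage
under selection uses 60 replicates at 400 patients x 100 mutations;
permutation-null coverage uses 200 replicate experiments (200 permutations
each) at 120 x 50, with the detection-power arm at 500 patients. The
pipeline determinism check runs the 200 x 100 default twice.

# Limitations

- The synthetic backend's rank landscape is hash-noise with mild anchor
  structure; conclusions about real immunopeptidomes require a real
  predictor behind the backend contract.
- The generator does not simulate raw reads, tumor purity, clonality,
  germline variation or survival; signature activities are parametric
  stand-ins for attribution matrices.
- HLA typing itself, predictor-specific allele compatibility lists, and
  de-novo signature extraction are out of scope; allele allow-lists are
  config where relevant.
- With small cohorts the rarer expression class can be too thin to
  cross-validate; the pipeline then skips the classifier and flags it
  rather than fitting a degenerate model.
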