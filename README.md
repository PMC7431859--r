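# immunosel

Patient-specific MHC presentation scoring of tumor driver mutations and
the biostatistics of immune selection.

## The problem

T cells can only eliminate a tumor cell if one of the patient's MHC
molecules presents a peptide covering a somatic mutation. If that
surveillance is effective early in tumorigenesis, the driver mutations
still observed at diagnosis should be biased toward poor presentation —
and if surveillance strength differs between patient groups (female vs
male, younger vs older), so should the size of that bias. `immunosel` is
for computational immunologists and cancer genomicists who want to
quantify that bias: it scores how well each patient can present each
driver mutation, compares observed-mutation scores between cohort groups
with permutation controls, and models mutation occurrence as a function of
presentation, sex and age.

## The score and the model

**PHBR (patient harmonic-mean best rank).** For a mutation in patient
*i*: enumerate all peptide windows containing an altered residue (8–11mers
for class I, 15mers for class II); for each of the patient's scoring
molecules take the best (minimum) percentile rank over those windows; and
aggregate the per-molecule best ranks *s*₁…*s*ₙ by harmonic mean

    PHBR = n / Σₖ (1 / sₖ)

over fixed slot sets: 6 class I slots (HLA-A/B/C ×2) and 12 class II
slots (4 DPA1/DPB1 combinations, 4 DQA1/DQB1 combinations, each DRB1
allele twice). Low PHBR = well presented. The harmonic mean is dominated
by the best-presenting molecule, matching the biology: one good presenter
makes a mutation visible.

**Occurrence model.** With *y*ᵢⱼ the binary occurrence of mutation *j* in
patient *i* and *x1*, *x2* the centered log PHBR-I/II scores:

    logit P(yᵢⱼ = 1) = β₀ + β₁ x1ᵢⱼ + β₂ x2ᵢⱼ + β₃ Sexᵢ
                       + β₄ x1ᵢⱼ·Sexᵢ + β₅ x2ᵢⱼ·Sexᵢ + ηᵢ,   ηᵢ ~ N(0, θη)

fit as a logistic GLMM (Laplace approximation) on expressed mutations
observed ≥ 2 times. Positive β₁/β₂ is the immunoediting signature;
positive score-by-sex interactions mean stronger selection in females.
An age model and single-score-class models complete the set of four.
Effects are summarized as 25th-vs-75th-percentile odds ratios. Group
comparisons use one-tailed Mann–Whitney tests with Cliff's d and
Benjamini–Hochberg adjustment, plus a mutation-reassignment permutation
null with a 99% CI.

Affinity predictions enter through a backend contract
(`backend(peptides, molecules) → percentile ranks`); precomputed rank
tables from any real predictor can be served with `make_table_backend()`,
and a deterministic synthetic backend plus a full synthetic-cohort
generator (with known selection coefficients) make every stage testable
against ground truth.

## Worked example

The `analysis/` drivers run the whole study on a 200-patient × 100-driver
synthetic cohort generated with selection truth β₂ = 0.31, β₅ = 0.15
(PHBR-II main effect and sex interaction), θη = 0.3:

```sh
Rscript analysis/01_simulate_cohort.R --seed 1
Rscript analysis/02_score_phbr.R      --seed 1
Rscript analysis/03_group_comparisons.R --seed 1
Rscript analysis/04_selection_models.R  --seed 1
Rscript analysis/05_aux_analyses.R      --seed 1
```

Output from that run (tables land in `results/`):

```
between-sex allele-frequency Pearson R (class I, n=2000): 0.989
PHBR-I: median 0.87 | PHBR-II: median 2.09
occurrence: 1029 observed driver events, 825 expressed (>= 5 mutant RNA reads)
female vs male PHBR-II: median 2.69 vs 2.30, p = 0.00011, Cliff's d = 0.149
sex model: PHBR-I 0.014, PHBR-II 0.306, PHBR-I:sex -0.043, PHBR-II:sex 0.304, theta_eta 0.197
quartile odds ratios: PHBR-I 1.02 [0.94, 1.10], PHBR-II 1.43 [1.31, 1.56]
expression classifier: mean CV AUROC 73.4% over 10 folds
```

Reading it: the cohort's genotype frequencies are balanced between sexes
(R ≈ 0.99), so any group difference in observed-mutation scores is not a
genotype artifact. The fitted PHBR-II effect (0.306) recovers the
generative 0.31 — observed drivers are biased toward poor class II
presentation — and the positive PHBR-II:sex interaction means the bias is
stronger in females, i.e. stronger immunoediting. The quartile odds
ratio says a mutation at the 75th percentile of PHBR-II has 1.43× the
odds of being observed compared to the 25th. Equivalent single calls:
`score_matrix()`, `fit_all_models()`, `quartile_odds_ratio()`,
`compare_observed_scores()`, `permutation_null()`, or `run_pipeline()`
for the whole bundle with a manifest.

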