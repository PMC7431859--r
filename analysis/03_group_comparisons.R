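# Stage 3: group-level comparisons of observed, expressed driver scores.
#
# Pools the PHBR scores of observed + expressed driver mutations by sex,
# age (pan-cohort 30th/70th percentiles) and sex-age groups; one-tailed
# Mann-Whitney tests (focal group = female / younger, alternative "focal
# scores higher", i.e. worse presentation), Cliff's d, BH adjustment; and
# the mutation-reassignment permutation control with a 99% CI.

source("analysis/00_common.R")
seed <- cli_seed()

patients <- read_tsv("patients.tsv")
long1 <- read_tsv("phbr_I_long.tsv")
long2 <- read_tsv("phbr_II_long.tsv")

all_cmp <- list()
for (grouping in c("sex", "age", "sex_age")) {
  groups <- patient_groups(patients, grouping)
  for (cl in c("I", "II")) {
    long <- if (cl == "I") long1 else long2
    cmp <- compare_observed_scores(long, groups)
    cmp$grouping <- grouping
    cmp$class <- cl
    all_cmp[[paste(grouping, cl)]] <- cmp
  }
}
cmp <- do.call(rbind, c(all_cmp, list(make.row.names = FALSE)))
write_tsv(cmp, "comparisons.tsv")
sig <- cmp[!cmp$missing & cmp$p_bh < 0.05, ]
message(nrow(sig), " of ", sum(!cmp$missing),
        " pairwise comparisons significant after BH")
fm <- cmp[cmp$grouping == "sex" & cmp$class == "II", ]
message(sprintf("female vs male PHBR-II: median %.2f vs %.2f, p = %.2g, Cliff's d = %.3f",
                fm$median_a, fm$median_b, fm$p_one_tailed, fm$cliffs_d))

# permutation control: does the sex difference exceed genotype-blind chance?
s2 <- long_to_matrix(long2, "phbr")
occ <- long_to_matrix(long2, "occurred")
expr <- long_to_matrix(long2, "expressed")
groups <- patient_groups(patients, "sex")
perm <- permutation_null(s2, occ * expr, groups, n_perm = 1000,
                         seed = stage_seed(seed, "permutation"))
message(sprintf("observed sex median difference %.3f vs null 99%% CI [%.3f, %.3f] -> %s",
                perm$observed, perm$ci_low, perm$ci_high,
                if (perm$outside_ci) "OUTSIDE (selection signal)" else "inside"))
write_tsv(data.frame(statistic = perm$observed, null_mean = perm$null_mean,
                     ci_low = perm$ci_low, ci_high = perm$ci_high,
                     outside_ci = perm$outside_ci, n_perm = perm$n_perm,
                     seed = perm$seed), "permutation.tsv")
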