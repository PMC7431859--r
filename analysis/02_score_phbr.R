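# Stage 2: PHBR presentation scoring and occurrence simulation.
#
# Scores every (patient, mutation) pair with the deterministic synthetic
# rank backend: per molecule, the best (minimum) percentile rank over the
# peptide windows covering the mutated residues; per patient, the harmonic
# mean over the 6 class I and 12 class II scoring slots. Then simulates
# mutation occurrence under a known immune-selection ground truth (PHBR-II
# main effect 0.31, PHBR-II:sex interaction 0.15, matching the magnitudes
# of the effects the method is designed to detect) and VAF-based expression.

source("analysis/00_common.R")
seed <- cli_seed()

patients <- read_tsv("patients.tsv")
genotypes <- read_tsv("genotypes.tsv")
catalog <- read_catalog("results/catalog.tsv")
proteins <- read_proteins("results/proteins.fasta")
backend <- make_synthetic_backend(stage_seed(seed, "backend"))

s1 <- score_matrix(genotypes, catalog, proteins, backend, "I")
s2 <- score_matrix(genotypes, catalog, proteins, backend, "II")
message(sprintf("PHBR-I: median %.2f | PHBR-II: median %.2f", median(s1), median(s2)))
message(sprintf("fraction of drivers below the weak-binding cutoff: class I (<2) %.2f, class II (<10) %.2f",
                mean(fraction_presented(s1, 2)), mean(fraction_presented(s2, 10))))

truth <- selection_truth(beta1 = 0.05, beta2 = 0.31, beta4 = 0.07,
                         beta5 = 0.15, intercept = -3, theta_eta = 0.3)
sim <- simulate_mutations(s1, s2, patients$sex, truth,
                          seed = stage_seed(seed, "occurrence"))
expr <- simulate_expression(sim$y, seed = stage_seed(seed, "expression"))
message("occurrence: ", sum(sim$y), " observed driver events, ",
        sum(expr$expressed), " expressed (>= 5 mutant RNA reads)")

write_tsv(phbr_long(s1, sim$y, expr$expressed, "I"), "phbr_I_long.tsv")
write_tsv(phbr_long(s2, sim$y, expr$expressed, "II"), "phbr_II_long.tsv")
write_tsv(expr$table, "occurrences.tsv")
write_tsv(data.frame(parameter = names(unclass(truth)),
                     value = unlist(unclass(truth))), "selection_truth.tsv")
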