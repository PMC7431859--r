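# Stage 5: auxiliary analyses.
#
# (a) sex-specific mutational-signature ratios (S01 simulated with a
# male/female activity ratio of 2, everything else unbiased), (b) the share
# of the driver set attributed to each signature, (c) presentation of
# C>T / T>C versus other substitutions across a genotype-independent allele
# panel, and (d) the VAF-based RNA-expression classifier with stratified
# 10-fold cross-validation.

source("analysis/00_common.R")
seed <- cli_seed()

patients <- read_tsv("patients.tsv")
catalog <- read_catalog("results/catalog.tsv")
proteins <- read_proteins("results/proteins.fasta")
occurrences <- read_tsv("occurrences.tsv")
backend <- make_synthetic_backend(stage_seed(seed, "backend"))

activities <- simulate_signature_activities(
  patients, driver_catalog_config()$signature_labels, sex_bias = c(S01 = 2),
  seed = stage_seed(seed, "signatures"))
ratios <- signature_sex_ratios(activities)
write_tsv(activities, "signature_activities.tsv")
write_tsv(ratios, "signature_sex_ratios.tsv")
s01 <- ratios[ratios$signature == "S01" & !ratios$skipped, ]
message(sprintf("S01 log2 male/female ratio: mean %.2f over %d tumor types (truth log2(2) = 1)",
                mean(s01$log2_ratio), nrow(s01)))

fr <- driver_signature_fractions(catalog$signature)
write_tsv(data.frame(signature = names(fr), percent = as.numeric(fr)),
          "driver_signature_fractions.tsv")
message("driver set by signature: ",
        paste(names(fr), sprintf("%.1f%%", fr), collapse = ", "))

panel <- unlist(lapply(default_allele_pool()[c("A", "B", "C")],
                       function(p) p$allele), use.names = FALSE)
subst <- substitution_class_presentation(catalog, proteins, panel, backend,
                                         default_window_lengths("I"))
message(sprintf("C>T/T>C vs other best ranks: median %.2f vs %.2f, p = %.2g, d = %.3f",
                subst$median_focal, subst$median_other, subst$p, subst$cliffs_d))
write_tsv(data.frame(subst[c("n_focal", "n_other", "median_focal",
                             "median_other", "U", "p", "cliffs_d")]),
          "substitution_presentation.tsv")

rows <- merge(occurrences, catalog[, c("mutation_id", "gene")], by = "mutation_id")
cls <- fit_expression_classifier(rows, seed = stage_seed(seed, "classifier"))
message(sprintf("expression classifier: mean CV AUROC %.1f%% over %d folds",
                100 * cls$mean_auroc, cls$n_folds))
write_tsv(data.frame(fold = seq_along(cls$fold_auroc), auroc = cls$fold_auroc),
          "expression_classifier_auroc.tsv")
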