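# Stage 1: generate the synthetic study population.
#
# Builds a 200-patient cohort with complete class I / class II HLA
# genotypes drawn from a common allele pool (no sex-specific frequency
# differences, mirroring cohorts whose between-sex genotype frequency
# correlation is ~0.99), plus a 100-mutation driver catalog of missense and
# inframe-indel events on random protein contexts.

source("analysis/00_common.R")
seed <- cli_seed()

cohort <- generate_cohort(cohort_config(n_patients = 200,
                                        seed = stage_seed(seed, "cohort")))
gen <- generate_driver_catalog(driver_catalog_config(n_mutations = 100),
                               seed = stage_seed(seed, "catalog"))

message("cohort: ", nrow(cohort$patients), " patients (",
        sum(cohort$patients$sex == 1), " female), ages ",
        min(cohort$patients$age_years), "-", max(cohort$patients$age_years))
message("catalog: ", nrow(gen$catalog), " mutations (",
        sum(gen$catalog$kind == "inframe_indel"), " inframe indels)")

# sanity control: between-sex allele-frequency correlation at study scale
big <- generate_cohort(cohort_config(n_patients = 2000,
                                     seed = stage_seed(seed, "freq_control")))
grp <- setNames(ifelse(big$patients$sex == 1, "female", "male"),
                big$patients$patient_id)
for (cl in c("I", "II")) {
  fr <- allele_frequencies(big$genotypes, grp, cl)
  message(sprintf("between-sex allele-frequency Pearson R (class %s, n=2000): %.3f",
                  cl, genotype_frequency_correlation(fr$female, fr$male)))
}

write_tsv(cohort$patients, "patients.tsv")
write_tsv(cohort$genotypes, "genotypes.tsv")
write_tsv(gen$catalog, "catalog.tsv")
write_proteins(gen$proteins, file.path(results_dir(), "proteins.fasta"))
message("  wrote results/proteins.fasta")
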