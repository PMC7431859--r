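# small cohort/catalog fixtures built in code

tiny_genotype <- function() {
  hla_genotype(list(
    A = c("A*01:01", "A*02:01"), B = c("B*07:02", "B*08:01"),
    C = c("C*07:01", "C*07:02"), DRB1 = c("DRB1*15:01", "DRB1*03:01"),
    DPA1 = c("DPA1*01:03", "DPA1*02:01"), DPB1 = c("DPB1*04:01", "DPB1*02:01"),
    DQA1 = c("DQA1*05:01", "DQA1*01:02"), DQB1 = c("DQB1*02:01", "DQB1*06:02")))
}

homozygous_genotype <- function() {
  hla_genotype(list(
    A = rep("A*01:01", 2), B = rep("B*07:02", 2), C = rep("C*07:01", 2),
    DRB1 = rep("DRB1*15:01", 2), DPA1 = rep("DPA1*01:03", 2),
    DPB1 = rep("DPB1*04:01", 2), DQA1 = rep("DQA1*05:01", 2),
    DQB1 = rep("DQB1*02:01", 2)))
}

# cohort + catalog + scored matrices at a given size, PHBR via the package
scored_fixture <- function(n_patients = 30, n_mutations = 20, seed = 42) {
  cohort <- generate_cohort(cohort_config(n_patients = n_patients, seed = seed))
  gen <- generate_driver_catalog(
    driver_catalog_config(n_mutations = n_mutations), seed = seed + 1)
  backend <- make_synthetic_backend(seed + 2)
  s1 <- score_matrix(cohort$genotypes, gen$catalog, gen$proteins, backend, "I")
  s2 <- score_matrix(cohort$genotypes, gen$catalog, gen$proteins, backend, "II")
  list(cohort = cohort, catalog = gen$catalog, proteins = gen$proteins,
       backend = backend, s1 = s1, s2 = s2)
}

# simulate occurrence + expression and build a model design in one step
design_fixture <- function(fx, truth, covariate = NULL, seed = 7) {
  if (is.null(covariate)) covariate <- fx$cohort$patients$sex
  sim <- simulate_mutations(fx$s1, fx$s2, covariate, truth, seed = seed)
  expr <- simulate_expression(sim$y, seed = seed + 1)
  design <- build_design(fx$s1, fx$s2, sim$y, expr$expressed,
                         fx$cohort$patients)
  list(sim = sim, expr = expr, design = design)
}
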