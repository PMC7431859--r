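test_that("cohort generation is deterministic and respects config boundaries", {
  cfg <- cohort_config(n_patients = 30, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  all_male <- generate_cohort(cohort_config(n_patients = 20,
                                            sex_fraction_female = 0, seed = 5))
  expect_true(all(all_male$patients$sex == 0))
  ad <- cohort_config(n_patients = 50, seed = 1)$age_distribution
  expect_true(all(a$patients$age_years >= ad[3] & a$patients$age_years <= ad[4]))
  # every patient fully typed: 16 allele slots
  expect_true(all(table(a$genotypes$patient_id) == 16))
  expect_error(cohort_config(n_patients = 1), "at least 2")
  pool <- default_allele_pool(); pool$A <- pool$A[0, ]
  expect_error(cohort_config(n_patients = 10, allele_pool = pool),
               "empty allele pool")
  badpool <- default_allele_pool(); badpool$A$freq <- badpool$A$freq * 2
  expect_error(cohort_config(n_patients = 10, allele_pool = badpool), "sum to 1")
})

test_that("unperturbed groups have near-identical allele frequencies at n = 2000", {
  cohort <- generate_cohort(cohort_config(n_patients = 2000, seed = 77,
                                          group_frequency_perturbation = 0))
  groups <- setNames(ifelse(cohort$patients$sex == 1, "female", "male"),
                     cohort$patients$patient_id)
  for (class in c("I", "II")) {
    fr <- allele_frequencies(cohort$genotypes, groups, class)
    r <- genotype_frequency_correlation(fr$female, fr$male)
    expect_gt(r, 0.95)
  }
  # a strong perturbation visibly decorrelates the sexes
  pert <- generate_cohort(cohort_config(n_patients = 2000, seed = 77,
                                        group_frequency_perturbation = 2))
  groups2 <- setNames(ifelse(pert$patients$sex == 1, "female", "male"),
                      pert$patients$patient_id)
  fr2 <- allele_frequencies(pert$genotypes, groups2, "I")
  expect_lt(genotype_frequency_correlation(fr2$female, fr2$male),
            genotype_frequency_correlation(fr$female, fr$male))
})

test_that("driver catalogs honor kind and class configuration", {
  cfg <- driver_catalog_config(n_mutations = 120, fraction_indels = 0)
  gen <- generate_driver_catalog(cfg, seed = 3)
  expect_identical(gen, generate_driver_catalog(cfg, seed = 3))
  expect_true(all(gen$catalog$kind == "missense"))
  # ref residues always match the context sequence
  for (i in sample(nrow(gen$catalog), 20)) {
    m <- gen$catalog[i, ]
    expect_equal(substr(gen$proteins[[m$protein_id]], m$pos, m$pos), m$ref)
  }
  ct_only <- generate_driver_catalog(
    driver_catalog_config(n_mutations = 50, fraction_indels = 0,
                          substitution_class_probs = c("C>T" = 1, "T>C" = 0, other = 0)),
    seed = 4)
  expect_true(all(ct_only$catalog$substitution_class == "C>T"))
  # class counts consistent with the configured multinomial (chi-square GOF)
  big <- generate_driver_catalog(
    driver_catalog_config(n_mutations = 1018, fraction_indels = 0), seed = 8)
  probs <- driver_catalog_config()$substitution_class_probs
  counts <- table(factor(big$catalog$substitution_class, levels = names(probs)))
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 1e-3)
  # proteins always long enough for the widest window
  expect_true(all(nchar(big$proteins) >= 15))
  expect_error(driver_catalog_config(n_mutations = 0), "at least 1")
  expect_error(driver_catalog_config(substitution_class_probs = c("C>T" = 0.5)),
               "sum to 1")
})

test_that("occurrence simulation matches the analytic logistic probabilities", {
  fx <- scored_fixture(n_patients = 120, n_mutations = 60, seed = 15)
  # symmetric null: all zeros -> marginal rate 1/2
  null_truth <- selection_truth(intercept = 0)
  sim0 <- simulate_mutations(fx$s1, fx$s2, fx$cohort$patients$sex, null_truth,
                             seed = 2)
  n_cells <- length(sim0$y)
  expect_lt(abs(mean(sim0$y) - 0.5), 3 * sqrt(0.25 / n_cells))
  # positive beta2: occurrence frequency tracks the per-cell oracle by decile
  truth <- selection_truth(beta2 = 1.2, intercept = -1.5)
  sim <- simulate_mutations(fx$s1, fx$s2, fx$cohort$patients$sex, truth, seed = 3)
  p_oracle <- occurrence_probabilities(fx$s1, fx$s2, fx$cohort$patients$sex, truth)
  expect_identical(dim(sim$y), dim(fx$s1))
  dec <- cut(rank(fx$s2, ties.method = "first"), 10, labels = FALSE)
  emp <- tapply(as.vector(sim$y), dec, mean)
  ana <- tapply(as.vector(p_oracle), dec, mean)
  n_bin <- tabulate(dec)
  expect_true(all(abs(emp - ana) <= 3 * sqrt(ana * (1 - ana) / n_bin)))
  expect_gt(emp[10], emp[1]) # higher PHBR-II decile -> more mutations
  # non-finite scores are refused with cell coordinates
  s_bad <- fx$s1; s_bad[2, 3] <- NA
  expect_error(simulate_mutations(s_bad, fx$s2, fx$cohort$patients$sex, truth),
               "row 2, column 3")
})

test_that("patient random intercepts overdisperse per-patient mutation counts", {
  fx <- scored_fixture(n_patients = 150, n_mutations = 60, seed = 25)
  base <- selection_truth(intercept = -1.5, theta_eta = 0)
  wide <- selection_truth(intercept = -1.5, theta_eta = 2)
  y0 <- simulate_mutations(fx$s1, fx$s2, fx$cohort$patients$sex, base, seed = 5)$y
  y1 <- simulate_mutations(fx$s1, fx$s2, fx$cohort$patients$sex, wide, seed = 5)$y
  disp <- function(y) var(rowSums(y)) / mean(rowSums(y))
  expect_gt(disp(y1), 2 * disp(y0))
})

test_that("expression simulation applies the 5-read rule and percentile ranks", {
  occ <- matrix(1, 2, 3, dimnames = list(c("p1", "p2"), c("m1", "m2", "m3")))
  ex <- simulate_expression(occ, seed = 4)
  expect_equal(ex$table$expressed, as.integer(ex$table$rna_mut_reads >= 5))
  expect_true(all(ex$table$vaf > 0 & ex$table$vaf <= 1))
  # read counts exactly at the boundary: {4, 5, 6} -> {0, 1, 1}
  expect_equal(as.integer(c(4, 5, 6) >= 5), c(0L, 1L, 1L))
  expect_equal(ex$table$expressed,
               as.integer(ex$table$rna_mut_reads >= 5))
  # VAF forced to zero is never expressed
  ex0 <- simulate_expression(occ, seed = 4, vaf = 0)
  expect_true(all(ex0$table$rna_mut_reads == 0))
  expect_true(all(ex0$table$expressed == 0))
  # a patient's single mutation ranks 100
  occ1 <- matrix(c(1, 0, 0, 0, 1, 1), 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("m1", "m2", "m3")))
  ex1 <- simulate_expression(occ1, seed = 6)
  expect_equal(ex1$table$vaf_percentile_rank[ex1$table$patient_id == "p1"], 100)
  ranks_p2 <- sort(ex1$table$vaf_percentile_rank[ex1$table$patient_id == "p2"])
  expect_equal(ranks_p2, c(50, 100))
  # expressed matrix aligns with the long table
  expect_equal(sum(ex1$expressed), sum(ex1$table$expressed))
})

test_that("signature activities reproduce configured sex biases", {
  pat <- data.frame(patient_id = sprintf("p%03d", 1:600),
                    sex = rep(c(0, 1), 300), stringsAsFactors = FALSE)
  act <- simulate_signature_activities(pat, c("S01", "S05"),
                                       sex_bias = c(S01 = 2), seed = 9)
  m <- act$S01[act$sex == 0]; f <- act$S01[act$sex == 1]
  expect_lt(abs(log2(mean(m) / mean(f)) - 1), 0.25)
  expect_lt(abs(log2(mean(act$S05[act$sex == 0]) /
                       mean(act$S05[act$sex == 1]))), 0.25)
  expect_true(all(act$S01 >= 0))
  expect_error(simulate_signature_activities(pat[0, ], "S01"), "empty cohort")
  expect_error(simulate_signature_activities(pat, "S01", sex_bias = c(S01 = -1)),
               "nonnegative")
  expect_error(simulate_signature_activities(pat, character(0)), "nonempty")
})
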