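#' Default HLA allele pool for synthetic cohorts
#'
#' A compact pool of common alleles per gene with plausible relative
#' frequencies (normalized to sum to 1 within each gene). Purely a
#' synthetic stand-in: names follow HLA nomenclature but frequencies are
#' round numbers, not population estimates.
#'
#' @return named list, `gene -> data.frame(allele, freq)`.
#' @export
default_allele_pool <- function() {
  mk <- function(gene, nums, w) {
    data.frame(allele = paste0(gene, "*", nums), freq = w / sum(w),
               stringsAsFactors = FALSE)
  }
  list(
    A    = mk("A",    c("01:01", "02:01", "03:01", "11:01", "24:02", "26:01"),
              c(18, 28, 13, 9, 12, 20)),
    B    = mk("B",    c("07:02", "08:01", "15:01", "35:01", "44:02", "51:01"),
              c(14, 12, 10, 11, 13, 40)),
    C    = mk("C",    c("03:04", "04:01", "05:01", "06:02", "07:01", "07:02"),
              c(12, 14, 9, 10, 25, 30)),
    DRB1 = mk("DRB1", c("01:01", "03:01", "04:01", "07:01", "11:01", "15:01"),
              c(10, 13, 12, 14, 21, 30)),
    DPA1 = mk("DPA1", c("01:03", "02:01", "02:02"), c(60, 30, 10)),
    DPB1 = mk("DPB1", c("01:01", "02:01", "04:01", "04:02"), c(15, 20, 45, 20)),
    DQA1 = mk("DQA1", c("01:02", "02:01", "03:01", "05:01"), c(30, 20, 25, 25)),
    DQB1 = mk("DQB1", c("02:01", "03:01", "05:01", "06:02"), c(22, 33, 20, 25)))
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients (>= 2).
#' @param sex_fraction_female probability a patient is female (sex coded
#'   0 = male, 1 = female).
#' @param age_distribution numeric `c(mean, sd, min, max)` in years; ages
#'   are drawn truncated-normal.
#' @param tumor_type_labels tumor type labels sampled uniformly.
#' @param allele_pool per-gene allele frequency tables
#'   ([default_allele_pool()]); frequencies must sum to 1 per gene.
#' @param group_frequency_perturbation nonnegative scalar; 0 (default)
#'   samples every patient's genotype from identical per-gene frequencies,
#'   larger values tilt the female group's allele frequencies.
#' @param seed integer seed.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          sex_fraction_female = 0.5,
                          age_distribution = c(mean = 60, sd = 13, min = 20, max = 90),
                          tumor_type_labels = c("LUAD", "SKCM", "HNSC", "LIHC"),
                          allele_pool = default_allele_pool(),
                          group_frequency_perturbation = 0,
                          seed = 1) {
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (sex_fraction_female < 0 || sex_fraction_female > 1) {
    stop("sex_fraction_female must be a probability")
  }
  if (group_frequency_perturbation < 0) {
    stop("group_frequency_perturbation must be nonnegative")
  }
  for (gene in .HLA_GENES) {
    pool <- allele_pool[[gene]]
    if (is.null(pool) || !nrow(pool)) stop("empty allele pool for gene ", gene)
    if (abs(sum(pool$freq) - 1) > 1e-9) {
      stop("allele frequencies for gene ", gene, " must sum to 1")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 sex_fraction_female = sex_fraction_female,
                 age_distribution = age_distribution,
                 tumor_type_labels = tumor_type_labels,
                 allele_pool = allele_pool,
                 group_frequency_perturbation = group_frequency_perturbation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic patient cohort with HLA genotypes
#'
#' Draws sex, age (truncated normal), tumor type and a complete class I +
#' class II genotype per patient from the configured allele pool.
#' Reproducible bit-for-bit under a fixed config seed. With
#' `group_frequency_perturbation = 0` both sexes sample from identical
#' allele frequencies, emulating cohorts whose between-group genotype
#' frequency correlation approaches 1.
#'
#' @param config a [cohort_config()].
#' @return list with `patients` (patient_id, sex, age_years, tumor_type)
#'   and `genotypes` (patient_id, gene, allele).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  sex <- rbinom(n, 1L, config$sex_fraction_female)
  ad <- config$age_distribution
  age <- rnorm(n, ad[1], ad[2])
  for (k in 1:50) {
    out <- age < ad[3] | age > ad[4]
    if (!any(out)) break
    age[out] <- rnorm(sum(out), ad[1], ad[2])
  }
  age <- pmin(pmax(age, ad[3]), ad[4])
  tumor <- sample(config$tumor_type_labels, n, replace = TRUE)
  patients <- data.frame(patient_id = ids, sex = sex, age_years = round(age, 1),
                         tumor_type = tumor, stringsAsFactors = FALSE)

  pert <- config$group_frequency_perturbation
  rows <- vector("list", length(.HLA_GENES))
  for (gi in seq_along(.HLA_GENES)) {
    gene <- .HLA_GENES[gi]
    pool <- config$allele_pool[[gene]]
    tilt <- rnorm(nrow(pool)) # consumed regardless of pert for stream stability
    f_male <- pool$freq
    f_female <- if (pert > 0) {
      w <- pool$freq * exp(pert * tilt)
      w / sum(w)
    } else pool$freq
    a_m <- sample(pool$allele, 2L * n, replace = TRUE, prob = f_male)
    a_f <- sample(pool$allele, 2L * n, replace = TRUE, prob = f_female)
    female <- rep(sex == 1L, each = 2L)
    alleles <- ifelse(female, a_f, a_m)
    rows[[gi]] <- data.frame(patient_id = rep(ids, each = 2L), gene = gene,
                             allele = alleles, stringsAsFactors = FALSE)
  }
  genotypes <- do.call(rbind, rows)
  genotypes <- genotypes[order(match(genotypes$patient_id, ids),
                               match(genotypes$gene, .HLA_GENES)), ]
  rownames(genotypes) <- NULL
  list(patients = patients, genotypes = genotypes)
}

#' Driver-catalog configuration
#'
#' Defaults emulate a recurrent driver set: mostly missense with a small
#' inframe-indel fraction (18/1018), substitution classes split across
#' C>T / T>C / other, and a recurrence floor of 3 tumors recorded as
#' catalog metadata.
#'
#' @param n_mutations number of mutations (>= 1).
#' @param protein_length_range `c(min, max)` residues for random contexts.
#' @param fraction_indels probability a mutation is an inframe indel.
#' @param substitution_class_probs named probabilities for `C>T`, `T>C`,
#'   `other` (missense only; indels are classed "other").
#' @param signature_labels signature labels assignable to mutations.
#' @param min_recurrence recurrence floor recorded with the catalog.
#' @return validated config list of class `driver_catalog_config`.
#' @export
driver_catalog_config <- function(n_mutations = 1018,
                                  protein_length_range = c(120, 400),
                                  fraction_indels = 18 / 1018,
                                  substitution_class_probs = c("C>T" = 0.35, "T>C" = 0.15, other = 0.5),
                                  signature_labels = c("S01", "S02", "S05", "S13", "unassigned"),
                                  min_recurrence = 3) {
  if (n_mutations < 1) stop("n_mutations must be at least 1")
  if (abs(sum(substitution_class_probs) - 1) > 1e-9) {
    stop("substitution class probabilities must sum to 1")
  }
  if (fraction_indels < 0 || fraction_indels > 1) {
    stop("fraction_indels must be a probability")
  }
  stopifnot(length(protein_length_range) == 2L,
            protein_length_range[1] <= protein_length_range[2])
  structure(list(n_mutations = as.integer(n_mutations),
                 protein_length_range = as.integer(protein_length_range),
                 fraction_indels = fraction_indels,
                 substitution_class_probs = substitution_class_probs,
                 signature_labels = signature_labels,
                 min_recurrence = as.integer(min_recurrence)),
            class = "driver_catalog_config")
}

#' Generate a synthetic driver-mutation catalog with protein contexts
#'
#' Protein contexts are random i.i.d. strings over the 20 standard amino
#' acids (the scoring logic is sequence-agnostic); a context shorter than
#' the longest peptide window is rejected and resampled. Missense mutations
#' get a substitution class drawn from the configured probabilities and a
#' loosely class-linked signature label (C>T favors S01, T>C favors S05);
#' indels are classed "other".
#'
#' @param config a [driver_catalog_config()].
#' @param seed integer seed.
#' @param max_window longest window the catalog must support (default 15).
#' @return list with `catalog` (mutation_id, gene, protein_id, kind, pos,
#'   ref, alt, substitution_class, signature) and `proteins` (named
#'   character vector).
#' @export
generate_driver_catalog <- function(config, seed = 1, max_window = 15L) {
  stopifnot(inherits(config, "driver_catalog_config"))
  set.seed(as.integer(seed))
  n <- config$n_mutations
  classes <- names(config$substitution_class_probs)
  sig_for_class <- function(cl) {
    sigs <- config$signature_labels
    pref <- switch(cl, "C>T" = "S01", "T>C" = "S05", NA_character_)
    if (!is.na(pref) && pref %in% sigs && runif(1) < 0.8) return(pref)
    sample(sigs, 1L)
  }
  rows <- vector("list", n)
  proteins <- character(n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(config$protein_length_range[1]:config$protein_length_range[2], 1L)
      if (len >= max_window) break
    }
    prot <- paste(sample(.AMINO_ACIDS, len, replace = TRUE), collapse = "")
    mut_id <- sprintf("M%04d", i)
    prot_id <- sprintf("prot_%s", mut_id)
    proteins[i] <- prot
    names(proteins)[i] <- prot_id
    is_indel <- runif(1) < config$fraction_indels
    if (is_indel) {
      del <- runif(1) < 0.5
      ilen <- sample(1:3, 1L)
      if (del) {
        pos <- sample(seq_len(len - ilen), 1L)
        ref <- substr(prot, pos, pos + ilen - 1L); alt <- ""
      } else {
        pos <- sample(seq_len(len - 1L), 1L)
        ref <- ""
        alt <- paste(sample(.AMINO_ACIDS, ilen, replace = TRUE), collapse = "")
      }
      kind <- "inframe_indel"; cl <- "other"
    } else {
      pos <- sample(seq_len(len), 1L)
      ref <- substr(prot, pos, pos)
      alt <- sample(setdiff(.AMINO_ACIDS, ref), 1L)
      kind <- "missense"
      cl <- sample(classes, 1L, prob = config$substitution_class_probs)
    }
    rows[[i]] <- data.frame(mutation_id = mut_id, gene = sprintf("GENE%03d", 1L + (i - 1L) %% 100L),
                            protein_id = prot_id, kind = kind, pos = pos,
                            ref = ref, alt = alt, substitution_class = cl,
                            signature = sig_for_class(cl),
                            stringsAsFactors = FALSE)
  }
  catalog <- do.call(rbind, rows)
  attr(catalog, "min_recurrence") <- config$min_recurrence
  list(catalog = catalog, proteins = proteins)
}

#' Ground-truth selection coefficients for the generative occurrence model
#'
#' The generative twin of the fitted occurrence models: the log-odds of a
#' (patient, mutation) occurrence is linear in the centered log-PHBR scores,
#' the centered covariate and their interactions, plus a per-patient
#' Normal(0, theta_eta) random intercept.
#'
#' @param beta1 PHBR-I (log, centered) main effect.
#' @param beta2 PHBR-II main effect.
#' @param beta3 covariate (sex or age) main effect.
#' @param beta4 PHBR-I x covariate interaction.
#' @param beta5 PHBR-II x covariate interaction.
#' @param intercept baseline log-odds (sets the marginal occurrence rate).
#' @param theta_eta random-intercept standard deviation (>= 0).
#' @return validated list of class `selection_truth`.
#' @export
selection_truth <- function(beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
                            beta5 = 0, intercept = -3, theta_eta = 0) {
  vals <- c(beta1, beta2, beta3, beta4, beta5, intercept, theta_eta)
  if (any(!is.finite(vals))) stop("all truth parameters must be finite")
  if (theta_eta < 0) stop("theta_eta must be nonnegative")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
                 beta5 = beta5, intercept = intercept, theta_eta = theta_eta),
            class = "selection_truth")
}

#' Per-cell occurrence probabilities under the generative model
#'
#' The analytic cell-by-cell logistic probabilities (before the Bernoulli
#' draw); exposed so simulations can be checked against the exact model.
#'
#' @param phbr1,phbr2 aligned PHBR-I / PHBR-II matrices (raw rank scale).
#' @param covariate numeric per-patient covariate (sex 0/1 or age years).
#' @param truth a [selection_truth()].
#' @param eta per-patient random intercepts (default all zero).
#' @return matrix of probabilities aligned with the inputs.
#' @export
occurrence_probabilities <- function(phbr1, phbr2, covariate, truth,
                                     eta = rep(0, nrow(phbr1))) {
  stopifnot(inherits(truth, "selection_truth"),
            identical(dim(phbr1), dim(phbr2)),
            length(covariate) == nrow(phbr1),
            length(eta) == nrow(phbr1))
  bad <- which(!is.finite(phbr1) | phbr1 <= 0 | !is.finite(phbr2) | phbr2 <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(phbr1))
    stop("non-finite or non-positive PHBR entries (", length(bad),
         " cell(s), first at row ", rc[1], ", column ", rc[2], ")")
  }
  x1 <- log(phbr1); x1 <- x1 - mean(x1)
  x2 <- log(phbr2); x2 <- x2 - mean(x2)
  cv <- covariate - mean(covariate)
  lin <- truth$intercept + truth$beta1 * x1 + truth$beta2 * x2 +
    truth$beta3 * cv + truth$beta4 * x1 * cv + truth$beta5 * x2 * cv + eta
  plogis(lin)
}

#' Simulate the binary mutation occurrence matrix
#'
#' Draws `y_ij ~ Bernoulli(p_ij)` with the logit of `p_ij` linear in the
#' centered log-PHBR scores, the centered covariate and the interactions
#' ([occurrence_probabilities()]), plus i.i.d. Normal(0, theta_eta) patient
#' random intercepts.
#'
#' @inheritParams occurrence_probabilities
#' @param seed integer seed.
#' @return list: `y` (binary matrix), `eta` (drawn intercepts),
#'   `probabilities` (the cell probabilities used).
#' @export
simulate_mutations <- function(phbr1, phbr2, covariate, truth, seed = 1) {
  set.seed(as.integer(seed))
  eta <- rnorm(nrow(phbr1), 0, truth$theta_eta)
  p <- occurrence_probabilities(phbr1, phbr2, covariate, truth, eta)
  y <- matrix(rbinom(length(p), 1L, p), nrow = nrow(p),
              dimnames = dimnames(phbr1))
  list(y = y, eta = eta, probabilities = p)
}

#' Simulate DNA VAF, mutant RNA reads and expression flags
#'
#' For every occurred cell: VAF ~ Beta(2, 5) (clonal-ish fractions mostly
#' below 0.5), mutant RNA reads negative binomial with mean `vaf * depth`
#' (the read model is a package choice; only the >= `threshold`-read
#' expression rule is fixed), and `expressed = reads >= threshold` (default
#' 5). VAF percentile ranks are computed within each patient; a patient's
#' single mutation ranks 100.
#'
#' @param occurrence binary occurrence matrix.
#' @param seed integer seed.
#' @param depth expected mutant-read depth at VAF = 1 (default 60).
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param threshold minimum mutant reads to call a mutation expressed.
#' @param vaf optional fixed VAF value(s) for the occurred cells (recycled);
#'   overrides the Beta draw, e.g. to force degenerate VAFs in tests.
#' @return list: `table` (patient_id, mutation_id, vaf, rna_mut_reads,
#'   expressed, vaf_percentile_rank; one row per occurred cell) and
#'   `expressed` (binary matrix aligned with `occurrence`).
#' @export
simulate_expression <- function(occurrence, seed = 1, depth = 60, nb_size = 2,
                                threshold = 5, vaf = NULL) {
  set.seed(as.integer(seed))
  idx <- which(occurrence == 1)
  rc <- arrayInd(idx, dim(occurrence))
  if (is.null(vaf)) {
    vaf <- pmax(rbeta(length(idx), 2, 5), 1e-6)
  } else {
    vaf <- rep_len(vaf, length(idx))
    if (any(vaf < 0 | vaf > 1)) stop("supplied VAFs must lie in [0, 1]")
  }
  reads <- rnbinom(length(idx), size = nb_size, mu = vaf * depth)
  tab <- data.frame(
    patient_id = rownames(occurrence)[rc[, 1]],
    mutation_id = colnames(occurrence)[rc[, 2]],
    vaf = vaf, rna_mut_reads = reads,
    expressed = as.integer(reads >= threshold),
    stringsAsFactors = FALSE)
  tab$vaf_percentile_rank <- NA_real_
  for (p in unique(tab$patient_id)) {
    i <- which(tab$patient_id == p)
    tab$vaf_percentile_rank[i] <- rank(tab$vaf[i]) / length(i) * 100
  }
  expressed <- occurrence * 0L
  expressed[idx] <- tab$expressed
  list(table = tab, expressed = expressed)
}

#' Simulate patient mutational-signature activities
#'
#' Gamma-distributed nonnegative activities per (patient, signature); for a
#' signature with configured sex bias `b`, male mean activity is `b` times
#' the female mean (so the recovered log2 male/female ratio is about
#' `log2(b)`).
#'
#' @param patients patient data.frame (patient_id, sex).
#' @param signature_labels signatures to simulate.
#' @param sex_bias named nonnegative male/female mean ratios (default 1 for
#'   every signature).
#' @param seed integer seed.
#' @param base_mean female mean activity (default 100).
#' @return data.frame: patient_id, tumor_type (if present), sex, one column
#'   per signature.
#' @export
simulate_signature_activities <- function(patients, signature_labels,
                                          sex_bias = NULL, seed = 1,
                                          base_mean = 100) {
  if (!nrow(patients)) stop("empty cohort")
  if (!length(signature_labels)) stop("signature_labels must be nonempty")
  bias <- setNames(rep(1, length(signature_labels)), signature_labels)
  if (!is.null(sex_bias)) {
    if (any(sex_bias < 0)) stop("sex bias ratios must be nonnegative")
    bias[names(sex_bias)] <- sex_bias
  }
  set.seed(as.integer(seed))
  out <- data.frame(patient_id = patients$patient_id,
                    sex = patients$sex, stringsAsFactors = FALSE)
  if (!is.null(patients$tumor_type)) out$tumor_type <- patients$tumor_type
  shape <- 2
  for (s in signature_labels) {
    mu <- ifelse(patients$sex == 0, base_mean * bias[[s]], base_mean)
    out[[s]] <- rgamma(nrow(patients), shape = shape, rate = shape / mu)
  }
  out
}
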