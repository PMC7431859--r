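#' Pipeline run configuration
#'
#' Captures everything a full synthetic end-to-end run needs. The config
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]), and all randomness flows from `seed` via named
#' per-stage streams ([stage_seed()]).
#'
#' @param out_dir output directory for the report bundle.
#' @param seed root seed.
#' @param n_patients,n_mutations synthetic cohort / catalog sizes.
#' @param covariate "sex" or "age": which covariate the generative
#'   selection model interacts with.
#' @param truth named list of [selection_truth()] parameters.
#' @param n_perm permutations for the reassignment null.
#' @param grouping grouping for the comparison family ("sex", "age",
#'   "sex_age").
#' @param sex_bias named male/female activity ratios for signatures.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir = "results",
                       seed = 1,
                       n_patients = 200,
                       n_mutations = 100,
                       covariate = "sex",
                       truth = list(beta1 = 0.05, beta2 = 0.31, beta3 = 0,
                                    beta4 = 0.07, beta5 = 0.15,
                                    intercept = -3, theta_eta = 0.3),
                       n_perm = 1000,
                       grouping = "sex",
                       sex_bias = c(S01 = 2)) {
  stopifnot(covariate %in% c("sex", "age"),
            grouping %in% c("sex", "age", "sex_age"))
  do.call(selection_truth, truth) # validates
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 n_mutations = as.integer(n_mutations),
                 covariate = covariate, truth = truth,
                 n_perm = as.integer(n_perm), grouping = grouping,
                 sex_bias = sex_bias),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  raw <- unclass(config)
  raw$sex_bias <- as.list(raw$sex_bias) # keep names through JSON
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$truth <- as.list(raw$truth)
  raw$sex_bias <- unlist(raw$sex_bias)
  do.call(run_config, raw)
}

.config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  stage_seed(0, s)
}

#' Run the full synthetic analysis pipeline
#'
#' Sequences every stage: cohort and catalog generation, PHBR-I/II scoring
#' with the deterministic synthetic backend, occurrence and expression
#' simulation under the configured ground truth, group comparisons,
#' mutation-reassignment permutation null, the four occurrence models with
#' quartile odds ratios, signature sex-ratio analysis, substitution-class
#' presentation, and the expression classifier. Writes a TSV bundle plus a
#' machine-readable manifest (seeds, config, truth, config hash) under
#' `config$out_dir` and returns the results invisibly. Numeric outputs are
#' byte-identical across reruns of the same config.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- sapply(c("cohort", "catalog", "backend", "occurrence",
                    "expression", "signatures", "permutation", "classifier"),
                  function(s) stage_seed(config$seed, s))

  cc <- cohort_config(n_patients = config$n_patients, seed = seeds[["cohort"]])
  cohort <- generate_cohort(cc)
  message("cohort: ", nrow(cohort$patients), " patients generated")
  dcfg <- driver_catalog_config(n_mutations = config$n_mutations)
  cat_gen <- generate_driver_catalog(dcfg, seed = seeds[["catalog"]])
  backend <- make_synthetic_backend(seeds[["backend"]])

  s1 <- score_matrix(cohort$genotypes, cat_gen$catalog, cat_gen$proteins,
                     backend, "I")
  s2 <- score_matrix(cohort$genotypes, cat_gen$catalog, cat_gen$proteins,
                     backend, "II")
  truth <- do.call(selection_truth, config$truth)
  cov <- if (config$covariate == "sex") cohort$patients$sex else cohort$patients$age_years
  sim <- simulate_mutations(s1, s2, cov, truth, seed = seeds[["occurrence"]])
  expr <- simulate_expression(sim$y, seed = seeds[["expression"]])
  message("occurrence: ", sum(sim$y), " observed cells, ",
          sum(expr$expressed), " expressed")

  long2 <- phbr_long(s2, sim$y, expr$expressed, "II")
  groups <- patient_groups(cohort$patients, config$grouping)
  comparisons <- compare_observed_scores(long2, groups)

  sex_groups <- patient_groups(cohort$patients, "sex")
  perm <- permutation_null(s2, sim$y * expr$expressed, sex_groups,
                           n_perm = config$n_perm,
                           seed = seeds[["permutation"]])

  design <- build_design(s1, s2, sim$y, expr$expressed, cohort$patients)
  models <- fit_all_models(design)
  or1 <- or2 <- NULL
  eq_main <- if (config$covariate == "sex") "1" else "2"
  if (!is.null(models$fits[[eq_main]]) && models$fits[[eq_main]]$converged) {
    or1 <- quartile_odds_ratio(models$fits[[eq_main]], "I", design)
    or2 <- quartile_odds_ratio(models$fits[[eq_main]], "II", design)
  }

  activities <- simulate_signature_activities(
    cohort$patients, dcfg$signature_labels, sex_bias = config$sex_bias,
    seed = seeds[["signatures"]])
  sig_ratios <- signature_sex_ratios(activities)
  sig_fracs <- driver_signature_fractions(cat_gen$catalog$signature)
  panel <- unique(unlist(lapply(default_allele_pool()[c("A", "B", "C")],
                                function(p) p$allele)))
  subst <- substitution_class_presentation(cat_gen$catalog, cat_gen$proteins,
                                           panel, backend,
                                           default_window_lengths("I"))
  cls_rows <- merge(expr$table, cat_gen$catalog[, c("mutation_id", "gene")],
                    by = "mutation_id")
  # the classifier needs both labels in every CV fold; tiny synthetic runs
  # may not produce enough of the rarer label, in which case it is skipped
  if (min(sum(cls_rows$expressed == 1), sum(cls_rows$expressed == 0)) >= 10) {
    cls <- fit_expression_classifier(cls_rows, seed = seeds[["classifier"]])
  } else {
    message("too few examples of one expression class; classifier skipped")
    cls <- list(mean_auroc = NA_real_, skipped = TRUE)
  }

  od <- config$out_dir
  write_tsv_strict(cohort$patients, file.path(od, "patients.tsv"))
  write_genotypes(cohort$genotypes, file.path(od, "genotypes.tsv"))
  write_catalog(cat_gen$catalog, file.path(od, "catalog.tsv"))
  write_proteins(cat_gen$proteins, file.path(od, "proteins.fasta"))
  write_tsv_strict(expr$table, file.path(od, "occurrences.tsv"))
  write_tsv_strict(phbr_long(s1, sim$y, expr$expressed, "I"),
                   file.path(od, "phbr_I_long.tsv"))
  write_tsv_strict(long2, file.path(od, "phbr_II_long.tsv"))
  write_tsv_strict(comparisons, file.path(od, "comparisons.tsv"))
  write_tsv_strict(data.frame(statistic = perm$observed,
                              null_mean = perm$null_mean,
                              ci_low = perm$ci_low, ci_high = perm$ci_high,
                              outside_ci = perm$outside_ci,
                              n_perm = perm$n_perm, seed = perm$seed),
                   file.path(od, "permutation.tsv"))
  write_tsv_strict(models$table, file.path(od, "model_coefficients.tsv"))
  write_tsv_strict(sig_ratios, file.path(od, "signature_sex_ratios.tsv"))
  write_tsv_strict(activities, file.path(od, "signature_activities.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("immunosel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    config_hash = .config_hash(config),
    stage_seeds = as.list(seeds),
    truth = config$truth,
    estimates = if (!is.null(models$fits[[eq_main]]))
      setNames(models$fits[[eq_main]]$coefficients$estimate,
               models$fits[[eq_main]]$coefficients$term),
    quartile_or = list(phbr_i = or1$or, phbr_ii = or2$or),
    classifier_mean_auroc = cls$mean_auroc)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, catalog = cat_gen, scores = list(I = s1, II = s2),
                 simulation = sim, expression = expr, comparisons = comparisons,
                 permutation = perm, design = design, models = models,
                 quartile_or = list(I = or1, II = or2),
                 signatures = list(ratios = sig_ratios, fractions = sig_fracs),
                 substitution = subst, classifier = cls, manifest = manifest))
}

#' Validate a set of pipeline input files
#'
#' Schema checks for every supplied TSV/FASTA plus cross-file referential
#' integrity: genotype rows must reference known patients, catalog rows
#' must reference proteins present in the FASTA, and each mutation's
#' reference residues must match its context sequence. Problems are
#' reported, not thrown, unless `strict = TRUE`.
#'
#' @param paths named list with any of `patients`, `genotypes`, `catalog`,
#'   `proteins`, `rank_table`.
#' @param strict error on the first problem instead of reporting.
#' @return data.frame (file, issue); zero rows for a clean input set.
#' @export
validate_inputs <- function(paths, strict = FALSE) {
  issues <- list()
  note <- function(file, issue) {
    if (strict) stop(file, ": ", issue)
    issues[[length(issues) + 1L]] <<- data.frame(file = file, issue = issue,
                                                 stringsAsFactors = FALSE)
  }
  load_or_note <- function(name, loader, ...) {
    if (is.null(paths[[name]])) return(NULL)
    tryCatch(loader(paths[[name]], ...), error = function(e) {
      note(paths[[name]], conditionMessage(e)); NULL
    })
  }
  patients <- load_or_note("patients", read_tsv_strict,
                           c("patient_id", "sex", "age_years", "tumor_type"))
  genotypes <- load_or_note("genotypes", read_genotypes)
  catalog <- load_or_note("catalog", read_catalog)
  proteins <- load_or_note("proteins", read_proteins)
  load_or_note("rank_table", read_rank_table)

  if (!is.null(genotypes) && !is.null(patients)) {
    unknown <- setdiff(unique(genotypes$patient_id), patients$patient_id)
    for (u in head(unknown, 20L)) {
      note(paths$genotypes, paste0("genotype references unknown patient ", u))
    }
  }
  if (!is.null(patients) && !is.null(genotypes)) {
    untyped <- setdiff(patients$patient_id, unique(genotypes$patient_id))
    for (u in head(untyped, 20L)) {
      note(paths$patients, paste0("patient ", u, " has no genotype rows"))
    }
  }
  if (!is.null(catalog) && !is.null(proteins)) {
    for (i in seq_len(nrow(catalog))) {
      m <- catalog[i, ]
      prot <- proteins[[m$protein_id]]
      if (is.null(prot)) {
        note(paths$catalog, paste0("mutation ", m$mutation_id,
                                   " references missing protein ", m$protein_id))
        next
      }
      res <- tryCatch({ apply_mutation(prot, m); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        note(paths$catalog, paste0("mutation ", m$mutation_id, ": ", res))
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(file = character(0), issue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
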