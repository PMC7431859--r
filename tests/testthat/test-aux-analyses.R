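make_activity_table <- function(n_per_sex = 40, bias = c(S01 = 1, S05 = 1),
                                seed = 1, tumor_type = "TT") {
  pat <- data.frame(patient_id = sprintf("%s_p%03d", tumor_type, 1:(2 * n_per_sex)),
                    sex = rep(c(0, 1), each = n_per_sex),
                    tumor_type = tumor_type, stringsAsFactors = FALSE)
  simulate_signature_activities(pat, names(bias), sex_bias = bias, seed = seed)
}

test_that("signature sex ratios recover configured biases with BH across the family", {
  act <- rbind(make_activity_table(60, c(S01 = 2, S05 = 1), seed = 2, "AA"),
               make_activity_table(60, c(S01 = 2, S05 = 1), seed = 3, "BB"))
  res <- signature_sex_ratios(act)
  expect_equal(nrow(res), 4) # 2 tumor types x 2 signatures
  biased <- res[res$signature == "S01", ]
  expect_true(all(abs(biased$log2_ratio - 1) < 0.5))
  flat <- res[res$signature == "S05", ]
  expect_true(all(abs(flat$log2_ratio) < 0.5))
  expect_true(all(res$p_bh >= res$p, na.rm = TRUE))
  # antisymmetry under swapping sex labels
  act_swap <- act; act_swap$sex <- 1 - act_swap$sex
  res_swap <- signature_sex_ratios(act_swap)
  expect_equal(res_swap$log2_ratio, -res$log2_ratio, tolerance = 1e-12)
  # stratum with a single female is skipped with a flag
  small <- make_activity_table(2, c(S01 = 1, S05 = 1), seed = 4, "CC")
  small <- small[-which(small$sex == 1)[1], ]
  res_small <- signature_sex_ratios(rbind(act, small))
  expect_true(all(res_small$skipped[res_small$tumor_type == "CC"]))
})

test_that("driver signature fractions sum to 100 with unassigned handling", {
  fr <- driver_signature_fractions(c("A", "A", "B", "unassigned"))
  expect_equal(unname(fr["A"]), 50)
  expect_equal(unname(fr["B"]), 25)
  expect_equal(unname(fr["unassigned"]), 25)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_equal(unname(driver_signature_fractions(rep("S01", 7))["S01"]), 100)
  expect_equal(sum(driver_signature_fractions(c("A", NA, ""))), 100)
  expect_error(driver_signature_fractions(character(0)), "empty")
})

test_that("substitution-class comparison detects constructed presentation bias", {
  set.seed(55)
  gen <- generate_driver_catalog(
    driver_catalog_config(n_mutations = 60, fraction_indels = 0), seed = 56)
  panel <- paste0("A*", sprintf("%02d:01", 1:6))
  ct_ids <- gen$catalog$mutation_id[gen$catalog$substitution_class %in% c("C>T", "T>C")]
  base <- make_synthetic_backend(57)
  # construct a backend that shifts windows of C>T / T>C mutations toward
  # poorer (higher) ranks
  ct_windows <- catalog_windows(gen$catalog[gen$catalog$mutation_id %in% ct_ids, ],
                                gen$proteins, default_window_lengths("I"))
  biased_backend <- function(peptides, molecules) {
    r <- base(peptides, molecules)
    bump <- peptides %in% ct_windows$peptide
    pmin(r + bump * 60, 100)
  }
  res <- substitution_class_presentation(gen$catalog, gen$proteins, panel,
                                         biased_backend,
                                         default_window_lengths("I"))
  expect_lt(res$p, 1e-6)
  expect_gt(res$cliffs_d, 0.3)
  expect_gt(res$median_focal, res$median_other)
  # unbiased backend: effect near zero
  res0 <- substitution_class_presentation(gen$catalog, gen$proteins, panel,
                                          base, default_window_lengths("I"))
  expect_lt(abs(res0$cliffs_d), 0.2)
  # empty class flagged
  cat_one <- gen$catalog
  cat_one$substitution_class <- "C>T"
  expect_warning(res1 <- substitution_class_presentation(
    cat_one, gen$proteins, panel, base, default_window_lengths("I")), "empty")
  expect_true(res1$missing)
})

make_expression_rows <- function(n, seed, labeler = NULL) {
  set.seed(seed)
  rows <- data.frame(
    patient_id = sample(sprintf("p%02d", 1:20), n, replace = TRUE),
    vaf = runif(n, 0.01, 0.9),
    gene = sample(c("TP53", "KRAS", "PIK3CA", "BRAF"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  rows$vaf_percentile_rank <- ave(rows$vaf, rows$patient_id,
                                  FUN = function(v) rank(v) / length(v) * 100)
  rows$expressed <- if (is.null(labeler)) rbinom(n, 1, 0.5) else labeler(rows)
  rows
}

test_that("expression classifier separates separable labels and is reproducible", {
  rows <- make_expression_rows(500, 61, function(r) as.integer(r$vaf > 0.3))
  fit <- fit_expression_classifier(rows, seed = 62)
  expect_gt(fit$mean_auroc, 0.98)
  fit2 <- fit_expression_classifier(rows, seed = 62)
  expect_identical(fit$mean_auroc, fit2$mean_auroc)
  expect_length(fit$fold_auroc, 10)
  # predictions are monotone in VAF when the fitted VAF effect is positive
  grid <- data.frame(patient_id = "px", vaf = seq(0.05, 0.9, length.out = 10),
                     vaf_percentile_rank = 50, gene = "TP53",
                     stringsAsFactors = FALSE)
  pred <- predict_expression(fit, grid)
  expect_true(all(diff(pred$probability) > 0))
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  # unseen gene falls back to baseline with a message
  expect_message(predict_expression(fit, transform(grid, gene = "NOVEL1")),
                 "unseen gene")
  expect_error(predict_expression(fit, grid[, c("vaf", "gene")]),
               "missing feature")
  expect_error(fit_expression_classifier(transform(rows, expressed = 1)),
               "both classes")
})

test_that("label-shuffled data gives chance-level AUROC", {
  aucs <- vapply(1:3, function(s) {
    rows <- make_expression_rows(400, 70 + s)
    fit_expression_classifier(rows, seed = 80 + s)$mean_auroc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("classifier AUROC on generative data is bounded by the Bayes oracle", {
  # generative draw mirroring simulate_expression's read model
  set.seed(90)
  n <- 900
  vaf <- pmax(rbeta(n, 2, 5), 1e-6)
  reads <- rnbinom(n, size = 2, mu = vaf * 60)
  rows <- data.frame(patient_id = sample(sprintf("p%02d", 1:30), n, TRUE),
                     vaf = vaf, gene = "G1", expressed = as.integer(reads >= 5),
                     stringsAsFactors = FALSE)
  rows$vaf_percentile_rank <- ave(rows$vaf, rows$patient_id,
                                  FUN = function(v) rank(v) / length(v) * 100)
  fit <- fit_expression_classifier(rows, seed = 91)
  # Bayes-optimal score is P(expressed | vaf), monotone in vaf: its AUROC is
  # the large-sample upper bound for any feature-based classifier
  bayes_score <- 1 - pnbinom(4, size = 2, mu = rows$vaf * 60)
  bayes_auc <- as.numeric(pROC::auc(pROC::roc(rows$expressed, bayes_score,
                                              quiet = TRUE, direction = "<",
                                              levels = c(0, 1))))
  expect_gt(bayes_auc, 0.6)
  expect_gt(fit$mean_auroc, 0.5 + 0.5 * (bayes_auc - 0.6))
  expect_lt(fit$mean_auroc, bayes_auc + 0.05)
})
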