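#' Sex-specific mutational-signature ratios
#'
#' For each (tumor type, signature) stratum: the log2 ratio of male to
#' female mean activity, a one-tailed Mann-Whitney p-value in the direction
#' of the observed ratio, and Benjamini-Hochberg adjustment across the full
#' family. Strata with fewer than two patients of either sex are skipped
#' (flagged); a zero female mean makes the ratio infinite (flagged).
#'
#' @param activities data.frame with patient_id, sex (0 = male, 1 = female),
#'   tumor_type, and one numeric column per signature.
#' @param signatures signature column names (default: all numeric columns
#'   besides sex).
#' @return data.frame: tumor_type, signature, n_male, n_female, log2_ratio,
#'   p, p_bh, skipped, infinite.
#' @export
signature_sex_ratios <- function(activities, signatures = NULL) {
  if (is.null(signatures)) {
    num <- vapply(activities, is.numeric, TRUE)
    signatures <- setdiff(names(activities)[num], c("sex", "age_years"))
  }
  if (!length(signatures)) stop("no signature columns found")
  if (any(unlist(activities[signatures]) < 0, na.rm = TRUE)) {
    stop("signature activities must be nonnegative")
  }
  tts <- unique(activities$tumor_type)
  rows <- list()
  for (tt in tts) {
    sub <- activities[activities$tumor_type == tt, , drop = FALSE]
    for (s in signatures) {
      male <- sub[[s]][sub$sex == 0]
      female <- sub[[s]][sub$sex == 1]
      skipped <- length(male) < 2 || length(female) < 2
      if (skipped) {
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_type = tt, signature = s, n_male = length(male),
          n_female = length(female), log2_ratio = NA_real_, p = NA_real_,
          skipped = TRUE, infinite = FALSE, stringsAsFactors = FALSE)
        next
      }
      mm <- mean(male); mf <- mean(female)
      infinite <- mf == 0
      ratio <- if (infinite) Inf else log2(mm / mf)
      dir <- if (is.finite(ratio) && ratio < 0) "less" else "greater"
      p <- mann_whitney_one_tailed(male, female, dir)$p
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_type = tt, signature = s, n_male = length(male),
        n_female = length(female), log2_ratio = ratio, p = p,
        skipped = FALSE, infinite = infinite, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !out$skipped
  if (any(ok)) out$p_bh[ok] <- bh_adjust(out$p[ok])
  out
}

#' Percentage of the driver set attributed to each signature
#'
#' @param labels character vector of per-mutation signature labels
#'   (unlabeled mutations should carry "unassigned").
#' @return named numeric percentages summing to 100.
#' @export
driver_signature_fractions <- function(labels) {
  if (!length(labels)) stop("empty mutation catalog")
  labels[is.na(labels) | labels == ""] <- "unassigned"
  tab <- table(labels)
  setNames(100 * as.numeric(tab) / length(labels), names(tab))
}

#' Presentation of C>T / T>C versus other substitutions across an allele panel
#'
#' Pools per-(mutation, molecule) best ranks over the whole configured
#' molecule panel (independent of patient genotypes) and compares the
#' age-associated substitution classes (C>T, T>C) against all other
#' mutations with a one-tailed Mann-Whitney test (alternative: C>T / T>C
#' more poorly presented, i.e. higher ranks) and Cliff's d.
#'
#' @param catalog driver catalog with a `substitution_class` column.
#' @param proteins named character vector of context sequences.
#' @param molecules character vector: the allele/molecule panel.
#' @param backend rank backend function.
#' @param lengths window length set.
#' @return list: n_focal, n_other, median_focal, median_other, U, p,
#'   cliffs_d, missing.
#' @export
substitution_class_presentation <- function(catalog, proteins, molecules,
                                            backend, lengths) {
  if (!"substitution_class" %in% names(catalog)) {
    stop("catalog lacks a substitution_class column")
  }
  best <- best_rank_matrix(catalog, proteins, backend, molecules, lengths)
  focal_mut <- catalog$mutation_id[catalog$substitution_class %in% c("C>T", "T>C")]
  other_mut <- setdiff(catalog$mutation_id, focal_mut)
  focal <- as.vector(best[rownames(best) %in% focal_mut, , drop = FALSE])
  other <- as.vector(best[rownames(best) %in% other_mut, , drop = FALSE])
  if (!length(focal) || !length(other)) {
    warning("one substitution class is empty; comparison flagged missing")
    return(list(n_focal = length(focal), n_other = length(other),
                median_focal = NA_real_, median_other = NA_real_,
                U = NA_real_, p = NA_real_, cliffs_d = NA_real_,
                missing = TRUE))
  }
  mw <- mann_whitney_one_tailed(focal, other, "greater")
  list(n_focal = length(focal), n_other = length(other),
       median_focal = median(focal), median_other = median(other),
       U = mw$U, p = mw$p, cliffs_d = cliffs_d(focal, other),
       missing = FALSE)
}

.classifier_matrix <- function(rows, gene_levels) {
  x <- cbind(vaf = rows$vaf, vaf_percentile_rank = rows$vaf_percentile_rank)
  for (g in gene_levels) x <- cbind(x, as.numeric(rows$gene == g))
  colnames(x) <- c("vaf", "vaf_percentile_rank", paste0("gene_", gene_levels))
  x
}

#' Train the VAF-based RNA-expression classifier
#'
#' Logistic classifier of the binary expressed label (>= 5 mutant RNA
#' reads) on DNA VAF, within-patient VAF percentile rank, and a one-hot
#' mutated-gene encoding, with internal regularization-strength selection
#' (ridge path via `glmnet::cv.glmnet`). Performance is reported as the
#' mean AUROC over stratified `n_folds`-fold cross-validation.
#'
#' @param rows data.frame with columns vaf, vaf_percentile_rank, gene,
#'   expressed (0/1).
#' @param n_folds number of outer CV folds (default 10).
#' @param seed integer seed (fold assignment and inner CV).
#' @return object of class `expression_classifier`: list with `fit`
#'   (glmnet), `lambda`, `gene_levels`, `mean_auroc`, `fold_auroc`,
#'   `n_folds`, `threshold`.
#' @export
fit_expression_classifier <- function(rows, n_folds = 10, seed = 1) {
  stopifnot(all(c("vaf", "vaf_percentile_rank", "gene", "expressed") %in% names(rows)))
  y <- as.integer(rows$expressed)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (sum(y == 1) < n_folds || sum(y == 0) < n_folds) {
    stop("need at least ", n_folds, " examples of each class")
  }
  gene_levels <- sort(unique(rows$gene))
  x <- .classifier_matrix(rows, gene_levels)
  set.seed(as.integer(seed))
  # stratified outer folds
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  # inner lambda-selection folds are stratified too, so no fold loses a class
  inner_cv <- function(xs, ys) {
    nf <- max(3L, min(5L, sum(ys == 1), sum(ys == 0)))
    fid <- integer(length(ys))
    for (cls in c(0L, 1L)) {
      i <- which(ys == cls)
      fid[i] <- sample(rep_len(seq_len(nf), length(i)))
    }
    glmnet::cv.glmnet(xs, ys, family = "binomial", alpha = 0, foldid = fid)
  }
  aucs <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    cv <- inner_cv(x[tr, , drop = FALSE], y[tr])
    prob <- as.numeric(predict(cv, x[!tr, , drop = FALSE], s = "lambda.min",
                               type = "response"))
    aucs[k] <- as.numeric(pROC::auc(pROC::roc(y[!tr], prob, quiet = TRUE,
                                              direction = "<", levels = c(0, 1))))
  }
  cv_full <- inner_cv(x, y)
  structure(list(fit = cv_full$glmnet.fit, lambda = cv_full$lambda.min,
                 gene_levels = gene_levels, mean_auroc = mean(aucs),
                 fold_auroc = aucs, n_folds = n_folds, threshold = 0.5),
            class = "expression_classifier")
}

#' Predict expression probabilities and binary calls
#'
#' Rows with genes unseen in training fall back to the no-gene-effect
#' baseline (all gene indicators zero), with a message.
#'
#' @param model an `expression_classifier`.
#' @param rows data.frame with vaf, vaf_percentile_rank, gene.
#' @param threshold probability cutoff for the binary call (default the
#'   model's stored 0.5).
#' @return data.frame: probability, expressed_call.
#' @export
predict_expression <- function(model, rows, threshold = model$threshold) {
  stopifnot(inherits(model, "expression_classifier"))
  need <- c("vaf", "vaf_percentile_rank", "gene")
  missing <- need[!need %in% names(rows)]
  if (length(missing)) stop("missing feature column(s): ",
                            paste(missing, collapse = ", "))
  if (anyNA(rows[need])) stop("missing feature values in prediction rows")
  unseen <- setdiff(unique(rows$gene), model$gene_levels)
  if (length(unseen)) {
    message(length(unseen), " unseen gene label(s) fall back to baseline")
  }
  x <- .classifier_matrix(rows, model$gene_levels)
  prob <- as.numeric(predict(model$fit, x, s = model$lambda, type = "response"))
  data.frame(probability = prob, expressed_call = as.integer(prob >= threshold))
}
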