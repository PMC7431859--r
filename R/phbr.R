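#' Best residue presentation rank for one molecule
#'
#' The minimum percentile rank over a mutation's peptide windows for a given
#' molecule: the single best chance that molecule has of presenting any
#' peptide covering the altered residue(s). Every window must be scored;
#' missing (peptide, molecule) pairs are an error, never silently skipped.
#'
#' @param rank_table data.frame (peptide, molecule, rank).
#' @param molecule molecule name.
#' @param windows character vector of window peptide sequences.
#' @return the minimum rank (positive scalar).
#' @export
best_residue_rank <- function(rank_table, molecule, windows) {
  windows <- unique(as.character(windows))
  sub <- rank_table[rank_table$molecule == molecule &
                      rank_table$peptide %in% windows, , drop = FALSE]
  missing <- setdiff(windows, sub$peptide)
  if (length(missing)) {
    stop("unscored window(s) for molecule ", molecule, ": ",
         paste(head(missing, 10L), collapse = ", "))
  }
  min(sub$rank)
}

#' Patient harmonic-mean best rank (PHBR)
#'
#' Aggregates the per-slot best ranks of a patient's scoring molecules into a
#' single presentation score: the harmonic mean `n / sum(1/s_k)`. The
#' harmonic mean is dominated by the best-presenting (lowest-rank) molecule,
#' so a patient presents a mutation well if any one molecule does. A low
#' PHBR means good presentation.
#'
#' @param slot_ranks numeric vector of per-slot best ranks, all > 0; length
#'   must be 6 (class I) or 12 (class II) unless `n_slots = NA`.
#' @param n_slots required slot count (6 or 12); `NA` skips the count check
#'   (used by formula-level tests).
#' @return the harmonic mean (positive scalar, bounded by min and max of the
#'   inputs).
#' @export
phbr <- function(slot_ranks, n_slots = NA) {
  if (!is.numeric(slot_ranks) || !length(slot_ranks)) {
    stop("slot_ranks must be a nonempty numeric vector")
  }
  if (any(!is.finite(slot_ranks) | slot_ranks <= 0)) {
    stop("all slot ranks must be finite and > 0")
  }
  if (!is.na(n_slots) && length(slot_ranks) != n_slots) {
    stop("expected ", n_slots, " slot ranks, got ", length(slot_ranks))
  }
  length(slot_ranks) / sum(1 / slot_ranks)
}

#' Best rank per (mutation, molecule) over a molecule panel
#'
#' For every catalog mutation, enumerates its peptide windows, scores every
#' distinct (window, molecule) pair with the backend, and takes each
#' molecule's minimum rank over the mutation's windows. This is the shared
#' core of per-patient PHBR scoring and panel-wide presentation analyses.
#'
#' @param catalog driver catalog data.frame.
#' @param proteins named character vector of context sequences.
#' @param backend rank backend function.
#' @param molecules character vector of molecule names (the panel).
#' @param lengths window length set.
#' @return numeric matrix, rownames = mutation_id, colnames = molecule.
#' @export
best_rank_matrix <- function(catalog, proteins, backend, molecules, lengths) {
  if (!length(molecules)) stop("molecule panel is empty")
  wins <- catalog_windows(catalog, proteins, lengths)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", wins$peptide)
  if (any(!ok)) {
    message("excluding ", sum(!ok), " window(s) with non-standard residues")
    wins <- wins[ok, , drop = FALSE]
  }
  mutations <- unique(catalog$mutation_id)
  pep <- unique(wins$peptide)
  grid <- expand.grid(peptide = pep, molecule = molecules,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rank <- backend(grid$peptide, grid$molecule)
  if (any(!is.finite(grid$rank) | grid$rank <= 0)) {
    bad <- which(!is.finite(grid$rank) | grid$rank <= 0)
    stop("backend returned non-positive/non-finite rank for ",
         length(bad), " pair(s), e.g. (", grid$peptide[bad[1]], ", ",
         grid$molecule[bad[1]], ")")
  }
  rank_mat <- matrix(grid$rank, nrow = length(pep), ncol = length(molecules),
                     dimnames = list(pep, molecules))
  best <- matrix(NA_real_, nrow = length(mutations), ncol = length(molecules),
                 dimnames = list(mutations, molecules))
  idx <- split(wins$peptide, factor(wins$mutation_id, levels = mutations))
  for (j in seq_along(mutations)) {
    wp <- idx[[j]]
    if (!length(wp)) stop("mutation ", mutations[j], " has no scorable windows")
    best[j, ] <- apply(rank_mat[wp, , drop = FALSE], 2L, min)
  }
  best
}

#' Patients x mutations PHBR score matrix
#'
#' For one MHC class, computes the dense score matrix: for every mutation,
#' each of the patient's 6 (class I) or 12 (class II) molecule slots takes
#' its best (minimum) rank over the mutation's peptide windows, and the
#' slots are aggregated by harmonic mean. Patients with incomplete typing
#' for the class are excluded from the matrix (not imputed); they remain
#' available to the other class.
#'
#' Internally the per-(mutation, molecule) best ranks are computed once over
#' the distinct molecules in the cohort, so cohorts sharing alleles score in
#' far less than patients x mutations x slots backend calls.
#'
#' @param genotypes genotype data.frame (patient_id, gene, allele).
#' @param catalog driver catalog data.frame.
#' @param proteins named character vector of context sequences.
#' @param backend rank backend function.
#' @param class "I" or "II".
#' @param lengths window lengths (default [default_window_lengths()]).
#' @param allele_allowlist optional character vector of allele names the
#'   rank backend supports; patients carrying any allele of this class
#'   outside the list are excluded (emulating predictor-compatibility
#'   exclusions), with a message.
#' @return numeric matrix, rownames = patient_id, colnames = mutation_id.
#' @export
score_matrix <- function(genotypes, catalog, proteins, backend, class,
                         lengths = default_window_lengths(class),
                         allele_allowlist = NULL) {
  class <- match_mhc_class(class)
  n_slots <- if (class == "I") 6L else 12L
  class_genes <- if (class == "I") .CLASS_I_GENES else .CLASS_II_GENES
  patients <- unique(genotypes$patient_id)
  slots <- list()
  n_incompatible <- 0L
  for (p in patients) {
    g <- genotype_of(genotypes, p)
    if (!is_complete(g, class)) next
    if (!is.null(allele_allowlist) &&
        !all(unlist(g[class_genes]) %in% allele_allowlist)) {
      n_incompatible <- n_incompatible + 1L
      next
    }
    slots[[as.character(p)]] <- assemble_molecules(g, class)
  }
  if (n_incompatible > 0) {
    message("excluding ", n_incompatible,
            " patient(s) with alleles outside the allow-list")
  }
  if (!length(slots)) stop("no patient has complete class ", class, " typing")
  kept <- names(slots)
  if (length(kept) < length(patients)) {
    message("excluding ", length(patients) - length(kept),
            " patient(s) with incomplete class ", class, " typing")
  }
  molecules <- sort(unique(unlist(slots, use.names = FALSE)))
  best <- best_rank_matrix(catalog, proteins, backend, molecules, lengths)
  mutations <- rownames(best)
  # harmonic mean over each patient's slots
  inv <- 1 / best
  out <- matrix(NA_real_, nrow = length(kept), ncol = length(mutations),
                dimnames = list(kept, mutations))
  for (i in seq_along(kept)) {
    s <- slots[[kept[i]]] # slot multiplicity preserved (homozygotes count twice)
    out[i, ] <- n_slots / rowSums(inv[, s, drop = FALSE])
  }
  out
}

#' Classify a percentile rank or PHBR score into binding categories
#'
#' Standard cutoffs: class I strong < 0.5, weak < 2; class II strong < 2,
#' weak < 10 (strict `<`; a value exactly on a boundary falls in the poorer
#' category).
#'
#' @param value positive score(s).
#' @param class "I" or "II".
#' @return character vector in {"strong", "weak", "nonbinder"}.
#' @export
classify_binding <- function(value, class) {
  class <- match_mhc_class(class)
  if (any(value <= 0)) stop("scores must be positive")
  cuts <- if (class == "I") c(strong = 0.5, weak = 2) else c(strong = 2, weak = 10)
  ifelse(value < cuts["strong"], "strong",
         ifelse(value < cuts["weak"], "weak", "nonbinder"))
}

#' Per-patient fraction of mutations presented below a score threshold
#'
#' @param scores patients x mutations PHBR matrix.
#' @param threshold positive score threshold (strict `<`).
#' @return named numeric vector of fractions in `[0, 1]` per patient; `NA`
#'   for a patient with no scored mutations.
#' @export
fraction_presented <- function(scores, threshold) {
  stopifnot(is.matrix(scores))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (!ncol(scores)) {
    warning("empty mutation set; fractions undefined")
    return(setNames(rep(NA_real_, nrow(scores)), rownames(scores)))
  }
  apply(scores, 1L, function(r) mean(r < threshold, na.rm = TRUE))
}

#' Long-format PHBR table
#'
#' Flattens aligned score / occurrence / expression matrices into one row per
#' (patient, mutation) cell for the comparison module.
#'
#' @param scores patients x mutations PHBR matrix.
#' @param occurrence binary occurrence matrix aligned with `scores` (or NULL).
#' @param expressed logical/binary expressed matrix aligned with `scores` (or
#'   NULL).
#' @param class "I" or "II" label for the output.
#' @return data.frame (patient_id, mutation_id, class, phbr, occurred,
#'   expressed).
#' @export
phbr_long <- function(scores, occurrence = NULL, expressed = NULL, class) {
  class <- match_mhc_class(class)
  align <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!all(rownames(scores) %in% rownames(m)) ||
        !all(colnames(scores) %in% colnames(m))) {
      stop(what, " matrix does not cover the score matrix")
    }
    m[rownames(scores), colnames(scores), drop = FALSE]
  }
  occurrence <- align(occurrence, "occurrence")
  expressed <- align(expressed, "expressed")
  df <- data.frame(
    patient_id = rep(rownames(scores), times = ncol(scores)),
    mutation_id = rep(colnames(scores), each = nrow(scores)),
    class = class,
    phbr = as.vector(scores),
    stringsAsFactors = FALSE)
  df$occurred <- if (is.null(occurrence)) NA_integer_ else as.integer(as.vector(occurrence))
  df$expressed <- if (is.null(expressed)) NA_integer_ else as.integer(as.vector(expressed))
  df
}
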