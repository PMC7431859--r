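#' Parse and normalize an HLA allele name
#'
#' Allele names use standard two-field nomenclature, e.g. `"A*02:01"` or
#' `"DRB1*15:01"`. Higher-resolution input (`"A*02:01:01"`) is truncated to
#' two fields with a warning; the gene prefix must be one of A, B, C, DRB1,
#' DPA1, DPB1, DQA1, DQB1.
#'
#' @param name allele name string.
#' @return list with elements `gene` and `name` (normalized).
#' @export
parse_hla_allele <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  parts <- strsplit(name, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("unparseable HLA allele name: '", name, "'")
  gene <- parts[1]
  if (!gene %in% .HLA_GENES) stop("unknown HLA gene '", gene, "' in allele '", name, "'")
  fields <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  if (length(fields) < 2L || any(!grepl("^[0-9]+$", fields))) {
    stop("unparseable HLA allele fields in '", name, "'")
  }
  if (length(fields) > 2L) {
    warning("allele '", name, "' truncated to two-field resolution")
    fields <- fields[1:2]
  }
  list(gene = gene, name = paste0(gene, "*", paste(fields, collapse = ":")))
}

#' Construct an HLA genotype
#'
#' A genotype carries exactly two allele slots per typed gene (homozygotes
#' repeat the allele). Genes missing from `alleles` are treated as untyped,
#' which makes the corresponding class incomplete.
#'
#' @param alleles named list, `gene -> character(2)` of allele names.
#' @return an object of class `hla_genotype`.
#' @export
hla_genotype <- function(alleles) {
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  out <- list()
  for (gene in names(alleles)) {
    a <- alleles[[gene]]
    if (length(a) != 2L) stop("gene ", gene, " must have exactly two allele slots")
    parsed <- lapply(a, parse_hla_allele)
    genes <- vapply(parsed, `[[`, "", "gene")
    if (any(genes != gene)) {
      stop("allele(s) ", paste(a[genes != gene], collapse = ", "),
           " inconsistent with gene ", gene)
    }
    out[[gene]] <- sort(vapply(parsed, `[[`, "", "name"))
  }
  structure(out, class = "hla_genotype")
}

#' Is a genotype completely typed for an MHC class?
#'
#' @param genotype an `hla_genotype`.
#' @param class "I" or "II".
#' @return logical; complete class I requires A, B, C (6 slots), complete
#'   class II requires DRB1, DPA1, DPB1, DQA1, DQB1 (10 allele slots).
#' @export
is_complete <- function(genotype, class) {
  genes <- switch(match_mhc_class(class), I = .CLASS_I_GENES, II = .CLASS_II_GENES)
  all(genes %in% names(genotype))
}

#' Assemble the scoring molecule set for one MHC class
#'
#' Class I scoring uses the patient's 6 classical class I alleles (HLA-A/B/C,
#' two slots each; homozygous alleles occupy two slots). Class II scoring uses
#' 12 molecule slots: the 4 DPA1/DPB1 alpha-beta combinations, the 4
#' DQA1/DQB1 combinations, and each DRB1 allele counted twice (the DR alpha
#' chain is invariant, so DR contributes 4 slots for consistency with DP/DQ).
#' Slot order is deterministic: gene groups in order (I: A, B, C; II: DP, DQ,
#' DR), alleles lexicographically within a gene.
#'
#' @param genotype an `hla_genotype`.
#' @param class "I" or "II".
#' @return character vector of molecule names (length 6 or 12). Class II
#'   heterodimers are named `"DPA1*x-DPB1*y"` etc.; DR molecules by their
#'   beta allele.
#' @export
assemble_molecules <- function(genotype, class) {
  class <- match_mhc_class(class)
  genes <- if (class == "I") .CLASS_I_GENES else .CLASS_II_GENES
  missing <- setdiff(genes, names(genotype))
  if (length(missing)) {
    stop("genotype incomplete for class ", class, ": missing gene(s) ",
         paste(missing, collapse = ", "))
  }
  if (class == "I") {
    slots <- unlist(lapply(.CLASS_I_GENES, function(g) sort(genotype[[g]])),
                    use.names = FALSE)
  } else {
    pair <- function(alpha, beta) {
      combos <- character(0)
      for (a in sort(genotype[[alpha]])) {
        for (b in sort(genotype[[beta]])) combos <- c(combos, paste0(a, "-", b))
      }
      combos
    }
    dr <- rep(sort(genotype[["DRB1"]]), each = 2L)
    slots <- c(pair("DPA1", "DPB1"), pair("DQA1", "DQB1"), dr)
  }
  slots
}

#' Read / write genotype tables
#'
#' The genotype TSV dialect is one row per allele slot with columns
#' `patient_id`, `gene`, `allele`.
#'
#' @param path file path.
#' @return data.frame with columns patient_id, gene, allele.
#' @export
read_genotypes <- function(path) {
  read_tsv_strict(path, c("patient_id", "gene", "allele"))
}

#' @rdname read_genotypes
#' @param genotypes genotype data.frame (patient_id, gene, allele).
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(all(c("patient_id", "gene", "allele") %in% names(genotypes)))
  write_tsv_strict(genotypes[, c("patient_id", "gene", "allele")], path)
}

#' Extract one patient's genotype from a genotype table
#'
#' @param genotypes genotype data.frame (patient_id, gene, allele).
#' @param patient_id patient to extract.
#' @return an `hla_genotype`.
#' @export
genotype_of <- function(genotypes, patient_id) {
  rows <- genotypes[genotypes$patient_id == patient_id, , drop = FALSE]
  if (!nrow(rows)) stop("no genotype rows for patient ", patient_id)
  alleles <- split(rows$allele, rows$gene)
  hla_genotype(alleles)
}

#' Per-group allele frequencies over the observed allele universe
#'
#' Counts allele slots per class within each group of patients and converts
#' to frequencies over the union of alleles observed anywhere in the cohort
#' (alleles absent from a group get frequency 0).
#'
#' @param genotypes genotype data.frame (patient_id, gene, allele).
#' @param groups named character/factor vector, `patient_id -> group label`.
#' @param class "I" or "II".
#' @return named list `group -> named numeric frequency vector`; every vector
#'   is aligned on the same allele universe and sums to 1.
#' @export
allele_frequencies <- function(genotypes, groups, class) {
  class <- match_mhc_class(class)
  genes <- if (class == "I") .CLASS_I_GENES else .CLASS_II_GENES
  rows <- genotypes[genotypes$gene %in% genes, , drop = FALSE]
  lv <- unique(as.character(groups))
  universe <- sort(unique(rows$allele))
  out <- list()
  for (g in lv) {
    ids <- names(groups)[as.character(groups) == g]
    sub <- rows[rows$patient_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) stop("group '", g, "' has no genotyped patients")
    counts <- table(factor(sub$allele, levels = universe))
    out[[g]] <- as.numeric(counts) / sum(counts)
    names(out[[g]]) <- universe
  }
  out
}

#' Pearson correlation of two allele-frequency vectors
#'
#' Vectors are aligned on the union of their allele names (absent alleles
#' count as frequency 0). A zero-variance vector makes the correlation
#' undefined; `NA` is returned with a warning.
#'
#' @param freq_a,freq_b named numeric frequency vectors.
#' @return Pearson R in `[-1, 1]`, or `NA` if degenerate.
#' @export
genotype_frequency_correlation <- function(freq_a, freq_b) {
  stopifnot(is.numeric(freq_a), is.numeric(freq_b))
  universe <- union(names(freq_a), names(freq_b))
  if (is.null(universe)) {
    if (length(freq_a) != length(freq_b)) stop("unnamed vectors of unequal length")
    a <- freq_a; b <- freq_b
  } else {
    a <- setNames(rep(0, length(universe)), universe)
    b <- a
    a[names(freq_a)] <- freq_a
    b[names(freq_b)] <- freq_b
  }
  if (var(a) == 0 || var(b) == 0) {
    warning("zero-variance frequency vector; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
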