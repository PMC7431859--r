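#' Apply a protein-level driver mutation to its context sequence
#'
#' Supported kinds are missense substitutions and inframe indels (whole
#' residues). The returned altered-position set marks which residues of the
#' mutant sequence are novel: the substituted residue for missense; all
#' inserted residues plus one flanking residue on each side for insertions;
#' the single junction residue for deletions. Windows overlapping this set
#' are the ones that can contain mutation-derived peptides.
#'
#' @param protein context protein sequence (string of one-letter residues).
#' @param mutation list or one-row data.frame with fields `kind`
#'   ("missense" or "inframe_indel"), `pos` (1-based), `ref`, `alt`
#'   (empty `ref` = insertion after `pos`; empty `alt` = deletion of `ref`
#'   starting at `pos`).
#' @return list with `mutant` (mutant sequence) and `altered` (sorted integer
#'   positions in mutant coordinates).
#' @export
apply_mutation <- function(protein, mutation) {
  stopifnot(is.character(protein), length(protein) == 1L)
  m <- as.list(mutation)
  pos <- as.integer(m$pos)
  ref <- as.character(m$ref)
  alt <- as.character(m$alt)
  if (is.na(ref)) ref <- ""
  if (is.na(alt)) alt <- ""
  n <- nchar(protein)
  if (pos < 1L || pos > n + (ref == "")) {
    stop("mutation position ", pos, " outside protein of length ", n)
  }
  if (nzchar(ref)) {
    found <- substr(protein, pos, pos + nchar(ref) - 1L)
    if (found != ref) {
      stop("reference mismatch at position ", pos, ": expected '", ref,
           "', found '", found, "'")
    }
  }
  if (identical(m$kind, "missense")) {
    if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt) {
      stop("missense mutation requires single differing ref/alt residues")
    }
    mutant <- paste0(substr(protein, 1L, pos - 1L), alt,
                     substr(protein, pos + 1L, n))
    altered <- pos
  } else if (identical(m$kind, "inframe_indel")) {
    if (nzchar(ref)) {
      left <- substr(protein, 1L, pos - 1L)
      right <- substr(protein, pos + nchar(ref), n)
    } else {
      left <- substr(protein, 1L, pos)
      right <- substr(protein, pos + 1L, n)
    }
    mutant <- paste0(left, alt, right)
    nm <- nchar(mutant)
    if (nzchar(alt)) {
      # inserted / replacing residues plus one flank on each side
      ins_start <- nchar(left) + 1L
      ins_end <- nchar(left) + nchar(alt)
      altered <- (ins_start - 1L):(ins_end + 1L)
    } else {
      # pure deletion: the junction residue (first residue after the join)
      altered <- min(pos, nm)
    }
    altered <- sort(unique(altered[altered >= 1L & altered <= nm]))
    if (!length(altered)) stop("indel leaves no altered residues in range")
  } else {
    stop("unknown mutation kind: ", m$kind)
  }
  list(mutant = mutant, altered = altered)
}

#' Enumerate peptide windows covering altered residues
#'
#' Returns all and only the substrings of each configured length that contain
#' at least one altered residue, clipped at the protein termini. An interior
#' missense mutation (at least `max(lengths) - 1` residues from both termini)
#' therefore yields `sum(lengths)` windows: 38 for class I lengths 8-11, 15
#' for the class II 15mer.
#'
#' @param mutant mutant protein sequence.
#' @param altered integer positions (1-based, mutant coordinates).
#' @param lengths integer vector of window lengths (see
#'   [default_window_lengths()]).
#' @return data.frame with columns `peptide`, `start`, `length`; windows are
#'   unique and ordered by length then start.
#' @export
extract_windows <- function(mutant, altered, lengths) {
  stopifnot(is.character(mutant), length(mutant) == 1L)
  n <- nchar(mutant)
  altered <- as.integer(altered)
  if (any(altered < 1L | altered > n)) {
    stop("altered position(s) outside mutant sequence of length ", n)
  }
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L)) stop("window lengths must be positive")
  if (n < max(lengths)) {
    stop("mutant sequence (", n, " aa) shorter than longest window (",
         max(lengths), " aa)")
  }
  out <- list()
  for (L in lengths) {
    starts <- integer(0)
    for (p in altered) {
      s <- max(1L, p - L + 1L):min(p, n - L + 1L)
      starts <- c(starts, s)
    }
    starts <- sort(unique(starts))
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = substring(mutant, starts, starts + L - 1L),
        start = starts, length = L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Deterministic synthetic percentile-rank backend
#'
#' A desk-scale stand-in for an external peptide-MHC affinity predictor.
#' The rank for a (peptide, molecule) pair is a pure hash of the pair and the
#' seed: marginally near-Uniform(0, 100] over random peptides, bit-for-bit
#' reproducible, and molecule-specific (each molecule carries a seeded
#' anchor-residue preference), so different genotypes produce different
#' presentation structure.
#'
#' @param peptides character vector of peptide sequences.
#' @param molecules character vector of molecule names (recycled against
#'   peptides if one has length 1).
#' @param seed integer backend seed.
#' @return numeric vector of percentile ranks in (0, 100].
#' @export
synthetic_rank_backend <- function(peptides, molecules, seed) {
  n <- max(length(peptides), length(molecules))
  peptides <- rep_len(as.character(peptides), n)
  molecules <- rep_len(as.character(molecules), n)
  synth_rank_cpp(peptides, molecules, as.integer(seed))
}

#' Construct rank-prediction backends
#'
#' A backend is a function `(peptides, molecules) -> ranks` used by
#' [predict_ranks()] and [score_matrix()]. `make_synthetic_backend` wraps the
#' deterministic hash backend; `make_table_backend` serves ranks from a
#' precomputed [read_rank_table()] table and errors on missing pairs.
#'
#' @param seed integer seed for the synthetic backend.
#' @return a backend function.
#' @export
make_synthetic_backend <- function(seed) {
  force(seed)
  function(peptides, molecules) synthetic_rank_backend(peptides, molecules, seed)
}

#' @rdname make_synthetic_backend
#' @param rank_table data.frame (peptide, molecule, rank).
#' @export
make_table_backend <- function(rank_table) {
  stopifnot(all(c("peptide", "molecule", "rank") %in% names(rank_table)))
  key <- paste(rank_table$peptide, rank_table$molecule, sep = "\r")
  lut <- setNames(rank_table$rank, key)
  function(peptides, molecules) {
    n <- max(length(peptides), length(molecules))
    peptides <- rep_len(peptides, n)
    molecules <- rep_len(molecules, n)
    k <- paste(peptides, molecules, sep = "\r")
    r <- unname(lut[k])
    if (anyNA(r)) {
      bad <- which(is.na(r))
      show <- head(bad, 10L)
      stop("rank table is missing ", length(bad), " (peptide, molecule) pair(s), e.g. ",
           paste(sprintf("(%s, %s)", peptides[show], molecules[show]), collapse = "; "))
    }
    r
  }
}

#' Score all peptide x molecule pairs with a backend
#'
#' Peptides containing non-standard residues (B, J, O, U, X, Z or other
#' characters outside the 20 standard amino acids) are excluded from scoring
#' with a message reporting the count.
#'
#' @param peptides character vector of peptides.
#' @param molecules character vector of molecule names.
#' @param backend a backend function (see [make_synthetic_backend()]).
#' @return data.frame (peptide, molecule, rank), one row per retained pair.
#' @export
predict_ranks <- function(peptides, molecules, backend) {
  peptides <- unique(as.character(peptides))
  molecules <- unique(as.character(molecules))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides)
  if (any(!ok)) {
    message("excluding ", sum(!ok), " peptide(s) with non-standard residues")
    peptides <- peptides[ok]
  }
  grid <- expand.grid(peptide = peptides, molecule = molecules,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rank <- tryCatch(backend(grid$peptide, grid$molecule), error = function(e) {
    stop("rank backend failed: ", conditionMessage(e))
  })
  if (any(!is.finite(rank) | rank <= 0 | rank > 100)) {
    bad <- which(!is.finite(rank) | rank <= 0 | rank > 100)[1]
    stop("backend returned invalid rank ", rank[bad], " for (",
         grid$peptide[bad], ", ", grid$molecule[bad], ")")
  }
  data.frame(peptide = grid$peptide, molecule = grid$molecule, rank = rank,
             stringsAsFactors = FALSE)
}

#' Read / write percentile-rank tables
#'
#' TSV with columns `peptide`, `molecule`, `rank`. Ranks must lie in
#' (0, 100]; duplicate (peptide, molecule) pairs are rejected with their line
#' numbers. Writing then reading restores an identical table.
#'
#' @param path file path.
#' @return data.frame (peptide, molecule, rank).
#' @export
read_rank_table <- function(path) {
  tab <- read_tsv_strict(path, c("peptide", "molecule", "rank"))
  tab$rank <- as.numeric(tab$rank)
  bad <- which(!is.finite(tab$rank) | tab$rank <= 0 | tab$rank > 100)
  if (length(bad)) {
    stop("invalid rank value(s) at data line(s) ",
         paste(head(bad, 10L), collapse = ", "), " of ", path)
  }
  key <- paste(tab$peptide, tab$molecule)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (peptide, molecule) pair(s) at data line(s) ",
         paste(head(dup, 10L), collapse = ", "), " of ", path)
  }
  tab
}

#' @rdname read_rank_table
#' @param rank_table data.frame (peptide, molecule, rank).
#' @export
write_rank_table <- function(rank_table, path) {
  stopifnot(all(c("peptide", "molecule", "rank") %in% names(rank_table)))
  if (any(rank_table$rank <= 0 | rank_table$rank > 100)) {
    stop("rank values must lie in (0, 100]")
  }
  key <- paste(rank_table$peptide, rank_table$molecule)
  if (anyDuplicated(key)) stop("duplicate (peptide, molecule) pairs")
  write_tsv_strict(rank_table[, c("peptide", "molecule", "rank")], path)
}

#' Read / write protein context sequences (FASTA)
#'
#' @param path FASTA file path.
#' @return named character vector, `protein_id -> sequence`.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' @rdname read_proteins
#' @param proteins named character vector of sequences.
#' @export
write_proteins <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read / write driver-mutation catalogs
#'
#' MAF-like TSV with columns `mutation_id`, `gene`, `protein_id`, `kind`,
#' `pos`, `ref`, `alt`, `substitution_class`, `signature`.
#'
#' @param path file path.
#' @return catalog data.frame.
#' @export
read_catalog <- function(path) {
  cat <- read_tsv_strict(path, c("mutation_id", "gene", "protein_id", "kind",
                                 "pos", "ref", "alt"))
  cat$pos <- as.integer(cat$pos)
  cat$ref[is.na(cat$ref)] <- ""
  cat$alt[is.na(cat$alt)] <- ""
  cat
}

#' @rdname read_catalog
#' @param catalog catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_strict(catalog, path)
}

#' All peptide windows for every mutation in a catalog
#'
#' @param catalog catalog data.frame (see [read_catalog()]).
#' @param proteins named character vector of context sequences.
#' @param lengths window length set.
#' @return data.frame (mutation_id, peptide, start, length).
#' @export
catalog_windows <- function(catalog, proteins, lengths) {
  out <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    m <- catalog[i, ]
    prot <- proteins[[m$protein_id]]
    if (is.null(prot)) stop("protein ", m$protein_id, " not found for mutation ",
                            m$mutation_id)
    mut <- apply_mutation(prot, m)
    w <- extract_windows(mut$mutant, mut$altered, lengths)
    w$mutation_id <- m$mutation_id
    out[[i]] <- w[, c("mutation_id", "peptide", "start", "length")]
  }
  do.call(rbind, out)
}
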