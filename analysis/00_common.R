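# Shared plumbing for the numbered analysis drivers. Each driver is run from
# the repository root as e.g.
#
#   Rscript analysis/01_simulate_cohort.R --seed 1
#
# and writes its tables under results/. All drivers must be run with the
# same --seed; every stage seed derives from it.

suppressPackageStartupMessages(library(immunosel))

cli_seed <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && i < length(args)) as.integer(args[i + 1]) else 1L
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

read_tsv <- function(name) {
  read.delim(file.path("results", name), sep = "\t",
             stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, name) {
  write.table(df, file.path(results_dir(), name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("  wrote results/", name)
}

# long (patient_id, mutation_id, value) -> patients x mutations matrix
long_to_matrix <- function(long, value) {
  pats <- unique(long$patient_id)
  muts <- unique(long$mutation_id)
  m <- matrix(NA_real_, length(pats), length(muts), dimnames = list(pats, muts))
  m[cbind(match(long$patient_id, pats), match(long$mutation_id, muts))] <-
    long[[value]]
  m
}
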