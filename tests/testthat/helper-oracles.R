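# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (pairwise loops, exhaustive enumeration,
# compensated arithmetic) so they share no code with the implementation.

# harmonic mean via Neumaier-compensated reciprocal summation
oracle_harmonic <- function(v) {
  s <- 0; comp <- 0
  for (x in sort(1 / v)) {
    t <- s + x
    comp <- comp + if (abs(s) >= abs(x)) (s - t) + x else (x - t) + s
    s <- t
  }
  length(v) / (s + comp)
}

# Cliff's d by explicit double loop
oracle_cliffs_d <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# all substrings of each length intersecting the altered set
oracle_windows <- function(seq, altered, lengths) {
  n <- nchar(seq)
  out <- list()
  for (L in sort(unique(lengths))) {
    for (s in seq_len(n - L + 1)) {
      span <- s:(s + L - 1)
      if (any(altered %in% span)) {
        out[[length(out) + 1]] <- data.frame(
          peptide = substr(seq, s, s + L - 1), start = s, length = L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# hand-applied BH step-up with monotone enforcement
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# two-sided Fisher exact p by hypergeometric tail enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random amino-acid string
random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}
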