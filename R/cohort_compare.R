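#' One-tailed Mann-Whitney U test
#'
#' U is computed on midranks. For small samples (`n + m <= 12`) the p-value
#' is obtained by exact enumeration of all rank splits (valid under ties,
#' where the classical exact distribution is not); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x focal sample (numeric, nonempty).
#' @param y reference sample (numeric, nonempty).
#' @param alternative "greater" tests whether `x` tends to exceed `y`;
#'   "less" the reverse.
#' @param exact force (`TRUE`)/forbid (`FALSE`) the enumeration path;
#'   default `NULL` enumerates when `n + m <= 12`.
#' @return list with `U` (the statistic for `x`), `p`, `method`.
#' @export
mann_whitney_one_tailed <- function(x, y, alternative = c("greater", "less"),
                                    exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (is.null(exact)) exact <- N <= 12L
  if (exact) {
    splits <- combn(N, n)
    u_null <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    p <- if (alternative == "greater") mean(u_null >= U) else mean(u_null <= U)
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- if (alternative == "greater") (U - mu - 0.5) / sqrt(sigma2)
           else (U - mu + 0.5) / sqrt(sigma2)
      p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
    }
    method <- "normal approximation"
  }
  list(U = U, p = max(p, .Machine$double.xmin), method = method)
}

#' Cliff's d effect size
#'
#' `d = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m)`, the difference between
#' the probabilities that a focal value exceeds versus falls below a
#' reference value. Computed in O((n+m) log(n+m)) via sorted search, exactly
#' matching pairwise counting.
#'
#' @param x focal sample.
#' @param y reference sample.
#' @return d in `[-1, 1]`; positive when `x` tends to be larger.
#' @export
cliffs_d <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  ys <- sort(y)
  m <- length(y)
  n_le <- findInterval(x, ys)                  # y <= x_i
  n_lt <- findInterval(x, ys, left.open = TRUE) # y < x_i
  sum(n_lt + n_le - m) / (length(x) * m)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), input order preserved.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || !length(p)) stop("p must be a nonempty numeric vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Reports both the sample odds ratio `ad / bc` and the conditional MLE odds
#' ratio, with the exact hypergeometric p-value. A zero margin makes the
#' test degenerate (flagged, p = 1); a single zero cell makes the sample OR
#' 0 or infinite (flagged).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative "two.sided" (default), "greater", or "less".
#' @return list with `or` (sample OR), `or_conditional`, `p`, `degenerate`,
#'   `or_degenerate`.
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin; test degenerate")
    return(list(or = NA_real_, or_conditional = NA_real_, p = 1,
                degenerate = TRUE, or_degenerate = TRUE))
  }
  or_sample <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  ft <- fisher.test(table, alternative = alternative)
  list(or = or_sample,
       or_conditional = unname(ft$estimate),
       p = ft$p.value,
       degenerate = FALSE,
       or_degenerate = !is.finite(or_sample) || or_sample == 0)
}

#' Categorize ages into younger / older groups
#'
#' Younger = at or below the 30th percentile of age at diagnosis, older = at
#' or above the 70th; the middle is excluded (`NA`). Percentiles are
#' computed pan-cohort by default, or within strata (e.g. tumor type) via
#' `by`.
#'
#' @param age numeric ages.
#' @param by optional stratification vector (same length as `age`).
#' @param probs lower/upper percentile cutoffs (default 0.3 / 0.7).
#' @return character vector "younger"/"older"/NA.
#' @export
age_categories <- function(age, by = NULL, probs = c(0.3, 0.7)) {
  cut_one <- function(a) {
    q <- quantile(a, probs, na.rm = TRUE)
    ifelse(a <= q[1], "younger", ifelse(a >= q[2], "older", NA_character_))
  }
  if (is.null(by)) return(cut_one(age))
  out <- rep(NA_character_, length(age))
  for (lev in unique(by)) {
    i <- which(by == lev)
    out[i] <- cut_one(age[i])
  }
  out
}

#' Patient group labels for a comparison family
#'
#' @param patients patient data.frame (patient_id, sex with 0 = male /
#'   1 = female, age_years, tumor_type).
#' @param grouping "sex", "age", or "sex_age".
#' @param age_by_tumor_type compute age percentiles within tumor type.
#' @return named character vector patient_id -> group label (NA = excluded),
#'   with a `"focal_order"` attribute listing levels from most to least
#'   focal (female before male, younger before older).
#' @export
patient_groups <- function(patients, grouping = c("sex", "age", "sex_age"),
                           age_by_tumor_type = FALSE) {
  grouping <- match.arg(grouping)
  sex <- ifelse(patients$sex == 1, "F", "M")
  if (grouping != "sex") {
    agecat <- age_categories(patients$age_years,
                             by = if (age_by_tumor_type) patients$tumor_type)
    agecat <- c(younger = "Y", older = "O")[agecat]
  }
  lab <- switch(grouping,
    sex = c(F = "female", M = "male")[sex],
    age = c(Y = "younger", O = "older")[agecat],
    sex_age = ifelse(is.na(agecat), NA, paste0(agecat, sex)))
  order <- switch(grouping,
    sex = c("female", "male"),
    age = c("younger", "older"),
    sex_age = c("YF", "YM", "OF", "OM"))
  structure(setNames(unname(lab), patients$patient_id), focal_order = order)
}

#' Pairwise group comparisons of observed-mutation PHBR scores
#'
#' Pools the (patient, mutation) score pairs of observed (and, by default,
#' expressed) driver mutations within each patient group and runs all
#' pairwise one-tailed Mann-Whitney tests with Cliff's d, adjusting the
#' family with Benjamini-Hochberg. The focal group of each pair is the one
#' listed first in the grouping's focal order (female before male, younger
#' before older) and the alternative is "focal greater" (worse
#' presentation); with that orientation Cliff's d is positive when the focal
#' group's scores tend to be higher.
#'
#' @param long long PHBR table ([phbr_long()]).
#' @param groups named group vector from [patient_groups()].
#' @param require_expressed restrict to expressed mutations (default TRUE).
#' @return data.frame, one row per group pair: group_a (focal), group_b,
#'   n_a, n_b, median_a, median_b, U, p_one_tailed, cliffs_d, p_bh,
#'   missing flag.
#' @export
compare_observed_scores <- function(long, groups, require_expressed = TRUE) {
  keep <- long$occurred %in% 1
  if (require_expressed) keep <- keep & long$expressed %in% 1
  obs <- long[keep, , drop = FALSE]
  obs$group <- unname(groups[obs$patient_id])
  obs <- obs[!is.na(obs$group), , drop = FALSE]
  levels <- attr(groups, "focal_order")
  levels <- levels[levels %in% unique(obs$group)]
  if (length(levels) < 2L) stop("fewer than two nonempty groups")
  pools <- split(obs$phbr, factor(obs$group, levels = levels))
  pairs <- combn(levels, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- pools[[a]]; xb <- pools[[b]]
    if (!length(xa) || !length(xb)) {
      rows[[k]] <- data.frame(group_a = a, group_b = b, n_a = length(xa),
                              n_b = length(xb), median_a = NA_real_,
                              median_b = NA_real_, U = NA_real_,
                              p_one_tailed = NA_real_, cliffs_d = NA_real_,
                              missing = TRUE)
      next
    }
    mw <- mann_whitney_one_tailed(xa, xb, "greater")
    rows[[k]] <- data.frame(group_a = a, group_b = b, n_a = length(xa),
                            n_b = length(xb), median_a = median(xa),
                            median_b = median(xb), U = mw$U,
                            p_one_tailed = mw$p, cliffs_d = cliffs_d(xa, xb),
                            missing = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !out$missing
  if (any(ok)) out$p_bh[ok] <- bh_adjust(out$p_one_tailed[ok])
  out
}

#' Mutation-reassignment permutation null for a group difference
#'
#' Breaks the genotype-mutation linkage: each permutation redraws, for every
#' mutation, the set of carrier patients uniformly (preserving each
#' mutation's occurrence count and the cohort's genotype multiset), reads
#' the reassigned carriers' PHBR scores, and recomputes the group-difference
#' statistic (focal minus reference, difference of group medians by
#' default). The 99% CI is the empirical 0.5%/99.5% quantile pair of the
#' null sample.
#'
#' @param scores patients x mutations PHBR matrix.
#' @param occurrence aligned binary occurrence matrix (already filtered to
#'   the cells of interest, e.g. expressed).
#' @param groups named two-level group vector (focal level first in its
#'   `focal_order` attribute or factor levels).
#' @param statistic "median" (default) or "mean".
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: observed, null (numeric vector), ci_low, ci_high,
#'   outside_ci, n_perm, seed, statistic.
#' @export
permutation_null <- function(scores, occurrence, groups,
                             statistic = c("median", "mean"),
                             n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "median") median else mean
  if (n_perm < 100) stop("n_perm must be at least 100")
  patients <- rownames(scores)
  stopifnot(identical(dim(scores), dim(occurrence)))
  g <- groups[patients]
  order <- attr(groups, "focal_order")
  if (is.null(order)) order <- sort(unique(na.omit(unname(g))))
  order <- order[order %in% g]
  if (length(order) != 2L) stop("grouping must have exactly two nonempty levels")
  group_idx <- match(unname(g), order) # NA = excluded patients
  n_pat <- length(patients)

  pooled_stat <- function(pat_idx, mut_idx) {
    gi <- group_idx[pat_idx]
    sc <- scores[cbind(pat_idx, mut_idx)]
    a <- sc[gi %in% 1L]
    b <- sc[gi %in% 2L]
    if (!length(a) || !length(b)) return(NA_real_)
    stat_fun(a) - stat_fun(b)
  }

  obs_cells <- which(occurrence == 1)
  obs_pat <- ((obs_cells - 1L) %% n_pat) + 1L
  obs_mut <- ((obs_cells - 1L) %/% n_pat) + 1L
  observed <- pooled_stat(obs_pat, obs_mut)
  counts <- tabulate(obs_mut, nbins = ncol(occurrence))
  mut_rep <- rep(seq_len(ncol(occurrence)), counts)
  set.seed(as.integer(seed))
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    # per mutation, redraw its carriers uniformly without replacement
    new_pat <- unlist(lapply(counts, function(cj) sample.int(n_pat, cj)),
                      use.names = FALSE)
    null[b] <- pooled_stat(new_pat, mut_rep)
  }
  ci <- quantile(null, c(0.005, 0.995), na.rm = TRUE, names = FALSE)
  list(observed = observed, null = null, null_mean = mean(null, na.rm = TRUE),
       ci_low = ci[1], ci_high = ci[2],
       outside_ci = is.finite(observed) && (observed < ci[1] | observed > ci[2]),
       n_perm = n_perm, seed = seed, statistic = statistic,
       groups = order)
}
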