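#' Build the long-format model design from PHBR and occurrence matrices
#'
#' One row per (patient, mutation) cell. Filters mirror the occurrence
#' modeling setup: mutations are retained if their expressed occurrence
#' count in the cohort is at least `min_occurrence` (default 2); patients
#' are retained if they have scores in both classes and at least one
#' observed, expressed driver mutation. Covariates are the centered natural
#' log of the PHBR scores, centered sex (0/1 male/female before centering)
#' and centered age in years; centering constants are computed on the
#' retained cells and recorded in the `"centering"` attribute.
#'
#' @param scores1,scores2 patients x mutations PHBR-I and PHBR-II matrices.
#' @param occurrence aligned binary occurrence matrix.
#' @param expressed aligned binary expressed matrix.
#' @param patients patient data.frame (patient_id, sex, age_years).
#' @param min_occurrence minimum expressed occurrence count per mutation.
#' @return data.frame (patient_id, mutation_id, y, x1c, x2c, sexc, agec)
#'   with attributes `centering` (named means) and `identifiable` (named
#'   logicals for sex and age variance).
#' @export
build_design <- function(scores1, scores2, occurrence, expressed, patients,
                         min_occurrence = 2) {
  common_pat <- intersect(rownames(scores1), rownames(scores2))
  common_mut <- intersect(colnames(scores1), colnames(scores2))
  if (!length(common_pat) || !length(common_mut)) {
    stop("no patients or mutations shared between the two score matrices")
  }
  sub <- function(m) m[common_pat, common_mut, drop = FALSE]
  s1 <- sub(scores1); s2 <- sub(scores2)
  occ <- sub(occurrence); expr <- sub(expressed)
  if (any(!is.finite(s1)) || any(!is.finite(s2))) {
    stop("non-finite PHBR scores in the aligned matrices")
  }
  obs_expr <- (occ == 1) & (expr == 1)
  keep_mut <- colSums(obs_expr) >= min_occurrence
  keep_pat <- rowSums(obs_expr) >= 1
  if (!any(keep_mut) || !any(keep_pat)) {
    stop("no rows left after occurrence/expression filtering")
  }
  s1 <- s1[keep_pat, keep_mut, drop = FALSE]
  s2 <- s2[keep_pat, keep_mut, drop = FALSE]
  occ <- occ[keep_pat, keep_mut, drop = FALSE]
  pat <- patients[match(rownames(s1), patients$patient_id), , drop = FALSE]
  if (anyNA(pat$patient_id)) stop("patient table missing retained patients")

  x1 <- log(s1); x2 <- log(s2)
  centering <- c(x1 = mean(x1), x2 = mean(x2),
                 sex = mean(pat$sex), age = mean(pat$age_years))
  df <- data.frame(
    patient_id = rep(rownames(s1), times = ncol(s1)),
    mutation_id = rep(colnames(s1), each = nrow(s1)),
    y = as.integer(as.vector(occ)),
    x1c = as.vector(x1) - centering["x1"],
    x2c = as.vector(x2) - centering["x2"],
    sexc = rep(pat$sex - centering["sex"], times = ncol(s1)),
    agec = rep(pat$age_years - centering["age"], times = ncol(s1)),
    stringsAsFactors = FALSE)
  attr(df, "centering") <- centering
  attr(df, "identifiable") <- c(sex = var(pat$sex) > 0,
                                age = var(pat$age_years) > 0)
  attr(df, "n_patients") <- nrow(s1)
  attr(df, "n_mutations") <- ncol(s1)
  df
}

.equation_terms <- list(
  `1` = c("x1c", "x2c", "sexc", "x1c:sexc", "x2c:sexc"),
  `2` = c("x1c", "x2c", "agec", "x1c:agec", "x2c:agec"),
  `3` = c("x1c", "agec", "sexc", "x1c:sexc", "x1c:agec"),
  `4` = c("x2c", "agec", "sexc", "x2c:sexc", "x2c:agec"))

#' Fit one mixed-effects logistic occurrence model
#'
#' Logistic regression of mutation occurrence on centered log-PHBR scores,
#' the sex or age covariate, and their interactions, with a per-patient
#' Normal(0, theta_eta) random intercept (fit by Laplace approximation via
#' `lme4::glmer`). An intercept is always included for identifiability and
#' reported alongside the printed terms. Wald z and two-sided p-values come
#' from the estimated coefficient covariance.
#'
#' The four equations: (1) both scores with sex and score:sex interactions;
#' (2) both scores with age and score:age interactions; (3) PHBR-I with both
#' sex and age and both interactions; (4) the same for PHBR-II.
#'
#' @param design design data.frame from [build_design()].
#' @param equation 1, 2, 3, or 4.
#' @return object of class `selection_fit`: list with `equation`,
#'   `coefficients` (term, estimate, se, z, p), `theta_eta`, `vcov`,
#'   `logLik`, `n_patients`, `n_mutations`, `n_cells`, `converged`,
#'   `messages`, `centering`, and the underlying `model`.
#' @export
fit_mixed_logit <- function(design, equation = 1) {
  equation <- as.character(equation)
  terms <- .equation_terms[[equation]]
  if (is.null(terms)) stop("equation must be 1, 2, 3 or 4")
  ident <- attr(design, "identifiable")
  uses_sex <- any(grepl("sexc", terms))
  uses_age <- any(grepl("agec", terms))
  if ((uses_sex && isFALSE(ident[["sex"]])) ||
      (uses_age && isFALSE(ident[["age"]]))) {
    bad <- c(if (uses_sex && isFALSE(ident[["sex"]])) "sex",
             if (uses_age && isFALSE(ident[["age"]])) "age")
    stop("equation ", equation, " not identifiable: zero variance in ",
         paste(bad, collapse = " and "))
  }
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + "),
                          "+ (1 | patient_id)"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = design, family = binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  est <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  theta <- vc$sdcor[vc$grp == "patient_id"][1]
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("failed to converge", msgs))
  structure(list(
    equation = as.integer(equation),
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), z = unname(z), p = pmax(unname(p), .Machine$double.xmin),
                              stringsAsFactors = FALSE),
    theta_eta = theta,
    vcov = V,
    logLik = as.numeric(stats::logLik(fit)),
    n_patients = attr(design, "n_patients"),
    n_mutations = attr(design, "n_mutations"),
    n_cells = nrow(design),
    converged = converged,
    messages = msgs,
    centering = attr(design, "centering"),
    model = fit), class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("Mixed-effects logistic selection model (equation ", x$equation, ")\n",
      sep = "")
  cat(sprintf("  %d patients x %d mutations (%d cells); theta_eta = %.4f; %s\n",
              x$n_patients, x$n_mutations, x$n_cells, x$theta_eta,
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Quartile odds ratio for a PHBR score
#'
#' The model-implied odds ratio of mutation occurrence comparing the 75th to
#' the 25th percentile of a score's centered-log column:
#' `exp(beta * (q75 - q25))`, with the CI obtained by transforming the Wald
#' interval of beta.
#'
#' @param fit a `selection_fit`.
#' @param score "I" or "II" (terms `x1c` / `x2c`).
#' @param design the design the model was fit on.
#' @param level confidence level (default 0.95).
#' @return list: or, ci_low, ci_high, q25, q75, term, degenerate.
#' @export
quartile_odds_ratio <- function(fit, score, design, level = 0.95) {
  if (!fit$converged) stop("model did not converge; odds ratio not reported")
  term <- switch(match_mhc_class(score), I = "x1c", II = "x2c")
  co <- fit$coefficients
  if (!term %in% co$term) stop("term ", term, " not in equation ", fit$equation)
  beta <- co$estimate[co$term == term]
  se <- co$se[co$term == term]
  q <- quantile(design[[term]], c(0.25, 0.75), names = FALSE)
  delta <- q[2] - q[1]
  if (delta == 0) {
    warning("degenerate quartiles (q75 == q25); OR = 1")
    return(list(or = 1, ci_low = 1, ci_high = 1, q25 = q[1], q75 = q[2],
                term = term, degenerate = TRUE))
  }
  zc <- qnorm(1 - (1 - level) / 2)
  list(or = exp(beta * delta),
       ci_low = exp((beta - zc * se) * delta),
       ci_high = exp((beta + zc * se) * delta),
       q25 = q[1], q75 = q[2], term = term, degenerate = FALSE)
}

#' Fit all four occurrence models
#'
#' Per-model failures (e.g. non-identifiable covariates) are isolated: the
#' failing equation appears in the output with `converged = FALSE` and its
#' error message, and the remaining models still fit.
#'
#' @param design design data.frame from [build_design()].
#' @param equations which equations to fit (default all four).
#' @return list with `fits` (per-equation `selection_fit` or NULL) and
#'   `table` (tidy coefficient data.frame: model, term, estimate, se, z, p,
#'   theta_eta, n_patients, n_mutations, converged, error).
#' @export
fit_all_models <- function(design, equations = 1:4) {
  fits <- list()
  rows <- list()
  for (eq in equations) {
    res <- tryCatch(fit_mixed_logit(design, eq), error = function(e) e)
    if (inherits(res, "error")) {
      fits[[as.character(eq)]] <- NULL
      rows[[as.character(eq)]] <- data.frame(
        model = eq, term = NA_character_, estimate = NA_real_, se = NA_real_,
        z = NA_real_, p = NA_real_, theta_eta = NA_real_,
        n_patients = NA_integer_, n_mutations = NA_integer_,
        converged = FALSE, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      fits[[as.character(eq)]] <- res
      co <- res$coefficients
      rows[[as.character(eq)]] <- data.frame(
        model = eq, term = co$term, estimate = co$estimate, se = co$se,
        z = co$z, p = co$p, theta_eta = res$theta_eta,
        n_patients = res$n_patients, n_mutations = res$n_mutations,
        converged = res$converged, error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
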