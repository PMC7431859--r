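test_that("design construction applies the occurrence >= 2 and patient filters", {
  s <- matrix(c(1, 2, 4, 8, 16, 32), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("m1", "m2")))
  occ <- matrix(c(1, 1, 0, 1, 0, 0), nrow = 3, dimnames = dimnames(s))
  expr <- matrix(1, 3, 2, dimnames = dimnames(s))
  pat <- data.frame(patient_id = c("p1", "p2", "p3"), sex = c(0, 1, 0),
                    age_years = c(40, 60, 70), stringsAsFactors = FALSE)
  # m2 expressed-observed once -> dropped; p3 has no observed expressed driver
  d <- build_design(s, s, occ, expr, pat)
  expect_setequal(unique(d$mutation_id), "m1")
  expect_setequal(unique(d$patient_id), c("p1", "p2"))
  # hand-checked covariates: x1c centered log over retained cells
  logs <- log(s[1:2, 1, drop = FALSE])
  expect_equal(d$x1c, as.vector(logs) - mean(logs))
  expect_equal(d$sexc, c(-0.5, 0.5))
  expect_equal(d$y, c(1, 1))
  cent <- attr(d, "centering")
  expect_equal(unname(cent["sex"]), 0.5)
  # all-female cohort flags sex as non-identifiable
  patF <- transform(pat, sex = 1)
  occ2 <- matrix(1, 3, 2, dimnames = dimnames(s))
  dF <- build_design(s, s, occ2, expr, patF)
  expect_false(attr(dF, "identifiable")[["sex"]])
  expect_error(build_design(s, s, occ * 0, expr, pat), "no rows left")
})

test_that("with theta ~ 0 the mixed fit matches a plain logistic oracle", {
  fx <- scored_fixture(n_patients = 80, n_mutations = 40, seed = 51)
  truth <- selection_truth(beta2 = 0.4, intercept = -1.5, theta_eta = 0)
  dd <- design_fixture(fx, truth, seed = 52)
  fit <- fit_mixed_logit(dd$design, 1)
  expect_s3_class(fit, "selection_fit")
  expect_lt(fit$theta_eta, 0.15)
  oracle <- glm(y ~ x1c + x2c + sexc + x1c:sexc + x2c:sexc,
                data = dd$design, family = binomial())
  oc <- coef(summary(oracle))
  for (term in fit$coefficients$term) {
    est <- fit$coefficients$estimate[fit$coefficients$term == term]
    expect_lt(abs(est - oc[term, "Estimate"]), 2 * oc[term, "Std. Error"])
  }
})

test_that("the Laplace fit agrees with an independent random-effect GAM fit", {
  skip_if_not_installed("mgcv")
  fx <- scored_fixture(n_patients = 60, n_mutations = 30, seed = 61)
  truth <- selection_truth(beta2 = 0.5, intercept = -1.2, theta_eta = 0.5)
  dd <- design_fixture(fx, truth, seed = 62)
  fit <- fit_mixed_logit(dd$design, 2)
  dat <- dd$design
  dat$patient_id <- factor(dat$patient_id)
  gam_fit <- mgcv::gam(y ~ x1c + x2c + agec + x1c:agec + x2c:agec +
                         s(patient_id, bs = "re"),
                       data = dat, family = binomial(), method = "REML")
  gc <- coef(gam_fit)[c("x1c", "x2c")]
  fc <- setNames(fit$coefficients$estimate, fit$coefficients$term)[c("x1c", "x2c")]
  se <- setNames(fit$coefficients$se, fit$coefficients$term)[c("x1c", "x2c")]
  expect_true(all(abs(fc - gc) < pmax(2 * se, 0.05)))
})

test_that("estimates are equivariant to recoding sex 0/1 -> 1/0", {
  fx <- scored_fixture(n_patients = 60, n_mutations = 30, seed = 71)
  truth <- selection_truth(beta2 = 0.4, beta5 = 0.4, intercept = -1.5,
                           theta_eta = 0.3)
  sim <- simulate_mutations(fx$s1, fx$s2, fx$cohort$patients$sex, truth, seed = 72)
  expr <- simulate_expression(sim$y, seed = 73)
  pat_flip <- transform(fx$cohort$patients, sex = 1 - sex)
  d1 <- build_design(fx$s1, fx$s2, sim$y, expr$expressed, fx$cohort$patients)
  d2 <- build_design(fx$s1, fx$s2, sim$y, expr$expressed, pat_flip)
  f1 <- fit_mixed_logit(d1, 1)
  f2 <- fit_mixed_logit(d2, 1)
  c1 <- setNames(f1$coefficients$estimate, f1$coefficients$term)
  c2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  tol <- 1e-3
  expect_equal(c1[["sexc"]], -c2[["sexc"]], tolerance = tol)
  expect_equal(c1[["x2c:sexc"]], -c2[["x2c:sexc"]], tolerance = tol)
  expect_equal(c1[["x1c"]], c2[["x1c"]], tolerance = tol)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-4)
})

test_that("quartile odds ratio has the closed form and matches predicted odds", {
  # closed form: beta = ln 2 with unit interquartile gap -> OR = 2
  fake <- structure(list(
    equation = 1L, converged = TRUE,
    coefficients = data.frame(term = "x2c", estimate = log(2), se = 0.1,
                              z = 1, p = 0.5)), class = "selection_fit")
  design <- data.frame(x2c = c(rep(-0.5, 2), rep(0.5, 2)))
  res <- quartile_odds_ratio(fake, "II", design)
  expect_equal(res$or, 2, tolerance = 1e-12)
  expect_false(res$degenerate)
  # beta = 0 -> OR = 1, CI contains 1
  fake0 <- fake; fake0$coefficients$estimate <- 0
  res0 <- quartile_odds_ratio(fake0, "II", design)
  expect_equal(res0$or, 1)
  expect_true(res0$ci_low <= 1 && res0$ci_high >= 1)
  # degenerate quartiles
  dgn <- data.frame(x2c = rep(0.3, 8))
  expect_warning(rd <- quartile_odds_ratio(fake, "II", dgn), "degenerate")
  expect_equal(rd$or, 1)
  # real fit: OR equals the ratio of model-predicted odds at q75 vs q25
  fx <- scored_fixture(n_patients = 50, n_mutations = 25, seed = 81)
  truth <- selection_truth(beta2 = 0.5, intercept = -1.5, theta_eta = 0.2)
  dd <- design_fixture(fx, truth, seed = 82)
  fit <- fit_mixed_logit(dd$design, 1)
  res2 <- quartile_odds_ratio(fit, "II", dd$design)
  q <- quantile(dd$design$x2c, c(0.25, 0.75), names = FALSE)
  nd <- data.frame(x1c = 0, x2c = q, sexc = 0, patient_id = dd$design$patient_id[1])
  eta <- predict(fit$model, newdata = nd, re.form = NA, type = "link")
  expect_equal(res2$or, exp(eta[2] - eta[1]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("fit_all_models isolates failures and flags non-identifiable equations", {
  fx <- scored_fixture(n_patients = 50, n_mutations = 25, seed = 91)
  pat <- transform(fx$cohort$patients, sex = 1) # single-sex cohort
  truth <- selection_truth(beta2 = 0.3, intercept = -1.5, theta_eta = 0.2)
  sim <- simulate_mutations(fx$s1, fx$s2, pat$age_years, truth, seed = 92)
  expr <- simulate_expression(sim$y, seed = 93)
  design <- build_design(fx$s1, fx$s2, sim$y, expr$expressed, pat)
  res <- fit_all_models(design)
  tab <- res$table
  expect_false(any(tab$converged[tab$model %in% c(1, 3, 4)]))
  expect_true(all(grepl("not identifiable",
                        tab$error[tab$model %in% c(1, 3, 4)])))
  expect_true(any(tab$converged[tab$model == 2]))
  expect_true(all(c("estimate", "se", "z", "p", "theta_eta") %in% names(tab)))
})
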