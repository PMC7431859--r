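# Stage 4: mixed-effects logistic models of mutation occurrence.
#
# Fits the four occurrence models (sex model, age model, and the PHBR-I- /
# PHBR-II-specific sex+age models) on the filtered design: expressed
# mutations observed >= 2 times, patients with both class scores and >= 1
# observed expressed driver; covariates are centered log PHBR scores,
# centered sex and centered age; per-patient random intercepts. Reports
# Wald tests and the 25th-vs-75th-percentile odds ratios.

source("analysis/00_common.R")
seed <- cli_seed()

patients <- read_tsv("patients.tsv")
long1 <- read_tsv("phbr_I_long.tsv")
long2 <- read_tsv("phbr_II_long.tsv")
s1 <- long_to_matrix(long1, "phbr")
s2 <- long_to_matrix(long2, "phbr")
occ <- long_to_matrix(long1, "occurred")
expr <- long_to_matrix(long1, "expressed")

design <- build_design(s1, s2, occ, expr, patients)
message("design: ", attr(design, "n_patients"), " patients x ",
        attr(design, "n_mutations"), " mutations (", nrow(design), " cells)")

models <- fit_all_models(design)
write_tsv(models$table, "model_coefficients.tsv")
sex_fit <- models$fits[["1"]]
if (!is.null(sex_fit) && sex_fit$converged) {
  co <- setNames(sex_fit$coefficients$estimate, sex_fit$coefficients$term)
  message(sprintf("sex model: PHBR-I %.3f, PHBR-II %.3f, PHBR-I:sex %.3f, PHBR-II:sex %.3f, theta_eta %.3f",
                  co[["x1c"]], co[["x2c"]], co[["x1c:sexc"]], co[["x2c:sexc"]],
                  sex_fit$theta_eta))
  ors <- lapply(c(I = "I", II = "II"),
                function(cl) quartile_odds_ratio(sex_fit, cl, design))
  message(sprintf("quartile odds ratios: PHBR-I %.2f [%.2f, %.2f], PHBR-II %.2f [%.2f, %.2f]",
                  ors$I$or, ors$I$ci_low, ors$I$ci_high,
                  ors$II$or, ors$II$ci_low, ors$II$ci_high))
  write_tsv(data.frame(score = c("PHBR-I", "PHBR-II"),
                       or = c(ors$I$or, ors$II$or),
                       ci_low = c(ors$I$ci_low, ors$II$ci_low),
                       ci_high = c(ors$I$ci_high, ors$II$ci_high)),
            "quartile_odds_ratios.tsv")
}
truth <- read_tsv("selection_truth.tsv")
message("generative truth for comparison: ",
        paste(truth$parameter, signif(truth$value, 3), sep = "=", collapse = ", "))
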