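#!/usr/bin/env Rscript
# Stage 4 — the four analysis sets on the simulated campaign.
#
# (1) dropout labeling and the count regression on wave x arm;
# (2) hierarchical models of visit days and registered activities with AIC
#     selection over main effects and second-order interactions;
# (3) per-activity-type hierarchical models (longer walks, longer rides,
#     sports sessions);
# (4) posttest linear models reduced by backward elimination.
# Writes a JSON report per analysis set under results/analysis/.

library(goalwave)

cohort <- read_cohort("results/cohort")
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

report <- function(fit, path) {
  jsonlite::write_json(
    list(formula = deparse(fit$formula), aic = fit$aic,
         coefficients = fit$coefficients,
         varcomp = as.list(fit$varcomp)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
}

## 1 — dropouts -----------------------------------------------------------
drops <- label_dropouts(cohort$visits, cohort$participants, W = 4)
counts <- participation_counts(cohort$visits, cohort$participants, W = 4)
cat("participation per wave:\n"); print(counts, row.names = FALSE)
fit_dr <- fit_dropout_regression(drops, cohort$participants, W = 4)
report(fit_dr, "results/analysis/dropout_regression.json")
cat("\ndropout count regression:\n"); print(fit_dr$coefficients, digits = 3)

## 2 — engagement levels --------------------------------------------------
records <- merge_participant_covariates(cohort$engagement,
                                        cohort$participants)
sub <- build_analysis_subset(records, cohort$participants)
cat("\nanalysis subset:", length(unique(sub$participant_id)),
    "participants,", nrow(sub), "participant-waves\n")

for (outcome in c("visit_days", "activities_registered")) {
  fit <- fit_engagement_model(sub, outcome)
  report(fit, file.path("results/analysis", paste0(outcome, ".json")))
  cat("\n[", outcome, "]\n", sep = ""); print(fit)
}

## 3 — per-activity-type models -------------------------------------------
for (outcome in c("walks_longer", "rides_longer", "sports_sessions")) {
  fit <- fit_engagement_model(sub, outcome)
  report(fit, file.path("results/analysis", paste0(outcome, ".json")))
  cat("\n[", outcome, "]\n", sep = ""); print(fit)
}

## 4 — posttest perception models -----------------------------------------
fits <- fit_posttest_models(cohort$posttest)
for (nm in names(fits)) {
  report(fits[[nm]], file.path("results/analysis", paste0(nm, ".json")))
  cat("\n[", nm, "]\n", sep = ""); print(fits[[nm]])
}
cat("\nreports written under results/analysis/\n")
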