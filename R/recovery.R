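#' Parameter-recovery study over replicate synthetic cohorts
#'
#' Generates `n_reps` independent Gaussian-mode cohorts under the given
#' configuration, fits the main-effects hierarchical model to the requested
#' engagement outcome on each replicate's analysis subset, and summarizes
#' each fixed effect against its configured ground truth. The Monte-Carlo
#' standard error of the mean estimate is `sd(estimates) / sqrt(n_reps)`; a
#' generator and estimator that agree should show `|mean - truth|` within
#' about two such standard errors.
#'
#' @param outcome Engagement outcome to fit (see [fit_engagement_model()]).
#' @param n_reps Number of replicate cohorts.
#' @param config A [cohort_config()]; its `mode` is forced to `"gaussian"`
#'   (continuous outcomes, no truncation or dropout), the regime in which the
#'   linear mixed model is correctly specified and recovery is unbiased.
#' @param seed Seed; replicate `r` uses `seed + r`.
#' @return A data frame with one row per fixed effect: `term`, `truth`,
#'   `mean_estimate`, `mc_se`, `bias`, `abs_z` (|bias| / mc_se).
#' @export
recover_fixed_effects <- function(outcome = "visit_days", n_reps = 100L,
                                  config = cohort_config(mode = "gaussian"),
                                  seed = 1L) {
  config$mode <- "gaussian"
  eff <- config$effects[[switch(outcome,
    visit_days = "visits",
    activities_registered = "activities",
    outcome
  )]]
  truth <- c("(Intercept)" = eff$intercept,
             relative_wave = eff$time,
             goal_typemaintain = eff$maintain,
             goal_typeimprove = eff$improve,
             armpersonalized = eff$personalized)
  est <- matrix(NA_real_, nrow = n_reps, ncol = length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seed + r
    ch <- generate_cohort(cfg, events = FALSE, posttest = FALSE)
    sub <- build_analysis_subset(
      merge_participant_covariates(ch$engagement, ch$participants),
      ch$participants
    )
    fit <- fit_engagement_model(sub, outcome, select = FALSE)
    cc <- fit$coefficients
    est[r, ] <- cc$estimate[match(names(truth), cc$term)]
  }
  means <- colMeans(est)
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_reps)
  data.frame(term = names(truth), truth = unname(truth),
             mean_estimate = unname(means), mc_se = unname(mc_se),
             bias = unname(means - truth),
             abs_z = unname(abs(means - truth) / mc_se),
             row.names = NULL)
}
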