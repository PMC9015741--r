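make_visits <- function(waves_visited, join_wave = 1L, W = 4L,
                        pid = "P1") {
  waves <- seq.int(join_wave, W)
  data.frame(participant_id = pid, wave = waves,
             visit_days = as.integer(waves %in% waves_visited),
             visited = waves %in% waves_visited)
}

test_that("dropout labeling follows the missed-wave rule with reclaiming", {
  participants <- data.frame(participant_id = "P1", join_wave = 1L)

  d1 <- label_dropouts(make_visits(c(1, 2)), participants, W = 4)
  expect_equal(d1$dropout_wave, 2L)
  expect_false(d1$reclaimed)

  d2 <- label_dropouts(make_visits(1:4), participants, W = 4)
  expect_true(is.na(d2$dropout_wave))

  d3 <- label_dropouts(make_visits(c(1, 3)), participants, W = 4)
  expect_equal(d3$dropout_wave, 1L)
  expect_true(d3$reclaimed)

  # a late joiner is only at risk after their join wave
  participants4 <- data.frame(participant_id = "P1", join_wave = 3L)
  d4 <- label_dropouts(make_visits(3, join_wave = 3L), participants4, W = 4)
  expect_equal(d4$dropout_wave, 3L)
})

test_that("per-wave participation counts match a brute-force oracle", {
  for (seed in c(5, 6)) {
    set.seed(seed)
    n <- 30
    participants <- data.frame(
      participant_id = sprintf("Q%02d", 1:n),
      join_wave = sample(1:4, n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
    )
    visits <- do.call(rbind, lapply(1:n, function(i) {
      jw <- participants$join_wave[i]
      waves <- seq.int(jw, 4)
      v <- c(TRUE, stats::runif(length(waves) - 1) < 0.6)
      data.frame(participant_id = participants$participant_id[i],
                 wave = waves, visit_days = as.integer(v) * 2L, visited = v)
    }))
    got <- participation_counts(visits, participants, W = 4)
    expect_equal(got, oracle_participation(visits, participants, W = 4))
  }
})

test_that("the analysis subset drops exactly the ineligible participants and waves", {
  fx <- records_from_patterns(
    pattern = list(A = c(1, 2, 3), B = 1, C = c(2, 4), D = 4, E = 1:4),
    join_wave = list(A = 1, B = 1, C = 2, D = 4, E = 1),
    arm = list(A = "control", B = "personalized", C = "personalized",
               D = "none", E = "control")
  )
  sub <- build_analysis_subset(fx$records, fx$participants)
  # D joined in the final wave (never allocated); B is registration-only
  expect_setequal(unique(sub$participant_id), c("A", "C", "E"))
  # only visited waves are retained
  expect_equal(sort(sub$wave[sub$participant_id == "A"]), c(1, 2, 3))
  expect_equal(sort(sub$wave[sub$participant_id == "C"]), c(2, 4))
  # idempotence
  expect_identical(build_analysis_subset(sub, fx$participants), sub)
})

test_that("the hierarchical model recovers a configured time effect", {
  cfg <- cohort_config(
    mode = "gaussian", seed = 41,
    effects = modifyList(cohort_config()$effects, list(
      visits = list(intercept = 7, time = -1.0, maintain = 0, improve = 0,
                    personalized = 0)
    ))
  )
  ch <- generate_cohort(cfg, events = FALSE, posttest = FALSE)
  sub <- build_analysis_subset(
    merge_participant_covariates(ch$engagement, ch$participants),
    ch$participants
  )
  fit <- fit_engagement_model(sub, "visit_days", select = FALSE)
  cc <- fit$coefficients
  tw <- cc[cc$term == "relative_wave", ]
  expect_lt(abs(tw$estimate - (-1.0)), 2 * tw$se)
  # both random-intercept variances are reported
  expect_true(all(c("participant_id", "organization_id") %in%
                    names(fit$varcomp)))
})

test_that("selection drops an arm with no configured effect in most replicates", {
  kept_arm <- vapply(1:9, function(r) {
    cfg <- cohort_config(mode = "gaussian", seed = 700 + r)
    ch <- generate_cohort(cfg, events = FALSE, posttest = FALSE)
    sub <- build_analysis_subset(
      merge_participant_covariates(ch$engagement, ch$participants),
      ch$participants
    )
    fit <- fit_engagement_model(sub, "visit_days")
    "arm" %in% all.vars(fit$formula)
  }, logical(1))
  expect_lt(mean(kept_arm), 0.5)
})

test_that("model selection prefers the intercept-only model for constant outcomes", {
  sub <- expand.grid(participant_id = sprintf("P%02d", 1:20),
                     relative_wave = 0:3, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  sub$wave <- sub$relative_wave + 1
  sub$organization_id <- rep(c("O1", "O2"), length.out = nrow(sub))
  sub$goal_type <- rep(c("unknown", "maintain", "improve", "unknown"),
                       length.out = nrow(sub))
  sub$arm <- rep(c("control", "personalized"), length.out = nrow(sub))
  sub$visit_days <- 5
  fit <- suppressWarnings(fit_engagement_model(sub, "visit_days"))
  expect_equal(length(lme4::fixef(fit$fit)), 1L)
})

test_that("dropout regression recovers flat and rising hazards", {
  flat <- expand.grid(wave = 1:3, arm = c("control", "personalized"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flat$dropouts <- 10
  # constant counts make the fit exact; lm warns about the perfect fit
  f1 <- suppressWarnings(fit_dropout_regression(flat))
  cc <- f1$coefficients
  expect_equal(cc$estimate[cc$term == "wave"], 0, tolerance = 1e-10)
  expect_equal(cc$estimate[cc$term == "armpersonalized"], 0,
               tolerance = 1e-10)
  expect_equal(cc$estimate[cc$term == "wave:armpersonalized"], 0,
               tolerance = 1e-10)

  # binomial dropouts on a fixed risk set with a known rising hazard
  set.seed(77)
  rising <- expand.grid(wave = 1:3, arm = c("control", "personalized"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rising$dropouts <- stats::rbinom(nrow(rising), size = 200,
                                   prob = stats::plogis(-3 + 0.6 * rising$wave))
  f2 <- fit_dropout_regression(rising)
  cc2 <- f2$coefficients
  expect_gt(cc2$estimate[cc2$term == "wave"], 0)

  single <- flat[flat$arm == "control", ]
  w <- testthat::capture_warnings(fit_dropout_regression(single))
  expect_true(any(grepl("single arm", w)))
})

test_that("backward elimination removes noise predictors and respects marginality", {
  set.seed(9)
  n <- 60
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  red <- backward_eliminate(stats::lm(y ~ x, data = d))
  expect_equal(names(stats::coef(red)), "(Intercept)")

  # marginality: while an interaction is retained, so are its main effects
  d2 <- data.frame(a = rnorm(n), b = rnorm(n))
  d2$y <- 2 * d2$a * d2$b + rnorm(n, 0, 0.1)  # pure interaction signal
  red2 <- backward_eliminate(stats::lm(y ~ a * b, data = d2))
  terms2 <- attr(stats::terms(red2), "term.labels")
  expect_true("a:b" %in% terms2)
  expect_true(all(c("a", "b") %in% terms2))
})

test_that("posttest models retain exactly the generated effects", {
  ch <- generate_cohort(cohort_config(seed = 12), events = FALSE)
  fits <- fit_posttest_models(ch$posttest)
  term_labels <- function(f) attr(stats::terms(f$fit), "term.labels")

  # only the personalized-arm effect drives bike perception
  expect_equal(term_labels(fits$bike_perception), "arm")
  # sports perception is driven by the goal-by-arm interaction
  expect_true("goal_type:arm" %in% term_labels(fits$sports_perception))
  # no effect was configured for walk perception
  expect_equal(length(term_labels(fits$walk_perception)), 0L)
  # self-efficacy declines with the number of visited waves
  expect_equal(term_labels(fits$self_efficacy), "waves_visited")
  cc <- fits$self_efficacy$coefficients
  est <- cc$estimate[cc$term == "waves_visited"]
  expect_lt(abs(est - (-0.329)), 2 * cc$se[cc$term == "waves_visited"])

  expect_equal(fit_posttest_models(ch$posttest[0, ]), list())
})
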