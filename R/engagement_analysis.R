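#' Label provisional dropouts and reclaimed users from the visit log
#'
#' A participant is labeled a (provisional) dropout if they did not visit the
#' app during a specific wave: they are assumed to have lost interest during
#' the previous wave. A later visit marks them as reclaimed.
#'
#' @param visits Data frame with `participant_id`, `wave` and `visited` (or
#'   `visit_days`, from which `visited` is derived) covering each
#'   participant's waves from joining to campaign end.
#' @param participants Data frame with `participant_id` and `join_wave`.
#' @param W Total number of waves.
#' @return Data frame with one row per participant: `participant_id`,
#'   `dropout_wave` (`NA` if never dropped) and `reclaimed`.
#' @export
label_dropouts <- function(visits, participants, W = 4L) {
  if (!"visited" %in% names(visits)) {
    visits$visited <- visits$visit_days > 0
  }
  out <- data.frame(participant_id = participants$participant_id,
                    dropout_wave = NA_integer_, reclaimed = FALSE)
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    jw <- participants$join_wave[i]
    pv <- visits[visits$participant_id == pid, , drop = FALSE]
    visited_waves <- sort(pv$wave[pv$visited])
    waves <- seq.int(jw, W)
    missed <- waves[!waves %in% visited_waves]
    missed <- missed[missed > jw]  # the join wave itself counts as visited
    if (length(missed) > 0) {
      first_missed <- min(missed)
      out$dropout_wave[i] <- first_missed - 1L
      out$reclaimed[i] <- any(visited_waves > first_missed)
    }
  }
  out
}

#' Per-wave participation counts
#'
#' Summarizes the visit log into per-wave counts of visiting participants,
#' first-wave joiners, participants who dropped out during the wave (did not
#' visit the following one), and reclaimed users visiting again after a
#' missed wave.
#'
#' @inheritParams label_dropouts
#' @return Data frame with `wave`, `visiting`, `new`, `dropped`, `reclaimed`.
#' @export
participation_counts <- function(visits, participants, W = 4L) {
  if (!"visited" %in% names(visits)) {
    visits$visited <- visits$visit_days > 0
  }
  jw <- participants$join_wave[match(visits$participant_id,
                                     participants$participant_id)]
  out <- data.frame(wave = seq_len(W), visiting = 0L, new = 0L,
                    dropped = 0L, reclaimed = 0L)
  for (w in seq_len(W)) {
    in_wave <- visits$wave == w & (visits$visited | jw == w)
    ids <- unique(visits$participant_id[in_wave])
    out$visiting[w] <- length(ids)
    out$new[w] <- sum(participants$join_wave == w &
                        participants$participant_id %in% ids)
    if (w < W) {
      next_visit <- visits$participant_id[visits$wave == w + 1 &
                                            visits$visited]
      out$dropped[w] <- sum(!ids %in% next_visit)
    }
    if (w > 1) {
      # visited this wave after missing at least one earlier wave
      # (the join wave itself counts as visited)
      for (pid in ids) {
        j <- participants$join_wave[participants$participant_id == pid]
        if (j >= w) next
        seen <- unique(c(j, visits$wave[visits$participant_id == pid &
                                          visits$visited & visits$wave < w]))
        if (!all(seq.int(j, w - 1) %in% seen)) {
          out$reclaimed[w] <- out$reclaimed[w] + 1L
        }
      }
    }
  }
  out
}

#' Build the analysis subset of engagement records
#'
#' Restricts the engagement records to participant-waves that contribute to
#' the treatment evaluation: participants never allocated to an arm (final
#' wave joiners) are dropped entirely; participants who only visited the app
#' during their first wave (registration-only users) or visited in fewer than
#' two distinct waves are dropped; and within remaining participants, only
#' waves they actually visited are kept. Idempotent by construction.
#'
#' @param records Engagement records with `participant_id`, `wave`,
#'   `relative_wave`, outcome columns and `visited`.
#' @param participants Data frame with `participant_id`, `join_wave`, `arm`.
#' @return The filtered engagement records.
#' @export
build_analysis_subset <- function(records, participants) {
  arm <- participants$arm[match(records$participant_id,
                                participants$participant_id)]
  keep <- arm != "none"
  records <- records[keep, , drop = FALSE]
  visited_waves <- tapply(records$wave[records$visited],
                          records$participant_id[records$visited],
                          function(w) length(unique(w)))
  enough <- names(visited_waves)[visited_waves >= 2]
  records <- records[records$participant_id %in% enough & records$visited, ,
                     drop = FALSE]
  rownames(records) <- NULL
  records
}

fixed_effect_table <- function(fit) {
  if (inherits(fit, "merMod")) {
    cc <- as.data.frame(summary(fit)$coefficients)
    names(cc) <- c("estimate", "se", "t")[seq_len(ncol(cc))]
  } else {
    cc <- as.data.frame(summary(fit)$coefficients[, 1:3, drop = FALSE])
    names(cc) <- c("estimate", "se", "t")
  }
  cc$term <- rownames(cc)
  rownames(cc) <- NULL
  # normal approximation of the t-ratio (approximate for mixed models)
  cc$p <- 2 * stats::pnorm(-abs(cc$t))
  cc[, c("term", "estimate", "se", "t", "p")]
}

new_model_fit <- function(fit, formula, aic, candidates = NULL) {
  vc <- if (inherits(fit, "merMod")) {
    v <- as.data.frame(lme4::VarCorr(fit))
    stats::setNames(v$vcov, v$grp)
  } else NULL
  structure(list(fit = fit, formula = formula,
                 coefficients = fixed_effect_table(fit),
                 varcomp = vc, aic = aic, candidates = candidates),
            class = "engagement_fit")
}

#' @export
print.engagement_fit <- function(x, ...) {
  cat("Selected model: ", deparse(x$formula), "\n", sep = "")
  cat("AIC:", format(x$aic, digits = 6), "\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$varcomp)) {
    cat("Random-intercept variances:\n")
    print(x$varcomp, digits = 4)
  }
  invisible(x)
}

# candidate fixed-effect structures: every subset of the main effects
# (including the intercept-only model, so selection can drop a predictor
# with no support), plus the full main-effects model with each pairwise
# interaction added singly and jointly
engagement_candidates <- function(mains) {
  if (length(mains) == 0) return("1")
  cands <- "1"
  for (k in seq_along(mains)) {
    cands <- c(cands, utils::combn(mains, k, FUN = paste,
                                   collapse = " + "))
  }
  base <- paste(mains, collapse = " + ")
  ints <- if (length(mains) >= 2) {
    utils::combn(mains, 2, FUN = paste, collapse = ":")
  } else character(0)
  cands <- c(cands,
             vapply(ints, function(i) paste(base, "+", i), character(1)))
  if (length(ints) >= 2) {
    cands <- c(cands, paste(base, "+", paste(ints, collapse = " + ")))
  }
  unname(unique(cands))
}

#' Fit hierarchical engagement models with information-criterion selection
#'
#' Fits linear mixed models of an engagement outcome on time (the relative
#' wave number), goal type (reference level: unknown) and arm, with random
#' intercepts for individuals and their organizations. The candidate set
#' comprises every subset of the main effects (down to the intercept-only
#' model, so an unsupported predictor can be dropped) and the full
#' main-effects model with each second-order interaction added singly and
#' jointly. Candidates are compared by AIC of maximum-likelihood fits over an
#' identical random structure; among candidates within 2 AIC units of the
#' minimum the most parsimonious one is selected, and the selected
#' fixed-effect structure is refit by REML. With a single organization the
#' organization intercept is dropped with a warning. Reported p-values use
#' the normal approximation of the t-ratio.
#'
#' @param subset Analysis subset from [build_analysis_subset()], merged with
#'   participant covariates (`goal_type`, `arm`, `organization_id`).
#' @param outcome One of `"visit_days"`, `"activities_registered"`,
#'   `"walks_longer"`, `"rides_longer"`, `"sports_sessions"`.
#' @param select If `FALSE`, skip selection and fit the main-effects model
#'   directly (used in parameter-recovery studies).
#' @return An `engagement_fit`.
#' @export
fit_engagement_model <- function(subset, outcome = c(
                                   "visit_days", "activities_registered",
                                   "walks_longer", "rides_longer",
                                   "sports_sessions"),
                                 select = TRUE) {
  outcome <- match.arg(outcome)
  stopifnot(nrow(subset) > 0)
  dat <- subset
  dat$goal_type <- factor(dat$goal_type,
                          levels = c("unknown", "maintain", "improve"))
  dat$goal_type <- droplevels(dat$goal_type)
  has_arm <- length(unique(dat$arm)) > 1
  if (has_arm) dat$arm <- factor(dat$arm, levels = c("control",
                                                     "personalized"))

  re <- "(1 | participant_id) + (1 | organization_id)"
  if (length(unique(dat$organization_id)) < 2) {
    warning("single organization: organization intercept dropped")
    re <- "(1 | participant_id)"
  }

  mains <- c("relative_wave",
             if (length(unique(dat$goal_type)) > 1) "goal_type",
             if (has_arm) "arm")
  cands <- engagement_candidates(mains)
  if (!select) cands <- paste(mains, collapse = " + ")
  # a constant outcome is explained by any candidate: take the smallest
  if (stats::var(dat[[outcome]]) == 0) cands <- cands[1]

  fit_one <- function(fx, reml) {
    f <- stats::as.formula(paste(outcome, "~", fx, "+", re))
    tryCatch(
      suppressMessages(lme4::lmer(f, data = dat, REML = reml,
                                  control = lme4::lmerControl(
                                    check.conv.singular = "ignore",
                                    calc.derivs = FALSE))),
      error = function(e) NULL
    )
  }

  aics <- rep(NA_real_, length(cands))
  npar <- rep(NA_real_, length(cands))
  for (k in seq_along(cands)) {
    m <- fit_one(cands[k], reml = FALSE)
    if (!is.null(m)) {
      aics[k] <- stats::AIC(m)
      npar[k] <- length(lme4::fixef(m))
    }
  }
  if (all(is.na(aics))) stop("no candidate model could be fitted")
  # most parsimonious candidate among those within 2 AIC units of the
  # minimum (models inside that band are substantially equivalent), with
  # remaining ties resolved by the lower AIC
  best_aic <- min(aics, na.rm = TRUE)
  close <- which(!is.na(aics) & aics <= best_aic + 2)
  close <- close[order(npar[close], aics[close])]
  k <- close[1]

  final <- fit_one(cands[k], reml = TRUE)
  if (is.null(final)) stop("selected model failed to refit")
  new_model_fit(final,
                stats::as.formula(paste(outcome, "~", cands[k], "+", re)),
                aics[k],
                candidates = data.frame(formula = cands, aic = aics))
}

#' Dropout regression over waves and arms
#'
#' Multiple linear regression of the per-wave dropout count on wave number,
#' arm, and their interaction, testing whether dropouts change over time and
#' differ between treatments. With a single arm in the data a reduced model
#' on wave only is fit, with a warning.
#'
#' @param dropouts Dropout records from [label_dropouts()], merged with
#'   participant `arm`; or a precomputed count table with `wave`, `arm`,
#'   `dropouts`.
#' @param participants Participant table (needed when `dropouts` are
#'   per-participant records).
#' @param W Total number of waves.
#' @return An `engagement_fit` for the count regression.
#' @export
fit_dropout_regression <- function(dropouts, participants = NULL, W = 4L) {
  if (!"dropouts" %in% names(dropouts)) {
    stopifnot(!is.null(participants))
    arm <- participants$arm[match(dropouts$participant_id,
                                  participants$participant_id)]
    dropouts <- dropouts[arm != "none", , drop = FALSE]
    arm <- arm[arm != "none"]
    # a dropout during the final wave is unobservable (no following wave),
    # so the count table covers waves 1..W-1
    counts <- expand.grid(wave = seq_len(W - 1L),
                          arm = c("control", "personalized"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    counts$dropouts <- mapply(function(w, a) {
      sum(dropouts$dropout_wave == w & arm == a, na.rm = TRUE)
    }, counts$wave, counts$arm)
  } else {
    counts <- dropouts
  }
  if (length(unique(counts$arm)) > 1) {
    fit <- stats::lm(dropouts ~ wave * arm, data = counts)
    f <- dropouts ~ wave * arm
  } else {
    warning("single arm: fitting reduced dropout model on wave only")
    fit <- stats::lm(dropouts ~ wave, data = counts)
    f <- dropouts ~ wave
  }
  new_model_fit(fit, f, stats::AIC(fit))
}

#' Backward elimination for linear models
#'
#' Starting from the full model, repeatedly deletes the predictor with the
#' highest p-value above the threshold until all remaining predictors are
#' significant. Marginality is respected: an interaction is removed before
#' the main effects it involves (only droppable terms are considered at each
#' step, as given by [stats::drop1()] F-tests). Terminates in at most as many
#' steps as there are initial predictors.
#'
#' @param fit An `lm` fit of the full model.
#' @param alpha Significance threshold (default 0.05).
#' @return The reduced `lm` fit.
#' @export
backward_eliminate <- function(fit, alpha = 0.05) {
  mf <- stats::model.frame(fit)
  repeat {
    tab <- stats::drop1(fit, test = "F")
    tab <- tab[-1, , drop = FALSE]  # drop the <none> row
    if (nrow(tab) == 0) break
    p <- tab[["Pr(>F)"]]
    if (all(is.na(p)) || max(p, na.rm = TRUE) <= alpha) break
    worst <- rownames(tab)[which.max(p)]
    f <- stats::update(stats::formula(fit),
                       stats::as.formula(paste(". ~ . -", worst)))
    fit <- stats::lm(f, data = mf)
  }
  fit
}

#' Posttest linear models with backward elimination
#'
#' For each posttest outcome (perceived impact on walk, bike and sports
#' performance, and self-efficacy), fits a linear model on time (the total
#' number of waves the participant visited the app), goal type, arm, and all
#' second-order interactions, then reduces it by backward elimination at
#' p > .05. Only respondents who used the app in more than one wave enter the
#' analysis.
#'
#' @param posttest Posttest table with `waves_visited`, `goal_type`, `arm`
#'   and the four outcome columns.
#' @param alpha Elimination threshold.
#' @return A named list of `engagement_fit` objects (empty when no analyzable
#'   respondents).
#' @export
fit_posttest_models <- function(posttest, alpha = 0.05) {
  outcomes <- c("walk_perception", "bike_perception", "sports_perception",
                "self_efficacy")
  dat <- posttest[posttest$waves_visited > 1 & posttest$arm != "none", ,
                  drop = FALSE]
  if (nrow(dat) == 0) return(list())
  dat$goal_type <- factor(dat$goal_type,
                          levels = c("unknown", "maintain", "improve"))
  dat$goal_type <- droplevels(dat$goal_type)
  dat$arm <- factor(dat$arm, levels = c("control", "personalized"))
  rhs <- if (length(unique(dat$goal_type)) > 1) {
    "(waves_visited + goal_type + arm)^2"
  } else {
    "waves_visited * arm"
  }
  fits <- list()
  for (y in intersect(outcomes, names(dat))) {
    full <- stats::lm(stats::as.formula(paste(y, "~", rhs)), data = dat)
    red <- backward_eliminate(full, alpha)
    fits[[y]] <- new_model_fit(red, stats::formula(red), stats::AIC(red))
  }
  fits
}

#' Merge engagement records with participant covariates
#'
#' Convenience join of the engagement table with `goal_type`, `arm` and
#' `organization_id`, as required by [fit_engagement_model()].
#'
#' @param records Engagement records.
#' @param participants Participant table.
#' @return The merged data frame.
#' @export
merge_participant_covariates <- function(records, participants) {
  merge(records,
        participants[, c("participant_id", "goal_type", "arm",
                         "organization_id")],
        by = "participant_id")
}
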