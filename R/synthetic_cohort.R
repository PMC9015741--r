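#' Configuration of the synthetic cohort generator
#'
#' Collects every knob of the generative model for a synthetic campaign
#' cohort: cohort composition, wave structure, the fixed effects of the
#' engagement outcomes (per participant-wave), variance components of the
#' random intercepts, the dropout hazard, intake capability distributions,
#' and posttest perception effects. The defaults encode the study conditions
#' the generator emulates: 176 participants across 7 organizations, goal
#' types split 93 unknown / 26 maintain / 57 improve, 4 waves of 14 days,
#' app-visit days falling by 1.174 per relative wave with goal-setting
#' bonuses of +2.176 (maintain) and +1.625 (improve) days, registered
#' activities falling by 0.080 per wave with bonuses +1.535 and +3.258, a
#' +0.917 improvement-goal effect on longer walks, sports-session effects of
#' +0.405 / +0.318 (goals) and +0.276 (personalized arm), and posttest
#' perception effects (+0.047 personalized on bike perception, +0.500 /
#' -0.227 goal-by-arm interaction on sports perception, -0.329 per visited
#' wave on self-efficacy).
#'
#' @param n_participants Cohort size.
#' @param n_organizations Number of organizations.
#' @param goal_counts Named integer vector of goal-type counts
#'   (`unknown`, `maintain`, `improve`); must sum to `n_participants`.
#' @param join_wave_counts Number of participants joining in each wave; must
#'   sum to `n_participants`.
#' @param W,wave_days Wave structure.
#' @param mode `"realistic"` (rounded, truncated outcomes and a dropout
#'   process) or `"gaussian"` (continuous Gaussian outcomes, no dropout,
#'   no truncation; used for unbiased parameter-recovery studies).
#' @param effects Named list of per-outcome fixed effects; see Details.
#' @param sd_individual,sd_organization,sd_residual Standard deviations of
#'   the individual random intercept, organization random intercept and
#'   residual on the visit-days/activities scale.
#' @param activity_sds Same three components on the per-activity-type count
#'   scale.
#' @param dropout_hazard_intercept,dropout_hazard_slope Discrete-time
#'   logistic dropout hazard on the relative-wave scale (realistic mode
#'   only).
#' @param reclaim_prob Per-wave probability that a dropped-out participant
#'   visits again.
#' @param capability_dist Parameters of the intake capability distributions.
#' @param n_posttest Number of posttest respondents.
#' @param posttest_selection_bias Log-weight per visit day applied when
#'   sampling posttest respondents (0 = missing completely at random).
#' @param sd_posttest Residual standard deviation of the posttest outcomes.
#' @param seed Integer seed.
#' @return A list with class `cohort_config`.
#' @details `effects` holds one list per outcome. Engagement outcomes
#' (`visits`, `activities`, `walks_longer`, `rides_longer`,
#' `sports_sessions`) take `intercept`, `time` (per relative wave),
#' `maintain`, `improve` (goal contrasts vs unknown) and `personalized`
#' (arm contrast vs control). Posttest outcomes (`walk_perception`,
#' `bike_perception`, `sports_perception`, `self_efficacy`) additionally
#' accept `maintain_x_personalized`, `improve_x_personalized` and `time`
#' (per visited wave).
#' @export
cohort_config <- function(
    n_participants = 176L,
    n_organizations = 7L,
    goal_counts = c(unknown = 93L, maintain = 26L, improve = 57L),
    join_wave_counts = c(140L, 16L, 10L, 10L),
    W = 4L,
    wave_days = 14L,
    mode = c("realistic", "gaussian"),
    effects = list(
      visits = list(intercept = 8, time = -1.174,
                    maintain = 2.176, improve = 1.625, personalized = 0),
      activities = list(intercept = 5, time = -0.080,
                        maintain = 1.535, improve = 3.258, personalized = 0),
      walks_longer = list(intercept = 1.2, time = 0,
                          maintain = 0.261, improve = 0.917,
                          personalized = 0),
      rides_longer = list(intercept = 1.0, time = 0,
                          maintain = 0, improve = 0, personalized = 0),
      sports_sessions = list(intercept = 1.0, time = 0,
                             maintain = 0.405, improve = 0.318,
                             personalized = 0.276),
      walk_perception = list(intercept = 3, time = 0, maintain = 0,
                             improve = 0, personalized = 0,
                             maintain_x_personalized = 0,
                             improve_x_personalized = 0),
      bike_perception = list(intercept = 3, time = 0, maintain = 0,
                             improve = 0, personalized = 0.047,
                             maintain_x_personalized = 0,
                             improve_x_personalized = 0),
      sports_perception = list(intercept = 3, time = 0, maintain = 0,
                               improve = 0, personalized = 0,
                               maintain_x_personalized = 0.500,
                               improve_x_personalized = -0.227),
      self_efficacy = list(intercept = 4, time = -0.329, maintain = 0,
                           improve = 0, personalized = 0,
                           maintain_x_personalized = 0,
                           improve_x_personalized = 0)
    ),
    sd_individual = 1.5,
    sd_organization = 0.5,
    sd_residual = 2.0,
    activity_sds = c(individual = 0.8, organization = 0.3, residual = 1.0),
    dropout_hazard_intercept = -1.0,
    dropout_hazard_slope = 0.3,
    reclaim_prob = 0.15,
    capability_dist = list(steps_meanlog = log(6500), steps_sdlog = 0.4,
                           bike_shape = 2, bike_scale = 20,
                           sports_lambda = 1.5),
    n_posttest = 46L,
    posttest_selection_bias = 0,
    sd_posttest = 0.05,
    seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("n_participants must be positive")
  if (sum(cfg$goal_counts) != cfg$n_participants) {
    stop("goal_counts must sum to n_participants")
  }
  if (length(cfg$join_wave_counts) != cfg$W ||
      sum(cfg$join_wave_counts) != cfg$n_participants) {
    stop("join_wave_counts must have length W and sum to n_participants")
  }
  if (cfg$W < 2) stop("W must be at least 2")
  sds <- c(cfg$sd_individual, cfg$sd_organization, cfg$sd_residual,
           cfg$activity_sds, cfg$sd_posttest)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  invisible(cfg)
}

goal_effect <- function(eff, goal_type) {
  ifelse(goal_type == "maintain", eff$maintain,
         ifelse(goal_type == "improve", eff$improve, 0))
}

#' Generate a synthetic campaign cohort
#'
#' Draws a full synthetic cohort under a [cohort_config()]: participant and
#' intake tables, per participant-wave engagement outcomes, an activity event
#' log consistent with the per-activity-type counts, and a posttest table.
#'
#' The engagement model per participant `i` in organization `g` at relative
#' wave `r` is `y = intercept + time * r + goal effect + arm effect +
#' u_i + v_g + e`, with `u_i ~ N(0, sd_individual^2)`,
#' `v_g ~ N(0, sd_organization^2)`, `e ~ N(0, sd_residual^2)`. In
#' `"gaussian"` mode the outcomes are emitted as-is (and there is no
#' dropout); in `"realistic"` mode visit days are rounded and truncated to
#' `[0, wave_days]`, activity counts to non-negative integers, and a
#' discrete-time logistic dropout hazard increasing in relative wave zeroes
#' out the waves after a participant loses interest (with a small
#' reclaim probability). Goal types are assigned deterministically by the
#' configured counts, not sampled, so the composition is exact. Arms are
#' assigned by goal-type-stratified minimization ([allocate_cohort()]).
#'
#' @param config A [cohort_config()].
#' @param events,posttest Set to `FALSE` to skip synthesizing the activity
#'   event log or the posttest table (replicate-heavy recovery studies only
#'   need the engagement table).
#' @return A list with class `synthetic_cohort`: `participants`, `intake`,
#'   `engagement` (participant x wave outcomes), `visits`, `events`,
#'   `posttest`, and the `config` used.
#' @export
generate_cohort <- function(config = cohort_config(), events = TRUE,
                            posttest = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  W <- config$W

  ## participants ---------------------------------------------------------
  ids <- sprintf("P%03d", seq_len(n))
  orgs <- sprintf("O%d", sample.int(config$n_organizations, n,
                                    replace = TRUE))
  dept <- paste0(orgs, "-D", sample.int(3L, n, replace = TRUE))
  join_wave <- rep(seq_len(W), times = config$join_wave_counts)
  join_wave <- join_wave[sample.int(n)]
  goal_type <- rep(names(config$goal_counts), times = config$goal_counts)
  goal_type <- goal_type[sample.int(n)]
  participants <- data.frame(
    participant_id = ids, organization_id = orgs, department_id = dept,
    join_wave = join_wave, goal_type = goal_type
  )
  participants <- allocate_cohort(participants, W = W,
                                  seed = config$seed + 1L)

  ## intake ---------------------------------------------------------------
  cd <- config$capability_dist
  has_intake <- participants$goal_type != "unknown"
  ni <- sum(has_intake)
  intake <- data.frame(
    participant_id = participants$participant_id[has_intake],
    steps_per_day = round(stats::rlnorm(ni, cd$steps_meanlog,
                                        cd$steps_sdlog)),
    bike_km_per_week = round(stats::rgamma(ni, shape = cd$bike_shape,
                                           scale = cd$bike_scale)),
    sports_sessions_per_week = stats::rpois(ni, cd$sports_lambda),
    goal_steps_per_day = rep(NA_real_, ni),
    goal_bike_km_per_week = rep(NA_real_, ni),
    goal_sports_sessions_per_week = rep(NA_real_, ni)
  )
  improver <- participants$goal_type[has_intake] == "improve"
  for (j in which(improver)) {
    # improve on at least one dimension; each dimension with prob 0.6
    dims <- stats::runif(3) < 0.6
    if (!any(dims)) dims[sample.int(3L, 1L)] <- TRUE
    if (dims[1]) {
      intake$goal_steps_per_day[j] <-
        round(intake$steps_per_day[j] * stats::runif(1, 1.1, 1.5))
    }
    if (dims[2]) {
      intake$goal_bike_km_per_week[j] <-
        round(intake$bike_km_per_week[j] * stats::runif(1, 1.1, 1.5))
    }
    if (dims[3]) {
      intake$goal_sports_sessions_per_week[j] <-
        intake$sports_sessions_per_week[j] + sample(1:2, 1)
    }
  }

  ## random intercepts ----------------------------------------------------
  org_levels <- sort(unique(orgs))
  v_org <- stats::rnorm(length(org_levels), 0, config$sd_organization)
  names(v_org) <- org_levels
  v_org_act <- stats::rnorm(length(org_levels), 0,
                            config$activity_sds[["organization"]])
  names(v_org_act) <- org_levels
  u_visits <- stats::rnorm(n, 0, config$sd_individual)
  u_activities <- stats::rnorm(n, 0, config$sd_individual)
  u_types <- matrix(stats::rnorm(3 * n, 0,
                                 config$activity_sds[["individual"]]),
                    nrow = n)
  colnames(u_types) <- c("walks_longer", "rides_longer", "sports_sessions")

  ## per participant-wave engagement --------------------------------------
  gaussian <- config$mode == "gaussian"
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    waves <- seq.int(participants$join_wave[i], W)
    r <- waves - participants$join_wave[i]
    gt <- participants$goal_type[i]
    pers <- as.numeric(participants$arm[i] == "personalized")

    mu_of <- function(name, u, v) {
      eff <- config$effects[[name]]
      eff$intercept + eff$time * r + goal_effect(eff, gt) +
        eff$personalized * pers + u + v
    }
    visits <- mu_of("visits", u_visits[i], v_org[orgs[i]]) +
      stats::rnorm(length(r), 0, config$sd_residual)
    acts <- mu_of("activities", u_activities[i], v_org[orgs[i]]) +
      stats::rnorm(length(r), 0, config$sd_residual)
    types <- sapply(c("walks_longer", "rides_longer", "sports_sessions"),
                    function(nm) {
                      mu_of(nm, u_types[i, nm], v_org_act[orgs[i]]) +
                        stats::rnorm(length(r), 0,
                                     config$activity_sds[["residual"]])
                    })
    types <- matrix(types, nrow = length(r),
                    dimnames = list(NULL, c("walks_longer", "rides_longer",
                                            "sports_sessions")))

    if (!gaussian) {
      # dropout state machine: active participants visit at least once
      h <- stats::plogis(config$dropout_hazard_intercept +
                           config$dropout_hazard_slope * r)
      active <- logical(length(r))
      state <- TRUE
      for (k in seq_along(r)) {
        if (r[k] == 0) {
          state <- TRUE  # everyone visits during their join wave
        } else if (state) {
          state <- stats::runif(1) > h[k]
        } else {
          state <- stats::runif(1) < config$reclaim_prob
        }
        active[k] <- state
      }
      visits <- ifelse(active,
                       pmin(pmax(round_half_up(visits), 1), config$wave_days),
                       0)
      acts <- ifelse(active, pmax(round_half_up(acts), 0), 0)
      types <- apply(types, 2, function(x) {
        ifelse(active, pmax(round_half_up(x), 0), 0)
      })
      types <- matrix(types, nrow = length(r),
                      dimnames = list(NULL, c("walks_longer", "rides_longer",
                                              "sports_sessions")))
    }

    rows[[i]] <- data.frame(
      participant_id = ids[i], wave = waves, relative_wave = r,
      visit_days = visits, activities_registered = acts,
      walks_longer = types[, "walks_longer"],
      rides_longer = types[, "rides_longer"],
      sports_sessions = types[, "sports_sessions"],
      visited = if (gaussian) TRUE else visits > 0
    )
  }
  engagement <- do.call(rbind, rows)
  rownames(engagement) <- NULL

  visits_log <- engagement[, c("participant_id", "wave", "visit_days",
                               "visited")]

  ## activity event log ---------------------------------------------------
  event_log <- if (events) {
    synthesize_events(participants, intake, engagement, config)
  } else NULL

  ## posttest -------------------------------------------------------------
  posttest_tab <- if (posttest) {
    synthesize_posttest(participants, engagement, config)
  } else NULL

  structure(list(participants = participants, intake = intake,
                 engagement = engagement, visits = visits_log,
                 events = event_log, posttest = posttest_tab,
                 config = config),
            class = "synthetic_cohort")
}

# expand per-wave activity counts into a plausible event log: dynamic-task
# events at magnitudes above their (control-schedule) thresholds, plus short
# walks as filler; counts are rounded in gaussian mode
synthesize_events <- function(participants, intake, engagement, config) {
  camp <- campaign_config(W = config$W, wave_days = config$wave_days)
  out <- list()
  for (i in seq_len(nrow(engagement))) {
    e <- engagement[i, ]
    if (!isTRUE(e$visited)) next
    sched <- control_schedule(e$wave, camp)
    day0 <- (e$wave - 1L) * config$wave_days
    add <- function(kind, count, magnitude) {
      count <- max(round_half_up(count), 0)
      if (count == 0) return()
      out[[length(out) + 1L]] <<- data.frame(
        participant_id = e$participant_id, kind = kind,
        magnitude = magnitude[seq_len(count)],
        day = day0 + sample.int(config$wave_days, count, replace = TRUE),
        source = sample(c("manual", "tracker"), count, replace = TRUE)
      )
    }
    nw <- max(round_half_up(e$walks_longer), 0)
    add("walk", nw,
        round(sched$min_walk_distance * stats::runif(max(nw, 1), 1.0, 1.6)))
    nr <- max(round_half_up(e$rides_longer), 0)
    add("ride", nr,
        round(sched$min_ride_distance * stats::runif(max(nr, 1), 1.0, 1.6)))
    ns <- max(round_half_up(e$sports_sessions), 0)
    add("sports", ns, round(stats::runif(max(ns, 1), 30, 90)))
    # short walks as filler background activity
    nshort <- stats::rpois(1, 1)
    add("walk", nshort, round(stats::runif(max(nshort, 1), 250, 900)))
  }
  if (length(out) == 0) {
    return(data.frame(participant_id = character(0), kind = character(0),
                      magnitude = numeric(0), day = integer(0),
                      source = character(0)))
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$day, ev$participant_id), ]
  rownames(ev) <- NULL
  ev
}

synthesize_posttest <- function(participants, engagement, config) {
  n <- nrow(participants)
  total_visits <- tapply(engagement$visit_days, engagement$participant_id,
                         sum)[participants$participant_id]
  total_visits[is.na(total_visits)] <- 0
  waves_visited <- tapply(engagement$visited, engagement$participant_id,
                          sum)[participants$participant_id]
  waves_visited[is.na(waves_visited)] <- 0
  w <- exp(config$posttest_selection_bias * as.numeric(total_visits))
  k <- min(config$n_posttest, n)
  resp <- sample.int(n, k, prob = w / sum(w))

  gt <- participants$goal_type[resp]
  pers <- as.numeric(participants$arm[resp] == "personalized")
  tw <- as.numeric(waves_visited[resp])
  outcome <- function(name) {
    eff <- config$effects[[name]]
    eff$intercept + eff$time * tw + goal_effect(eff, gt) +
      eff$personalized * pers +
      eff$maintain_x_personalized * (gt == "maintain") * pers +
      eff$improve_x_personalized * (gt == "improve") * pers +
      stats::rnorm(k, 0, config$sd_posttest)
  }
  data.frame(
    participant_id = participants$participant_id[resp],
    goal_type = gt, arm = participants$arm[resp],
    waves_visited = tw,
    walk_perception = outcome("walk_perception"),
    bike_perception = outcome("bike_perception"),
    sports_perception = outcome("sports_perception"),
    self_efficacy = outcome("self_efficacy")
  )
}

#' A tiny handcrafted cohort for documentation and integration tests
#'
#' Six participants over a two-wave, one-organization campaign with a fully
#' known event log: a participant with a single 300 m walk (worth 2 points as
#' a short walk), one who never opens the app in wave 2 (a dropout during
#' wave 1), one who joins only in the final wave (never allocated), a
#' registration-only visitor, an event-free participant, and one active
#' participant with known longer-walk scores.
#'
#' @return A `synthetic_cohort`-shaped list (with `posttest` empty).
#' @export
generate_worked_fixture <- function() {
  camp <- campaign_config(W = 2L, wave_days = 14L)
  participants <- data.frame(
    participant_id = paste0("F0", 1:6),
    organization_id = "O1",
    department_id = c("O1-D1", "O1-D1", "O1-D2", "O1-D2", "O1-D1", "O1-D2"),
    join_wave = c(1L, 1L, 1L, 2L, 1L, 1L),
    goal_type = c("improve", "unknown", "maintain", "unknown", "unknown",
                  "unknown"),
    arm = c("personalized", "control", "personalized", "none", "control",
            "control")
  )
  intake <- data.frame(
    participant_id = c("F01", "F03"),
    steps_per_day = c(7000, 6000),
    bike_km_per_week = c(10, 20),
    sports_sessions_per_week = c(2, 3),
    goal_steps_per_day = c(9000, NA),
    goal_bike_km_per_week = c(15, NA),
    goal_sports_sessions_per_week = c(3, NA)
  )
  events <- data.frame(
    participant_id = c("F01", "F01", "F01", "F03", "F03", "F05"),
    kind = c("walk", "walk", "sports", "ride", "walk", "walk"),
    magnitude = c(300, 2500, 45, 4200, 2600, 400),
    day = c(2L, 5L, 6L, 3L, 16L, 1L),
    source = "manual"
  )
  visits <- expand.grid(participant_id = participants$participant_id,
                        wave = 1:2, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  visits <- visits[visits$wave >= participants$join_wave[
    match(visits$participant_id, participants$participant_id)], ]
  visit_days <- c(F01 = 1, F02 = 2, F03 = 3, F04 = 0, F05 = 1, F06 = 1)
  visits$visit_days <- ifelse(
    visits$wave == 1, visit_days[visits$participant_id],
    c(F01 = 2, F02 = 0, F03 = 4, F04 = 1, F05 = 0,
      F06 = 1)[visits$participant_id]
  )
  visits$visited <- visits$visit_days > 0
  visits <- visits[order(visits$participant_id, visits$wave), ]
  rownames(visits) <- NULL
  structure(list(participants = participants, intake = intake,
                 engagement = NULL, visits = visits, events = events,
                 posttest = data.frame(), config = camp),
            class = "synthetic_cohort")
}
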