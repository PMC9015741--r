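#' Stratified arm assignment for one joining participant
#'
#' Minimization-style sequential balancing: within the participant's
#' goal-type stratum (`unknown`, `maintain`, `improve`), the participant is
#' assigned to whichever arm currently has fewer members, so that the arm
#' counts within every stratum never differ by more than one. Ties are broken
#' by the supplied random number generator, making the allocation sequence
#' reproducible under a fixed seed. Participants joining during the final
#' wave are never allocated (`arm = "none"`): they only ever experience the
#' default task set.
#'
#' @param goal_type One of `"unknown"`, `"maintain"`, `"improve"`.
#' @param strata_counts A named list of per-stratum tallies, each
#'   `c(control = n, personalized = n)`.
#' @param join_wave Wave during which the participant joined.
#' @param W Total number of waves.
#' @return A list with `arm` and the updated `strata_counts`.
#' @export
assign_arm <- function(goal_type, strata_counts, join_wave, W = 4L) {
  stopifnot(goal_type %in% c("unknown", "maintain", "improve"))
  if (join_wave >= W) {
    return(list(arm = "none", strata_counts = strata_counts))
  }
  tally <- strata_counts[[goal_type]]
  if (is.null(tally)) tally <- c(control = 0L, personalized = 0L)
  arm <- if (tally["control"] < tally["personalized"]) {
    "control"
  } else if (tally["control"] > tally["personalized"]) {
    "personalized"
  } else {
    sample(c("control", "personalized"), 1L)
  }
  tally[arm] <- tally[arm] + 1L
  strata_counts[[goal_type]] <- tally
  list(arm = arm, strata_counts = strata_counts)
}

#' Allocate a cohort of participants to study arms
#'
#' Participants are processed in arrival order (join wave, then row order,
#' mirroring signup order) and assigned by [assign_arm()]; allocation takes
#' effect at the start of the wave after the join wave. The random tie-break
#' stream is seeded locally so the allocation is reproducible and does not
#' disturb the caller's RNG state.
#'
#' @param participants Data frame with `participant_id`, `join_wave` and
#'   `goal_type`.
#' @param W Total number of waves.
#' @param seed Integer seed for tie-breaking.
#' @return The participants data frame with an `arm` column
#'   (`control`/`personalized`/`none`).
#' @export
allocate_cohort <- function(participants, W = 4L, seed = 1L) {
  stopifnot(all(c("participant_id", "join_wave", "goal_type") %in%
                  names(participants)))
  ord <- order(participants$join_wave)
  counts <- list()
  arm <- character(nrow(participants))
  local_seed(seed, {
    for (i in ord) {
      res <- assign_arm(participants$goal_type[i], counts,
                        participants$join_wave[i], W)
      arm[i] <- res$arm
      counts <- res$strata_counts
    }
  })
  participants$arm <- arm
  participants
}

# evaluate expr under a locally seeded RNG, restoring global RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Active task parameters for a participant in a given wave
#'
#' During the wave a participant joins, everyone receives the default
#' (control-style) task set regardless of eventual arm; from the next wave
#' on, control-arm participants follow the generic schedule and
#' personalized-arm participants the goal engine. Never-allocated
#' participants (`arm = "none"`) keep the default set throughout.
#'
#' @param arm One of `"control"`, `"personalized"`, `"none"`.
#' @param join_wave Wave during which the participant joined.
#' @param w Wave to plan, `w >= join_wave`.
#' @inheritParams personalized_schedule
#' @return A one-row data frame of dynamic parameters.
#' @export
active_taskset <- function(arm, join_wave, w, intake = NULL, history = NULL,
                           population_history = NULL,
                           config = campaign_config()) {
  if (w < join_wave) stop("wave ", w, " precedes join wave ", join_wave)
  if (arm == "none" || w == join_wave || arm == "control") {
    control_schedule(w, config)
  } else {
    personalized_schedule(intake, w, history, population_history, config)
  }
}

#' Plan dynamic-task parameters for a cohort
#'
#' Computes one row of dynamic parameters per participant and wave from their
#' join wave onward, applying the default-set grace period and per-arm
#' schedule of [active_taskset()]. Personalized parameters are computed at
#' wave commencement: only events strictly before the wave's first day enter
#' the capability fallbacks.
#'
#' @param participants Data frame with `participant_id`, `join_wave`, `arm`.
#' @param intake Data frame of intake records (one row per participant who
#'   completed the survey), or `NULL`.
#' @param events Activity event log used for capability fallbacks, or `NULL`.
#' @param waves Waves to plan (default all).
#' @param config A [campaign_config()].
#' @return Data frame with `participant_id`, `wave`, `min_walk_distance`,
#'   `min_ride_distance`, `rewarded_sports_sessions`.
#' @export
plan_tasksets <- function(participants, intake = NULL, events = NULL,
                          waves = seq_len(config$W),
                          config = campaign_config()) {
  unknown <- setdiff(
    if (is.null(intake)) character(0) else intake$participant_id,
    participants$participant_id
  )
  if (length(unknown)) {
    stop("unknown participant ids in intake: ",
         paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (w in waves) {
    wave_start_day <- (w - 1L) * config$wave_days + 1L
    past <- if (is.null(events)) NULL else
      events[events$day < wave_start_day, , drop = FALSE]
    active <- participants[participants$join_wave <= w, , drop = FALSE]
    for (i in seq_len(nrow(active))) {
      p <- active[i, ]
      p_intake <- if (is.null(intake)) NULL else {
        r <- intake[intake$participant_id == p$participant_id, ,
                    drop = FALSE]
        if (nrow(r)) r else NULL
      }
      hist <- if (is.null(past)) NULL else
        past[past$participant_id == p$participant_id, , drop = FALSE]
      pop <- if (is.null(past)) NULL else
        past[past$participant_id != p$participant_id, , drop = FALSE]
      params <- active_taskset(p$arm, p$join_wave, w, p_intake, hist, pop,
                               config)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = p$participant_id, wave = w), params
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
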