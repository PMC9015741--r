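#' Build the six-task set for one participant and wave
#'
#' Three static tasks (short walk of at least 250 m, short ride of at least
#' 1 km, healthy moment of the week) are combined with three dynamic tasks
#' whose complexity parameters come from the goal engine: a longer walk of at
#' least `min_walk_distance` meters, a longer ride of at least
#' `min_ride_distance` meters, and sports sessions of at least 30 minutes
#' rewarded up to `X = rewarded_sports_sessions` times per week at `40 / X`
#' points each (so the weekly sports maximum is always 40). For every task,
#' `points_per_activity * max_rewards_per_week = max_points_per_week`.
#'
#' @param dynamic A one-row data frame with `min_walk_distance`,
#'   `min_ride_distance`, `rewarded_sports_sessions` (as returned by
#'   [control_schedule()] or [personalized_schedule()]).
#' @param config A [campaign_config()].
#' @return A data frame with one row per task: `task`, `kind` (the activity
#'   kind it rewards), `threshold` (meters or minutes), `points_per_activity`,
#'   `max_rewards_per_week`, `max_points_per_week`.
#' @export
build_taskset <- function(dynamic, config = campaign_config()) {
  stopifnot(nrow(dynamic) == 1)
  pr <- config$point_rules
  X <- dynamic$rewarded_sports_sessions
  tasks <- data.frame(
    task = c("short_walk", "longer_walk", "short_ride", "longer_ride",
             "sports_session", "healthy_moment"),
    kind = c("walk", "walk", "ride", "ride", "sports", "healthy_moment"),
    threshold = c(pr$short_walk$threshold, dynamic$min_walk_distance,
                  pr$short_ride$threshold, dynamic$min_ride_distance,
                  pr$sports_session$threshold, NA),
    points_per_activity = c(pr$short_walk$points, pr$longer_walk$points,
                            pr$short_ride$points, pr$longer_ride$points,
                            pr$sports_session$weekly_points / X,
                            pr$healthy_moment$points),
    max_rewards_per_week = c(pr$short_walk$max_rewards,
                             pr$longer_walk$max_rewards,
                             pr$short_ride$max_rewards,
                             pr$longer_ride$max_rewards,
                             X,
                             pr$healthy_moment$max_rewards)
  )
  tasks$max_points_per_week <- tasks$points_per_activity *
    tasks$max_rewards_per_week
  tasks
}

qualifying_tasks <- function(event, taskset) {
  cand <- taskset[taskset$kind == event$kind, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  ok <- is.na(cand$threshold) | (!is.na(event$magnitude) &
                                   event$magnitude >= cand$threshold)
  cand[ok, , drop = FALSE]
}

new_ledger_state <- function() {
  new.env(parent = emptyenv())
}

#' Score a stream of activity events
#'
#' Each event is matched to the single highest-points task it qualifies for
#' within the participant's task set of that wave (a 2.5 km walk is rewarded
#' as a longer walk, not additionally as a short walk). The matched task's
#' points are awarded only while its weekly reward count and weekly point cap
#' are not exhausted; once exhausted, further qualifying events of that week
#' earn nothing. Weeks are consecutive 7-day windows from campaign start.
#'
#' @param events Data frame of activity events with columns `participant_id`,
#'   `kind` (`walk`/`ride`/`sports`/`healthy_moment`), `magnitude` (meters
#'   for walks/rides, minutes for sports, `NA` otherwise) and `day` (1-based
#'   day index from campaign start). An optional `source` column is carried
#'   through unused.
#' @param tasksets Data frame with one row per `participant_id` x `wave`
#'   holding the dynamic parameters (`min_walk_distance`, `min_ride_distance`,
#'   `rewarded_sports_sessions`), as produced by [plan_tasksets()].
#' @param config A [campaign_config()].
#' @return An object of class `score_ledger`: a list with `awards` (one row
#'   per event, with matched `task` and `points`), `weekly` (per participant,
#'   week and task: `rewards_granted`, `points_granted`) and `wave_totals`
#'   (per participant and wave).
#' @export
score_events <- function(events, tasksets, config = campaign_config()) {
  stopifnot(all(c("participant_id", "kind", "magnitude", "day") %in%
                  names(events)))
  if (nrow(events) > 0 && any(events$day < 1)) {
    stop("event before campaign start")
  }
  # stable chronological order; equal-day events keep input order
  events <- events[order(events$day), , drop = FALSE]
  events$wave <- if (nrow(events)) wave_of_day(events$day, config) else
    integer(0)
  events$week <- if (nrow(events)) week_of_day(events$day, config) else
    integer(0)

  ts_key <- paste(tasksets$participant_id, tasksets$wave)
  taskset_cache <- new.env(parent = emptyenv())
  get_taskset <- function(pid, wave) {
    key <- paste(pid, wave)
    ts <- taskset_cache[[key]]
    if (is.null(ts)) {
      i <- match(key, ts_key)
      if (is.na(i)) stop("no taskset for participant ", pid, " wave ", wave)
      ts <- build_taskset(tasksets[i, , drop = FALSE], config)
      taskset_cache[[key]] <- ts
    }
    ts
  }

  rewards <- new_ledger_state()  # key -> c(rewards, points)
  n <- nrow(events)
  award_task <- character(n)
  award_points <- numeric(n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    ts <- get_taskset(ev$participant_id, ev$wave)
    cand <- qualifying_tasks(ev, ts)
    if (nrow(cand) == 0) {
      award_task[i] <- NA_character_
      next
    }
    best <- cand[which.max(cand$points_per_activity), ]
    award_task[i] <- best$task
    key <- paste(ev$participant_id, ev$week, best$task)
    st <- rewards[[key]]
    if (is.null(st)) st <- c(0, 0)
    # tolerance guards the exact-rational sports cap (40/X * X == 40)
    if (st[1] + 1 <= best$max_rewards_per_week &&
        st[2] + best$points_per_activity <=
          best$max_points_per_week + 1e-9) {
      award_points[i] <- best$points_per_activity
      rewards[[key]] <- st + c(1, best$points_per_activity)
    }
  }
  awards <- cbind(events, task = award_task, points = award_points)

  weekly <- if (n > 0) {
    scored <- awards[!is.na(awards$task), , drop = FALSE]
    if (nrow(scored) > 0) {
      stats::aggregate(
        list(rewards_granted = scored$points > 0,
             points_granted = scored$points),
        by = list(participant_id = scored$participant_id,
                  week = scored$week, task = scored$task),
        FUN = sum
      )
    } else empty_weekly()
  } else empty_weekly()

  wave_totals <- if (n > 0) {
    stats::aggregate(
      list(points = awards$points),
      by = list(participant_id = awards$participant_id, wave = awards$wave),
      FUN = sum
    )
  } else {
    data.frame(participant_id = character(0), wave = integer(0),
               points = numeric(0))
  }

  structure(list(awards = awards, weekly = weekly, wave_totals = wave_totals),
            class = "score_ledger")
}

empty_weekly <- function() {
  data.frame(participant_id = character(0), week = integer(0),
             task = character(0), rewards_granted = integer(0),
             points_granted = numeric(0))
}

#' Individual and department leaderboards for one wave
#'
#' Individual scores are wave totals ranked within each organization;
#' department scores are the arithmetic mean of member wave totals. Both are
#' computed from the current reset period only, so at the start of a wave all
#' scores are zero. Enrolled participants without any scored activity in the
#' wave appear with zero points.
#'
#' @param ledger A `score_ledger` from [score_events()].
#' @param wave Wave number.
#' @param participants Data frame with `participant_id`, `organization_id`,
#'   `department_id` defining leaderboard membership.
#' @return A list with `individual` (participant_id, organization_id, points,
#'   rank within organization) and `department` (organization_id,
#'   department_id, mean_points, rank within organization).
#' @export
leaderboards <- function(ledger, wave, participants) {
  wt <- ledger$wave_totals
  wt <- wt[wt$wave == wave, c("participant_id", "points"), drop = FALSE]
  ind <- merge(participants[, c("participant_id", "organization_id",
                                "department_id")],
               wt, by = "participant_id", all.x = TRUE)
  ind$points[is.na(ind$points)] <- 0
  ind <- ind[order(ind$organization_id, -ind$points, ind$participant_id), ]
  ind$rank <- stats::ave(-ind$points, ind$organization_id,
                         FUN = function(x) rank(x, ties.method = "min"))
  rownames(ind) <- NULL

  dep <- stats::aggregate(
    list(mean_points = ind$points),
    by = list(organization_id = ind$organization_id,
              department_id = ind$department_id),
    FUN = mean
  )
  dep <- dep[order(dep$organization_id, -dep$mean_points,
                   dep$department_id), ]
  dep$rank <- stats::ave(-dep$mean_points, dep$organization_id,
                         FUN = function(x) rank(x, ties.method = "min"))
  rownames(dep) <- NULL
  list(individual = ind, department = dep)
}
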