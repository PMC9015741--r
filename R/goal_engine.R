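#' Transform intake self-reports into task units
#'
#' Intake surveys ask for steps walked per day and kilometers biked per week;
#' the dynamic tasks are phrased as single-trip minimum distances. Daily steps
#' are converted to meters with an average stride length of 0.73 m and spread
#' over three walks per day; weekly bike kilometers are spread over five
#' rides per week. Values are rounded to the nearest integer meter.
#'
#' @param steps_per_day Non-negative number of steps walked per day.
#' @param config A [campaign_config()].
#' @return Minimum walk distance in meters (integer), before capping.
#' @examples
#' steps_to_min_walk_distance(7000) # 1703
#' @export
steps_to_min_walk_distance <- function(steps_per_day,
                                       config = campaign_config()) {
  if (any(is.na(steps_per_day)) || any(steps_per_day < 0)) {
    stop("steps_per_day must be non-negative")
  }
  round_half_up(steps_per_day * config$stride_m / config$walks_per_day)
}

#' @param km_per_week Non-negative number of kilometers biked per week.
#' @return Minimum ride distance in meters (integer), before capping.
#' @examples
#' weekly_km_to_min_ride_distance(10) # 2000
#' @rdname steps_to_min_walk_distance
#' @export
weekly_km_to_min_ride_distance <- function(km_per_week,
                                           config = campaign_config()) {
  if (any(is.na(km_per_week)) || any(km_per_week < 0)) {
    stop("km_per_week must be non-negative")
  }
  round_half_up(km_per_week / config$rides_per_week * 1000)
}

activity_types <- c("walk", "ride", "sports")

check_activity_type <- function(activity_type) {
  if (length(activity_type) != 1 || !activity_type %in% activity_types) {
    stop("unknown activity type: ", paste(activity_type, collapse = ", "))
  }
  activity_type
}

intake_capability_value <- function(intake, activity_type, config) {
  v <- switch(activity_type,
    walk   = intake$steps_per_day,
    ride   = intake$bike_km_per_week,
    sports = intake$sports_sessions_per_week
  )
  if (is.null(v) || length(v) == 0 || is.na(v)) return(NULL)
  switch(activity_type,
    walk   = steps_to_min_walk_distance(v, config),
    ride   = weekly_km_to_min_ride_distance(v, config),
    sports = round_half_up(v)
  )
}

intake_goal_value <- function(intake, activity_type, config) {
  v <- switch(activity_type,
    walk   = intake$goal_steps_per_day,
    ride   = intake$goal_bike_km_per_week,
    sports = intake$goal_sports_sessions_per_week
  )
  if (is.null(v) || length(v) == 0 || is.na(v)) return(NULL)
  switch(activity_type,
    walk   = steps_to_min_walk_distance(v, config),
    ride   = weekly_km_to_min_ride_distance(v, config),
    sports = round_half_up(v)
  )
}

# last recorded performance of one participant for an activity type, in task
# units; NULL if no history. For walks/rides this is the magnitude (m) of the
# most recent event (ties on day broken by the largest magnitude); for sports
# it is the number of sports events in the most recent 7-day scoring week
# containing one, since the task unit is sessions/week.
last_performance <- function(history, activity_type,
                             config = campaign_config()) {
  if (is.null(history) || nrow(history) == 0) return(NULL)
  h <- history[history$kind == activity_type, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  if (activity_type == "sports") {
    weeks <- week_of_day(h$day, config)
    sum(weeks == max(weeks))
  } else {
    h <- h[order(h$day, h$magnitude), , drop = FALSE]
    h$magnitude[nrow(h)]
  }
}

# mean performance over a set of participants, in task units; NULL when no
# participant has history for the type. For sports: mean weekly session count
# over each participant's active weeks.
population_performance <- function(population_history, activity_type,
                                   config = campaign_config()) {
  if (is.null(population_history) || nrow(population_history) == 0) {
    return(NULL)
  }
  h <- population_history[population_history$kind == activity_type, ,
                          drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  if (activity_type == "sports") {
    per_week <- stats::aggregate(
      list(n = h$day),
      by = list(participant_id = h$participant_id,
                week = week_of_day(h$day, config)),
      FUN = length
    )
    mean(per_week$n)
  } else {
    mean(h$magnitude)
  }
}

#' Resolve a participant's capability for one activity dimension
#'
#' Capability is resolved in task units with the following priority: the
#' intake self-report (transformed to task units); the participant's last
#' recorded performance for that activity type; the average performance of
#' all other users for that type; and finally a fixed default (1 km walk,
#' 2 km ride, 2 sports sessions). The function is total: it always returns a
#' value.
#'
#' @param intake A one-row data frame (or list) with intake columns
#'   `steps_per_day`, `bike_km_per_week`, `sports_sessions_per_week`
#'   (`NA`/absent when not stated), or `NULL` when the intake survey was not
#'   completed.
#' @param activity_type One of `"walk"`, `"ride"`, `"sports"`.
#' @param history Activity events of the focal participant (data frame with
#'   `kind`, `magnitude`, `day`), or `NULL`.
#' @param population_history Activity events of all *other* participants,
#'   or `NULL`.
#' @param config A [campaign_config()].
#' @return Capability in task units (meters or sessions/week).
#' @export
resolve_capability <- function(intake = NULL, activity_type, history = NULL,
                               population_history = NULL,
                               config = campaign_config()) {
  check_activity_type(activity_type)
  if (!is.null(intake)) {
    v <- intake_capability_value(intake, activity_type, config)
    if (!is.null(v)) return(v)
  }
  v <- last_performance(history, activity_type, config)
  if (!is.null(v)) return(v)
  v <- population_performance(population_history, activity_type, config)
  if (!is.null(v)) return(v)
  unname(config$capability_defaults[[activity_type]])
}

#' Resolve a participant's goal for one activity dimension
#'
#' The goal, in task units, is the transformed intake goal when one was
#' stated. Participants who completed the intake but stated no improvement
#' target on this dimension keep a maintenance goal equal to their
#' capability, so their task parameter stays constant across waves.
#' Participants without intake get a default improvement goal: capability
#' times 1.1 for walks and rides, capability plus one session for sports.
#'
#' @inheritParams resolve_capability
#' @param capability Resolved capability in task units.
#' @return Goal in task units.
#' @export
resolve_goal <- function(intake = NULL, activity_type, capability,
                         config = campaign_config()) {
  check_activity_type(activity_type)
  if (!is.null(intake)) {
    v <- intake_goal_value(intake, activity_type, config)
    if (!is.null(v)) return(v)
    # intake completed, no improvement desired on this dimension: maintain
    return(capability)
  }
  if (activity_type == "sports") {
    capability + config$goal_sports_increment
  } else {
    capability * config$goal_uplift
  }
}

#' Linear growth of a task parameter toward the goal
#'
#' At the commencement of wave `w` of `W`, the task parameter is
#' `capability + (goal - capability) * w / W`, rounded to the nearest integer
#' task unit; it equals the goal exactly in the final wave and stays constant
#' when goal equals capability.
#'
#' @param capability,goal Values in task units.
#' @param w Wave number, `1 <= w <= W`.
#' @param W Total number of waves.
#' @return Interpolated parameter (integer task units), before capping.
#' @export
interpolate_parameter <- function(capability, goal, w, W = 4L) {
  stopifnot(W >= 1, all(w >= 1), all(w <= W))
  round_half_up(capability + (goal - capability) * w / W)
}

#' Cap a task parameter to its allowed range
#'
#' Minimum walk distances are clamped to 1--10 km, minimum ride distances to
#' 2--17.5 km, and rewarded sports sessions to 2--10 per week; a suggested
#' frequency of zero sports sessions is thus overridden to two.
#'
#' @param activity_type One of `"walk"`, `"ride"`, `"sports"`.
#' @param value Parameter value in task units, `>= 0`.
#' @param config A [campaign_config()].
#' @return The clamped value.
#' @export
cap_parameter <- function(activity_type, value, config = campaign_config()) {
  check_activity_type(activity_type)
  stopifnot(all(value >= 0))
  b <- config$caps[[activity_type]]
  pmin(pmax(value, b[1]), b[2])
}

#' Control-arm schedule of dynamic-task parameters
#'
#' Returns the generic guideline-based parameters suggested to the control
#' arm for one wave: minimum walk distance 1500/2000/2250/2500 m, minimum
#' ride distance 3500/4000/4250/4500 m, and 4/4/5/5 rewarded sports sessions
#' across waves 1--4.
#'
#' @param w Wave number.
#' @param config A [campaign_config()].
#' @return A one-row data frame with `min_walk_distance`, `min_ride_distance`
#'   and `rewarded_sports_sessions`.
#' @export
control_schedule <- function(w, config = campaign_config()) {
  sched <- config$control_schedule
  if (length(w) != 1 || !w %in% sched$wave) {
    stop("wave out of range: ", w)
  }
  row <- sched[sched$wave == w, c("min_walk_distance", "min_ride_distance",
                                  "rewarded_sports_sessions")]
  rownames(row) <- NULL
  row
}

#' Personalized schedule of dynamic-task parameters
#'
#' For each of the three dynamic tasks, resolves the participant's capability
#' and goal ([resolve_capability()], [resolve_goal()]), interpolates linearly
#' toward the goal at wave `w` of `W` ([interpolate_parameter()]), and caps
#' the result ([cap_parameter()]). Total by construction: every fallback
#' combination yields valid parameters.
#'
#' @inheritParams resolve_capability
#' @param w Wave number at whose commencement the parameters are set.
#' @return A one-row data frame with `min_walk_distance`, `min_ride_distance`
#'   and `rewarded_sports_sessions`.
#' @export
personalized_schedule <- function(intake = NULL, w, history = NULL,
                                  population_history = NULL,
                                  config = campaign_config()) {
  stopifnot(w >= 1, w <= config$W)
  one <- function(type) {
    cap <- resolve_capability(intake, type, history, population_history,
                              config)
    goal <- resolve_goal(intake, type, cap, config)
    cap_parameter(type, interpolate_parameter(cap, goal, w, config$W), config)
  }
  data.frame(
    min_walk_distance        = one("walk"),
    min_ride_distance        = one("ride"),
    rewarded_sports_sessions = one("sports")
  )
}
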