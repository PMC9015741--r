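#' Campaign configuration
#'
#' Returns the default configuration of an 8-week, 4-wave health-promotion
#' campaign: wave structure, the transformation constants that turn intake
#' self-reports into task units, the cap bounds for each dynamic task, the
#' fixed fallback capabilities, the generic (control-arm) schedule, and the
#' point rules of the six tasks.
#'
#' Task units are meters for walk and ride distances and rewarded sessions
#' per week for sports. Intake self-reports arrive in survey units
#' (steps/day, km/week, sessions/week) and are transformed by
#' [steps_to_min_walk_distance()] and [weekly_km_to_min_ride_distance()].
#'
#' @param W Total number of waves of the campaign.
#' @param wave_days Length of one wave in days.
#' @return A list with class `campaign_config`.
#' @export
campaign_config <- function(W = 4L, wave_days = 14L) {
  stopifnot(W >= 1, wave_days >= 7)
  structure(list(
    W = as.integer(W),
    wave_days = as.integer(wave_days),
    # intake transformations: steps/day * stride / trips_per_day -> meters;
    # km/week / rides_per_week -> km
    stride_m = 0.73,
    walks_per_day = 3,
    rides_per_week = 5,
    # fallback goal rules when no intake: +10% distance, +1 session
    goal_uplift = 1.1,
    goal_sports_increment = 1,
    # cap bounds per dynamic task, in task units
    caps = list(
      walk   = c(1000, 10000),
      ride   = c(2000, 17500),
      sports = c(2, 10)
    ),
    # fixed capability defaults when no intake, no history, empty population
    capability_defaults = c(walk = 1000, ride = 2000, sports = 2),
    # generic schedule suggested to the control arm, one column per wave
    control_schedule = data.frame(
      wave                     = 1:4,
      min_walk_distance        = c(1500, 2000, 2250, 2500),
      min_ride_distance        = c(3500, 4000, 4250, 4500),
      rewarded_sports_sessions = c(4, 4, 5, 5)
    ),
    # static-task thresholds (meters / minutes) and point rules
    point_rules = list(
      short_walk     = list(threshold = 250,  points = 2,  max_rewards = 14),
      longer_walk    = list(threshold = NA,   points = 8,  max_rewards = 7),
      short_ride     = list(threshold = 1000, points = 4,  max_rewards = 7),
      longer_ride    = list(threshold = NA,   points = 8,  max_rewards = 7),
      sports_session = list(threshold = 30,   points = NA, max_rewards = NA,
                            weekly_points = 40),
      healthy_moment = list(threshold = NA,   points = 10, max_rewards = 1)
    )
  ), class = "campaign_config")
}

#' Read a campaign configuration from YAML
#'
#' Reads a YAML file holding any subset of the `campaign_config()` fields and
#' merges it over the defaults. The control schedule may be given as a list
#' of per-wave rows.
#'
#' @param path Path to a YAML file.
#' @return A `campaign_config` list.
#' @export
read_campaign_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- campaign_config(
    W = raw$W %||% 4L,
    wave_days = raw$wave_days %||% 14L
  )
  scalar_fields <- intersect(
    names(raw),
    c("stride_m", "walks_per_day", "rides_per_week",
      "goal_uplift", "goal_sports_increment")
  )
  cfg[scalar_fields] <- raw[scalar_fields]
  if (!is.null(raw$caps)) {
    for (t in names(raw$caps)) cfg$caps[[t]] <- as.numeric(raw$caps[[t]])
  }
  if (!is.null(raw$capability_defaults)) {
    cd <- unlist(raw$capability_defaults)
    cfg$capability_defaults[names(cd)] <- cd
  }
  if (!is.null(raw$control_schedule)) {
    cfg$control_schedule <- as.data.frame(
      do.call(rbind, lapply(raw$control_schedule, as.data.frame))
    )
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up, used for all integer task parameters (R's round() would
# round 0.5 to even)
round_half_up <- function(x) floor(x + 0.5)

#' Wave and week indexing
#'
#' Days are 1-based from campaign start. Each wave is `wave_days` long and is
#' split into consecutive 7-day scoring weeks anchored at the campaign start.
#'
#' @param day Integer day index, 1-based.
#' @param config A `campaign_config`.
#' @return Integer wave (or week) index.
#' @export
wave_of_day <- function(day, config = campaign_config()) {
  stopifnot(all(day >= 1))
  pmin(((as.integer(day) - 1L) %/% config$wave_days) + 1L, config$W)
}

#' @rdname wave_of_day
#' @export
week_of_day <- function(day, config = campaign_config()) {
  stopifnot(all(day >= 1))
  ((as.integer(day) - 1L) %/% 7L) + 1L
}
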