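test_that("intake transformations convert survey units to task units", {
  expect_equal(steps_to_min_walk_distance(7000), 1703)
  expect_equal(steps_to_min_walk_distance(0), 0)
  expect_equal(steps_to_min_walk_distance(3000), 730)
  expect_equal(weekly_km_to_min_ride_distance(10), 2000)
  expect_equal(weekly_km_to_min_ride_distance(0), 0)
  expect_equal(weekly_km_to_min_ride_distance(7), 1400)
  expect_error(steps_to_min_walk_distance(-1), "non-negative")
  expect_error(weekly_km_to_min_ride_distance(-0.5), "non-negative")
})

test_that("capability resolution follows the intake > history > population > default chain", {
  # no information at all: fixed defaults
  expect_equal(resolve_capability(NULL, "ride"), 2000)
  expect_equal(resolve_capability(NULL, "walk"), 1000)
  expect_equal(resolve_capability(NULL, "sports"), 2)

  # intake takes priority over everything
  intake <- data.frame(steps_per_day = 7000, bike_km_per_week = NA,
                       sports_sessions_per_week = NA)
  hist <- data.frame(kind = "walk", magnitude = 5000, day = 3,
                     participant_id = "A")
  expect_equal(resolve_capability(intake, "walk", history = hist), 1703)

  # last performance: most recent event wins, day ties break to the largest
  hist2 <- data.frame(kind = c("walk", "walk", "ride"),
                      magnitude = c(1800, 2200, 9999),
                      day = c(1, 5, 2), participant_id = "A")
  expect_equal(resolve_capability(NULL, "walk", history = hist2), 2200)
  tie <- data.frame(kind = "walk", magnitude = c(1500, 1900), day = c(4, 4),
                    participant_id = "A")
  expect_equal(resolve_capability(NULL, "walk", history = tie), 1900)

  # population mean of other users when the focal history lacks the type
  pop <- data.frame(kind = c("ride", "ride"), magnitude = c(3000, 5000),
                    day = c(1, 2), participant_id = c("B", "C"))
  expect_equal(
    resolve_capability(NULL, "ride", history = hist2[hist2$kind == "walk", ],
                       population_history = pop),
    4000
  )

  # sports capability from history is a weekly session count
  sp <- data.frame(kind = "sports", magnitude = c(40, 50, 30),
                   day = c(2, 9, 11), participant_id = "A")
  expect_equal(resolve_capability(NULL, "sports", history = sp), 2)
})

test_that("goal resolution uses intake goals, maintenance, or default uplift", {
  expect_equal(resolve_goal(NULL, "ride", capability = 2000), 2200)
  expect_equal(resolve_goal(NULL, "sports", capability = 2), 3)
  intake <- data.frame(steps_per_day = 6000, bike_km_per_week = 10,
                       sports_sessions_per_week = 1,
                       goal_steps_per_day = 7000,
                       goal_bike_km_per_week = NA,
                       goal_sports_sessions_per_week = NA)
  expect_equal(resolve_goal(intake, "walk", capability = 1460), 1703)
  # intake completed but no ride goal: maintain current capability
  expect_equal(resolve_goal(intake, "ride", capability = 2000), 2000)
})

test_that("interpolation grows linearly and hits the goal in the final wave", {
  expect_equal(interpolate_parameter(1000, 2000, w = 4, W = 4), 2000)
  expect_equal(interpolate_parameter(1500, 1500, w = 2, W = 4), 1500)
  expect_equal(interpolate_parameter(1000, 2000, w = 2, W = 4), 1500)

  # endpoint exactness and monotonicity over a brute-force grid
  for (capab in c(0, 500, 1703, 4000)) {
    for (goal in c(0, 250, 1703, 2200, 6000)) {
      path <- sapply(1:4, function(w) interpolate_parameter(capab, goal, w, 4))
      expect_equal(path[4], round(goal))
      d <- diff(path)
      if (goal > capab) expect_true(all(d >= 0))
      if (goal < capab) expect_true(all(d <= 0))
    }
  }
})

test_that("capping clamps to the per-task bounds and is idempotent", {
  expect_equal(cap_parameter("sports", 0), 2)
  expect_equal(cap_parameter("walk", 5000), 5000)
  expect_equal(cap_parameter("ride", 20000), 17500)
  expect_equal(cap_parameter("walk", 120), 1000)
  expect_equal(cap_parameter("walk", 99999), 10000)
  expect_equal(cap_parameter("sports", 99), 10)
  expect_error(cap_parameter("swim", 1), "unknown activity type")

  for (type in c("walk", "ride", "sports")) {
    for (v in c(0, 1, 500, 1000, 2000, 9999, 17500, 30000)) {
      once <- cap_parameter(type, v)
      expect_identical(cap_parameter(type, once), once)
    }
  }
})

test_that("the control schedule matches the guideline table and grows over waves", {
  expect_equal(unlist(control_schedule(1)), c(min_walk_distance = 1500,
                                              min_ride_distance = 3500,
                                              rewarded_sports_sessions = 4))
  expect_equal(unlist(control_schedule(3)), c(min_walk_distance = 2250,
                                              min_ride_distance = 4250,
                                              rewarded_sports_sessions = 5))
  expect_equal(unlist(control_schedule(4)), c(min_walk_distance = 2500,
                                              min_ride_distance = 4500,
                                              rewarded_sports_sessions = 5))
  expect_error(control_schedule(5), "wave out of range")

  sched <- t(sapply(1:4, function(w) unlist(control_schedule(w))))
  expect_true(all(diff(sched[, "min_walk_distance"]) > 0))
  expect_true(all(diff(sched[, "min_ride_distance"]) > 0))
  expect_true(all(diff(sched[, "rewarded_sports_sessions"]) >= 0))
})

test_that("personalized schedules compose resolution, interpolation and caps", {
  # maintenance on every dimension: parameters constant across waves
  intake <- data.frame(steps_per_day = 7000, bike_km_per_week = 10,
                       sports_sessions_per_week = 3,
                       goal_steps_per_day = 7000,
                       goal_bike_km_per_week = NA,
                       goal_sports_sessions_per_week = NA)
  walks <- sapply(1:4, function(w) {
    personalized_schedule(intake, w)$min_walk_distance
  })
  expect_equal(walks, rep(1703, 4))

  # total fallback: no intake, no history, empty population
  expect_equal(personalized_schedule(NULL, w = 4)$rewarded_sports_sessions, 3)
  expect_equal(personalized_schedule(NULL, w = 2)$min_ride_distance, 2100)

  # fallback totality across all information patterns
  hist <- data.frame(kind = "walk", magnitude = 2200, day = 2,
                     participant_id = "A")
  pop <- data.frame(kind = c("ride", "sports"), magnitude = c(6000, 45),
                    day = c(1, 1), participant_id = "B")
  for (ik in list(NULL, intake)) {
    for (hk in list(NULL, hist)) {
      for (pk in list(NULL, pop)) {
        p <- personalized_schedule(ik, w = 3, history = hk,
                                   population_history = pk)
        expect_true(p$min_walk_distance >= 1000 &
                      p$min_walk_distance <= 10000)
        expect_true(p$min_ride_distance >= 2000 &
                      p$min_ride_distance <= 17500)
        expect_true(p$rewarded_sports_sessions >= 2 &
                      p$rewarded_sports_sessions <= 10)
        expect_true(all(unlist(p) == round(unlist(p))))
      }
    }
  }
})
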