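# Fixtures and independent oracles used across the suite. Everything is
# built in code; no files are read.

# a random activity event stream for cap/reset property tests
random_event_stream <- function(n, seed, pids = c("A", "B", "C"),
                                max_day = 56L) {
  set.seed(seed)
  data.frame(
    participant_id = sample(pids, n, replace = TRUE),
    kind = sample(c("walk", "ride", "sports", "healthy_moment"), n,
                  replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
    magnitude = round(stats::runif(n, 0, 6000)),
    day = sample.int(max_day, n, replace = TRUE),
    source = "manual"
  )
}

# a flat taskset table (every participant-wave on the control schedule)
control_plan <- function(pids, config = campaign_config()) {
  do.call(rbind, lapply(seq_len(config$W), function(w) {
    cbind(data.frame(participant_id = pids, wave = w),
          control_schedule(w, config))
  }))
}

# Brute-force participation oracle: per-wave counts recomputed from the raw
# visit log with plain set operations, independently of the package's
# labeling pass. The join wave always counts as visited.
oracle_participation <- function(visits, participants, W) {
  visited_set <- function(pid) {
    jw <- participants$join_wave[participants$participant_id == pid]
    sort(unique(c(jw, visits$wave[visits$participant_id == pid &
                                    visits$visit_days > 0])))
  }
  sets <- lapply(participants$participant_id, visited_set)
  names(sets) <- participants$participant_id
  jw <- stats::setNames(participants$join_wave, participants$participant_id)
  out <- data.frame(wave = seq_len(W), visiting = 0L, new = 0L,
                    dropped = 0L, reclaimed = 0L)
  for (w in seq_len(W)) {
    here <- names(sets)[vapply(sets, function(s) w %in% s, logical(1))]
    out$visiting[w] <- length(here)
    out$new[w] <- sum(jw[here] == w)
    if (w < W) {
      out$dropped[w] <- sum(vapply(here, function(p) {
        !(w + 1) %in% sets[[p]]
      }, logical(1)))
    }
    out$reclaimed[w] <- sum(vapply(here, function(p) {
      jw[p] < w && length(setdiff(seq.int(jw[p], w - 1), sets[[p]])) > 0
    }, logical(1)))
  }
  out
}

# a small engagement-record table with fully known membership, for subset
# filter tests: `pattern` maps participant -> visited waves
records_from_patterns <- function(pattern, join_wave, arm) {
  pids <- names(pattern)
  rows <- lapply(pids, function(p) {
    waves <- seq.int(join_wave[[p]], 4L)
    data.frame(participant_id = p, wave = waves,
               relative_wave = waves - join_wave[[p]],
               visit_days = as.integer(waves %in% pattern[[p]]) * 3L,
               activities_registered = as.integer(waves %in% pattern[[p]]),
               visited = waves %in% pattern[[p]])
  })
  records <- do.call(rbind, rows)
  participants <- data.frame(participant_id = pids,
                             join_wave = unlist(join_wave)[pids],
                             arm = unlist(arm)[pids],
                             goal_type = "unknown",
                             organization_id = "O1")
  list(records = records, participants = participants)
}
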