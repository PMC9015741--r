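#!/usr/bin/env Rscript
# Stage 2 — plan dynamic-task parameters per participant and wave.
#
# Control-arm participants follow the guideline schedule; personalized-arm
# participants get parameters grown linearly from their (resolved) capability
# toward their goal, capped to the allowed ranges; everyone keeps the default
# set during their join wave. Writes results/taskplan.csv and prints the
# personalized-arm parameter spread per wave.

library(goalwave)

cohort <- read_cohort("results/cohort")

plan <- plan_tasksets(cohort$participants, cohort$intake, cohort$events)
write_table_csv(plan, "results/taskplan.csv")

pers <- cohort$participants$participant_id[
  cohort$participants$arm == "personalized"]
pp <- plan[plan$participant_id %in% pers, ]
summary_tab <- do.call(rbind, lapply(split(pp, pp$wave), function(d) {
  data.frame(
    wave = d$wave[1],
    walk_mean = round(mean(d$min_walk_distance)),
    walk_min = min(d$min_walk_distance),
    walk_max = max(d$min_walk_distance),
    ride_mean = round(mean(d$min_ride_distance)),
    sports_mean = round(mean(d$rewarded_sports_sessions), 2),
    sports_max = max(d$rewarded_sports_sessions)
  )
}))
cat("personalized-arm complexity parameters by wave:\n")
print(summary_tab, row.names = FALSE)
cat("task plan rows:", nrow(plan), "-> results/taskplan.csv\n")
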