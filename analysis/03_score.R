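#!/usr/bin/env Rscript
# Stage 3 — score the activity event log and build leaderboards.
#
# Every registered activity is matched to the best qualifying task of that
# participant's wave task set and rewarded under the weekly point and reward
# caps; individual and department-average leaderboards reset each wave.
# Writes results/awards.csv and results/leaderboards.json.

library(goalwave)

cohort <- read_cohort("results/cohort")
plan <- read_table_csv("results/taskplan.csv")

ledger <- score_events(cohort$events, plan)
write_table_csv(ledger$awards, "results/awards.csv")
write_leaderboards(ledger, cohort$participants, waves = 1:4,
                   "results/leaderboards.json")

cat("events scored:", nrow(ledger$awards), "\n")
cat("points awarded:", sum(ledger$awards$points), "\n")
cat("points by wave:\n")
print(tapply(ledger$awards$points, ledger$awards$wave, sum))
top <- leaderboards(ledger, 1, cohort$participants)$individual
cat("wave-1 individual leaderboard (top 5 overall):\n")
print(head(top[order(-top$points), ], 5), row.names = FALSE)
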