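Package: goalwave
Title: Adaptive Goal Setting, Gamified Scoring, and Engagement Analysis
    for Wave-Based mHealth Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the intervention engine and engagement-analysis
    pipeline of a wave-based, gamified mobile-health campaign promoting
    walks, bike rides, and sports sessions. Task-complexity parameters
    (minimum walk and ride distances, rewarded sports-session frequency)
    are personalized from self-reported capabilities and goals and grown
    linearly toward the goal across campaign waves, or set from a generic
    guideline schedule for the control arm. Registered activities are
    scored under per-task point rules with weekly reward caps, feeding
    individual and department-average leaderboards that reset each wave.
    Joining participants are allocated to arms by goal-type-stratified
    minimization. A synthetic-cohort generator emulates the trial's
    engagement structure (linear mixed models with random intercepts for
    participants and organizations, a time-increasing dropout process),
    and the analysis layer reproduces dropout labeling and regression,
    hierarchical engagement models with information-criterion selection,
    per-activity-type models, and posttest linear models with backward
    elimination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
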