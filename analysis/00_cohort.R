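# Shared cohort definition for the analysis scripts.
#
# Six synthetic cows on the default study conditions: five with a
# rise-then-decline R-R trend whose turning offset spreads across the
# 40-76 h range the indicators are expected to cover, and one
# monotone-decline cow (the regime in which RSI never signals). Sourced by
# the numbered drivers; not a script itself.

library(calvetrend)

cohort_specs <- function() {
  list(
    s021 = synthetic_spec(turning_offset = 54, seed = 210),
    s045 = synthetic_spec(turning_offset = 72, seed = 450),
    s057 = synthetic_spec(turning_offset = 62, baseline_rr = 580, seed = 570),
    s058 = synthetic_spec(turning_offset = 43, baseline_rr = 590, seed = 580),
    s886 = synthetic_spec(turning_offset = 48, artifact_fraction = 0.04,
                          seed = 886),
    s055 = spec_monotone_decline(seed = 550)
  )
}

paths <- list(
  scratch = "scratch/cohort",   # beat-level intermediates (large)
  results = "results"           # small summary tables
)
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)
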