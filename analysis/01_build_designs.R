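#!/usr/bin/env Rscript
# Stimulus designs, association statistics, and the sample-size planning
# computation. Everything here is deterministic design arithmetic: the
# omitted-range session (600 trials), the three frequency-manipulated
# sessions (1,588 / 1,584 / 1,588 trials), the proportion-smaller table that
# the association account predicts behavior from, and the noncentral-F
# power analysis for a three-group ANOVA at f = 0.64.

suppressPackageStartupMessages(library(numsize))
dir.create("results", showWarnings = FALSE)

designs <- list(
  study1 = build_study1_design(repeats = 20L),
  everyday = build_trial_templates(build_frequency_table("everyday"), 2L),
  uniform = build_trial_templates(build_frequency_table("uniform"), 22L),
  reversed_everyday = build_trial_templates(
    build_frequency_table("reversed_everyday"), 2L))

counts <- data.frame(
  design = names(designs),
  n_values = vapply(designs, function(d) length(d$values), 0L),
  n_templates = vapply(designs, function(d) nrow(d$templates), 0L),
  total_trials = vapply(designs, function(d) d$total_trials, 0L))
write.csv(counts, "results/design_counts.csv", row.names = FALSE)
cat("Design totals:\n"); print(counts, row.names = FALSE)

ev <- designs$everyday$templates
cat(sprintf("\nMost frequent ordered pair (5 vs 10): %d presentations\n",
            ev$multiplicity[ev$left_value == 5 & ev$right_value == 10]))
cat(sprintf("Least frequent ordered pair (40 vs 45): %d presentations\n",
            ev$multiplicity[ev$left_value == 40 & ev$right_value == 45]))

assoc <- association_statistics(designs$study1)
write.csv(assoc, "results/association_statistics.csv", row.names = FALSE)
cat("\nAssociation statistics of the omitted-range design",
    "(proportion of trials in which each value is the smaller member):\n")
print(assoc, row.names = FALSE)

# a dot-array geometry sanity check: 45 non-overlapping dots in the 2-degree
# field, half black / half white
arr <- generate_dot_array(45, seed = 1)
cat(sprintf("\nDot array: %d dots placed, min pairwise distance %.3f deg\n",
            arr$n_dots, min(dist(arr$positions))))

pw <- required_n_oneway_anova(f = 0.64, alpha = 0.05, power = 0.95,
                              k_groups = 3)
jsonlite::write_json(pw, "results/power_analysis.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("\nPower analysis: f = 0.64, alpha = .05, 3 groups -> N = %d",
            pw$n_total),
    sprintf("(achieved power %.3f)\n", pw$power))
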