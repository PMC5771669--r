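#!/usr/bin/env Rscript
# Generate the synthetic cohorts every downstream analysis consumes:
# FLIP traces, per-cell circle segregation outcomes, anaphase timelines and
# nuclear-rim profiles. All tables land under results/data/ with their seed
# recorded in the header.

suppressPackageStartupMessages(library(nucbarrier))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

# FLIP cohorts: the exchange rate across the bud neck encodes barrier
# strength (lower = tighter barrier); one cohort per growth condition
flip_conditions <- list(
  calorie_restricted = 0.001,   # strengthened barrier
  optimal            = 0.002,   # wild-type-like
  heat               = 0.0035,  # weakened barrier
  barrier_mutant     = 0.02     # strong barrier defect
)
for (cond in names(flip_conditions)) {
  cfg <- flip_sim_config(n_cells = 30, exchange_rate = flip_conditions[[cond]],
                         seed = 100 + match(cond, names(flip_conditions)))
  write_pipeline_csv(gen_flip_traces(cfg),
                     file.path("results/data", paste0("flip_", cond, ".csv")))
}

# segregation cohorts: per-circle bud-passage probabilities in the regime of
# the imaging assay (low under optimal growth, elevated under heat)
seg_conditions <- c(optimal = 0.04, heat = 0.17, barrier_mutant = 0.13)
for (cond in names(seg_conditions)) {
  cfg <- segregation_sim_config(n_cells = 300, p_pass = seg_conditions[[cond]],
                                n_experiments = 3,
                                seed = 200 + match(cond, names(seg_conditions)))
  write_pipeline_csv(gen_circle_observations(cfg),
                     file.path("results/data", paste0("circle_obs_", cond, ".csv")))
}

# anaphase timelines: early/late stage durations with stage-specific
# passage hazards (early-anaphase passages dominate)
tl_conditions <- list(
  optimal = list(early = 3.9, late = 14.5, h_early = 0.03, h_late = 0.004),
  heat    = list(early = 3.4, late = 12.9, h_early = 0.06, h_late = 0.004)
)
for (cond in names(tl_conditions)) {
  p <- tl_conditions[[cond]]
  cfg <- timeline_sim_config(n_cells = 300, early_mean = p$early,
                             late_mean = p$late, hazard_early = p$h_early,
                             hazard_late = p$h_late,
                             seed = 300 + match(cond, names(tl_conditions)))
  write_pipeline_csv(gen_timelines(cfg),
                     file.path("results/data", paste0("timelines_", cond, ".csv")))
}

# rim profiles: circles attached to NPC punctae vs detached
rim_conditions <- c(attached = 1, detached = 0)
for (cond in names(rim_conditions)) {
  cfg <- rim_sim_config(n_cells = 60, p_attached = rim_conditions[[cond]],
                        seed = 400 + match(cond, names(rim_conditions)))
  write_pipeline_csv(gen_rim_profiles(cfg),
                     file.path("results/data", paste0("rim_", cond, ".csv")))
}

cat("wrote", length(list.files("results/data")), "tables to results/data/\n")
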