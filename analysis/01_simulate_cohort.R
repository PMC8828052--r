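#!/usr/bin/env Rscript
# Simulate the study cohort: 2,000 subjects across 10 unequally sized sites
# spanning ages 2-100, 20 ROIs (16 thickness-like, 4 volume-like), SHASH
# noise, two planted clinical groups, and per-subject Euler characteristics
# with 5% planted low-quality scans. Writes the demographic + ROI tables that
# every later stage reads back through the package's ingest path.

library(neuronorm)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg0 <- default_sim_config(2000L, 20L, 10L, seed = seed)
cfg <- simulation_config(
  n_subjects = cfg0$n_subjects,
  site_sizes = setNames(cfg0$site_sizes, cfg0$site_ids),
  age_range = cfg0$age_range, trajectory_params = cfg0$trajectory_params,
  sex_offset = cfg0$sex_offset, site_offsets = cfg0$site_offsets,
  site_scales = cfg0$site_scales, noise_params = cfg0$noise_params,
  clinical_effects = default_clinical_effects(cfg0$trajectory_params$roi),
  seed = seed
)
cohort <- simulate_clinical_groups(cfg)
cohort <- simulate_euler_numbers(cohort, outlier_fraction = 0.05,
                                 seed = seed + 11L)

write_cohort(cohort, file.path(out, "demographics.csv"),
             file.path(out, "roi_measures.csv"))
jsonlite::write_json(list(seed = seed, config_hash = config_hash(cfg)),
                     file.path(out, "simulation_manifest.json"),
                     auto_unbox = TRUE)

cat(sprintf("cohort: %d subjects (%d controls), %d ROIs, %d sites\n",
            nrow(cohort), sum(cohort$group == "control"),
            length(roi_names(cohort)), length(unique(cohort$site))))
cat(sprintf("planted low-quality scans: %d (%.1f%%)\n",
            sum(cohort$ec_outlier), 100 * mean(cohort$ec_outlier)))
cat("wrote", out, "\n")
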