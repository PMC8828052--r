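# Small in-code fixtures shared across tests.

tiny_cohort <- function(n = 300, n_rois = 3, n_sites = 3, seed = 11,
                        noise_params = list(a = 0.1, b = 1.05, base_scale = 0.12)) {
  simulate_reference_cohort(
    default_sim_config(n, n_rois, n_sites, seed = seed,
                       noise_params = noise_params)
  )
}

# Gaussian-noise cohort (identity-warp ground truth).
gaussian_cohort <- function(n = 400, n_rois = 2, n_sites = 3, seed = 5) {
  tiny_cohort(n, n_rois, n_sites, seed,
              noise_params = list(a = 0, b = 1, base_scale = 0.12))
}

quick_bundle <- function(cohort, ...) {
  fit_normative_models(cohort, n_restarts = 0, ...)
}

# hand-built cohort over an explicit age/sex/site grid
grid_cohort <- function(ages, sexes = 0, sites = "A") {
  n <- length(ages)
  df <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), age = ages,
    sex = rep_len(sexes, n), site = rep_len(sites, n), group = "control",
    roi1 = 0
  )
  cohort_table(df, "roi1")
}
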