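#' Default clinical group definitions for the synthetic cohort
#'
#' Two illustrative transdiagnostic groups: a focal-thinning group (negative
#' shift confined to a small ROI subset, present in a fraction of subjects —
#' clinical effects are heterogeneous) and a focal-thickening group.
#'
#' @param rois Character vector of ROI names to draw affected subsets from.
#' @return A named list usable as `clinical_effects` in
#'   [simulation_config()].
#' @export
default_clinical_effects <- function(rois) {
  n <- length(rois)
  list(
    thin_focal = list(rois = rois[seq_len(min(5L, n))],
                      shift = -1.5, prevalence = 0.6, n = 150L),
    thick_focal = list(rois = rois[seq(min(6L, n), min(8L, n))],
                       shift = 1.0, prevalence = 0.5, n = 100L)
  )
}

write_csv_out <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Run the full normative-modeling pipeline on a synthetic cohort
#'
#' simulate -> QC -> site-stratified split -> per-ROI warped BLR fits ->
#' deviation maps -> evaluation -> clinical summary, writing every stage's
#' table under `out_dir`. Fully deterministic given `seed`: re-running with
#' the same arguments produces byte-identical outputs. Every output directory
#' carries a manifest with the configuration hash.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_subjects,n_rois,n_sites Cohort dimensions (see
#'   [default_sim_config()]).
#' @param ec_outlier_fraction Fraction of planted low-quality scans per site.
#' @param sex_stratified Additionally fit separate male/female model bundles
#'   (sensitivity analysis); writes one bundle per sex.
#' @param n_restarts Restarts per ROI fit (see [fit_roi()]).
#' @return Invisibly, a list with the in-memory objects of every stage and
#'   the written file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_subjects = 2000L,
                         n_rois = 20L, n_sites = 10L,
                         ec_outlier_fraction = 0.03,
                         sex_stratified = FALSE, n_restarts = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # 1. simulate reference + clinical cohort with EC, through the real I/O path
  config <- default_sim_config(n_subjects, n_rois, n_sites, seed = seed)
  config <- simulation_config(
    n_subjects = config$n_subjects,
    site_sizes = setNames(config$site_sizes, config$site_ids),
    age_range = config$age_range,
    trajectory_params = config$trajectory_params,
    sex_offset = config$sex_offset,
    site_offsets = config$site_offsets,
    site_scales = config$site_scales,
    noise_params = config$noise_params,
    clinical_effects = default_clinical_effects(config$trajectory_params$roi),
    seed = config$seed
  )
  cohort <- simulate_clinical_groups(config)
  cohort <- simulate_euler_numbers(cohort,
                                   outlier_fraction = ec_outlier_fraction,
                                   seed = derive_seed(seed, "ec"))
  demo_path <- file.path(out_dir, "demographics.csv")
  roi_path <- file.path(out_dir, "roi_measures.csv")
  write_cohort(cohort, demo_path, roi_path)
  cohort <- read_cohort(roi_path, demo_path)
  paths$cohort <- c(demo_path, roi_path)

  # 2. automated EC quality control
  qc <- euler_qc(cohort)
  paths$qc <- write_csv_out(qc, file.path(out_dir, "qc_report.csv"))
  cohort <- cohort_subset(cohort, which(qc$include[match(cohort$subject_id,
                                                         qc$subject_id)]))

  # 3. site-stratified split of the controls; clinical groups are test-only
  is_control <- cohort$group == "control"
  controls <- cohort_subset(cohort, which(is_control))
  clin <- if (any(!is_control)) cohort_subset(cohort, which(!is_control)) else NULL
  split <- split_train_test(controls, seed = derive_seed(seed, "split"))

  # 4. per-ROI warped BLR fits
  bundle <- fit_normative_models(split$train, n_restarts = n_restarts,
                                 seed = derive_seed(seed, "fit"))
  paths$model <- file.path(out_dir, "model_bundle.json")
  write_model(bundle, paths$model)
  if (sex_stratified) {
    for (sx in c(0, 1)) {
      sub <- cohort_subset(split$train, which(split$train$sex == sx))
      bsx <- fit_normative_models(sub, n_restarts = n_restarts,
                                  seed = derive_seed(seed, paste0("fit-sex", sx)))
      psx <- file.path(out_dir, sprintf("model_bundle_sex%d.json", sx))
      write_model(bsx, psx)
      paths$model <- c(paths$model, psx)
    }
  }

  # 5. deviations on the test half plus clinical groups
  test_all <- if (is.null(clin)) split$test else {
    cohort_table(rbind(as.data.frame(split$test), as.data.frame(clin)),
                 roi_names(cohort), provenance = attr(cohort, "provenance"))
  }
  dev <- deviation_map(bundle, test_all)
  dev_df <- data.frame(subject_id = rownames(dev),
                       group = test_all$group,
                       site = test_all$site,
                       as.data.frame(unclass(dev)), check.names = FALSE)
  paths$deviations <- write_csv_out(dev_df, file.path(out_dir, "deviations.csv"))

  # 6. evaluation on held-out controls
  eval_report <- evaluation_report(bundle, split$train, split$test)
  paths$evaluation <- write_csv_out(eval_report,
                                    file.path(out_dir, "evaluation.csv"))

  # 7. centile chart for the first ROI
  ages <- seq(config$age_range[1], config$age_range[2], length.out = 100)
  cent <- centile_curves(bundle$models[[1L]], ages, sex = 0,
                         site = bundle$models[[1L]]$design_spec$reference_site)
  paths$centiles <- write_csv_out(cent, file.path(out_dir, "centiles.csv"))

  # 8. transdiagnostic clinical summary
  summary_df <- NULL
  if (!is.null(clin)) {
    summary_df <- clinical_summary(dev, test_all)
    paths$clinical <- write_csv_out(summary_df,
                                    file.path(out_dir, "clinical_summary.csv"))
  }

  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    n_subjects = n_subjects, n_rois = n_rois, n_sites = n_sites,
    package_version = as.character(utils::packageVersion("neuronorm")),
    outputs = basename(unlist(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, cohort = cohort, qc = qc, split = split,
                 bundle = bundle, deviations = dev, evaluation = eval_report,
                 clinical = summary_df, paths = paths))
}
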