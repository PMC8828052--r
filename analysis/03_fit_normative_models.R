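#!/usr/bin/env Rscript
# Fit the reference models: QC-filter, site-stratified split of the controls,
# then one warped Bayesian linear regression per ROI (cubic B-spline age
# basis, sex offset, fixed site effects; SHASH likelihood warp; type-II ML by
# L-BFGS with restarts). Serializes the fitted bundle.

library(neuronorm)

seed <- 1L
cohort <- read_cohort("results/data/roi_measures.csv",
                      "results/data/demographics.csv")
qc <- read.csv("results/qc_report.csv")
cohort <- cohort_subset(cohort,
                        qc$include[match(cohort$subject_id, qc$subject_id)])
controls <- cohort_subset(cohort, cohort$group == "control")
split <- split_train_test(controls, fraction = 0.5, seed = seed + 23L)
bundle <- fit_normative_models(split$train, n_restarts = 1L, seed = seed + 31L)
write_model(bundle, "results/model_bundle.json")
write.csv(data.frame(subject_id = c(split$train$subject_id,
                                    split$test$subject_id),
                     half = rep(c("train", "test"),
                                c(nrow(split$train), nrow(split$test)))),
          "results/split_assignment.csv", row.names = FALSE)

warps <- t(vapply(bundle$models, function(m) {
  c(a = m$hyper$warp$a, b = m$hyper$warp$b, beta = m$hyper$beta)
}, numeric(3)))
cat(sprintf("fitted %d ROI models on %d training subjects\n",
            length(bundle$models), nrow(split$train)))
cat(sprintf("warp skew a in [%.2f, %.2f]; tailweight b in [%.2f, %.2f]\n",
            min(warps[, "a"]), max(warps[, "a"]),
            min(warps[, "b"]), max(warps[, "b"])))
cat(sprintf("all converged: %s\n",
            all(vapply(bundle$models,
                       function(m) m$fit_report$converged, logical(1)))))
cat("wrote results/model_bundle.json, results/split_assignment.csv\n")
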