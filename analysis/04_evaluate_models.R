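#!/usr/bin/env Rscript
# Evaluate the fitted reference models out of sample: per-ROI explained
# variance, MSLL against the training baseline, skew and excess kurtosis of
# the held-out deviation scores; stability of the metrics over 10 random
# resamples of the test half; deviation maps for the whole test set; and a
# centile chart for one example ROI.

library(neuronorm)

cohort <- read_cohort("results/data/roi_measures.csv",
                      "results/data/demographics.csv")
qc <- read.csv("results/qc_report.csv")
cohort <- cohort_subset(cohort,
                        qc$include[match(cohort$subject_id, qc$subject_id)])
split_tab <- read.csv("results/split_assignment.csv")
bundle <- read_model("results/model_bundle.json")
train <- cohort_subset(cohort, cohort$subject_id %in%
                         split_tab$subject_id[split_tab$half == "train"])
test <- cohort_subset(cohort, cohort$subject_id %in%
                        split_tab$subject_id[split_tab$half == "test"])

report <- suppressWarnings(evaluation_report(bundle, train, test))
write.csv(report, "results/evaluation.csv", row.names = FALSE)
cat(sprintf("explained variance: median %.3f (range %.3f-%.3f)\n",
            median(report$explained_variance),
            min(report$explained_variance), max(report$explained_variance)))
cat(sprintf("MSLL: median %.3f (all negative: %s)\n",
            median(report$msll), all(report$msll < 0)))
cat(sprintf("deviation shape: |skew| median %.3f, |excess kurtosis| median %.3f\n",
            median(abs(report$skew)), median(abs(report$excess_kurtosis))))

controls <- cohort_subset(cohort, cohort$group == "control")
stab <- suppressWarnings(
  resampled_evaluation(controls, n_replicates = 10L, seed = 24L,
                       n_restarts = 1L)
)
write.csv(stab, "results/evaluation_resampled.csv", row.names = FALSE)
sds <- aggregate(explained_variance ~ roi, stab, sd)
cat(sprintf("metric stability over 10 test resamples: max SD(EV) = %.4f\n",
            max(sds$explained_variance)))

dev <- suppressWarnings(deviation_map(bundle, test))
write.csv(data.frame(subject_id = rownames(dev), as.data.frame(unclass(dev)),
                     check.names = FALSE),
          "results/deviations_test.csv", row.names = FALSE)

roi1 <- bundle$models[[1L]]
ages <- seq(roi1$design_spec$age_min, roi1$design_spec$age_max,
            length.out = 200)
cent <- rbind(
  centile_curves(roi1, ages, sex = 0, site = roi1$design_spec$reference_site),
  centile_curves(roi1, ages, sex = 1, site = roi1$design_spec$reference_site)
)
write.csv(cent, "results/centiles_example_roi.csv", row.names = FALSE)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  obs <- data.frame(age = test$age, value = roi_matrix(test)[, 1])
  p <- plot_centiles(cent[cent$sex == 0, ], observed = obs)
  ggplot2::ggsave("results/figures/centiles_example_roi.pdf", p,
                  width = 7, height = 5)
}
cat("wrote results/evaluation*.csv, results/deviations_test.csv, centile chart\n")
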