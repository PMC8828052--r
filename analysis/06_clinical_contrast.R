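#!/usr/bin/env Rscript
# Transdiagnostic clinical summary: score the clinical groups against the
# reference models, map the percentage of subjects with extreme deviations
# (|Z| > 2) per ROI versus same-site controls, and run mass-univariate Welch
# tests (BH-FDR corrected) on both the raw measures and the deviation scores.

library(neuronorm)

cohort <- read_cohort("results/data/roi_measures.csv",
                      "results/data/demographics.csv")
qc <- read.csv("results/qc_report.csv")
cohort <- cohort_subset(cohort,
                        qc$include[match(cohort$subject_id, qc$subject_id)])
split_tab <- read.csv("results/split_assignment.csv")
bundle <- read_model("results/model_bundle.json")

test_controls <- cohort_subset(
  cohort, cohort$subject_id %in%
    split_tab$subject_id[split_tab$half == "test"]
)
clinical <- cohort_subset(cohort, cohort$group != "control")
test_all <- cohort_table(
  rbind(as.data.frame(test_controls), as.data.frame(clinical)),
  roi_names(cohort)
)
dev <- suppressWarnings(deviation_map(bundle, test_all))
summ <- clinical_summary(dev, test_all)
write.csv(summ, "results/clinical_summary.csv", row.names = FALSE)

for (g in unique(summ$group)) {
  sg <- summ[summ$group == g, ]
  top <- sg[order(-pmax(sg$pct_negative_extreme, sg$pct_positive_extreme)), ]
  cat(sprintf("\ngroup %s (n = %d, matched controls n = %d):\n",
              g, sg$group_n[1], sg$control_n[1]))
  cat(sprintf("  most affected ROI: %s (%.1f%% neg-extreme vs %.1f%% in controls)\n",
              top$roi[1], top$pct_negative_extreme[1],
              top$ctrl_pct_negative_extreme[1]))
  cat(sprintf("  FDR-significant ROIs: %d on deviations, %d on raw measures\n",
              sum(sg$sig_dev, na.rm = TRUE), sum(sg$sig_raw, na.rm = TRUE)))
}
cat("\nwrote results/clinical_summary.csv\n")
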