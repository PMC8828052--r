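#!/usr/bin/env Rscript
# Automated QC from the Freesurfer Euler characteristic: per-site robust
# standardization of the mean EC and a conservative one-sided exclusion at
# 5 robust-SD units. Compares decisions against the generator's planted
# ground truth.

library(neuronorm)

cohort <- read_cohort("results/data/roi_measures.csv",
                      "results/data/demographics.csv")
qc <- euler_qc(cohort, robust = TRUE, threshold = 5)
write.csv(qc, "results/qc_report.csv", row.names = FALSE)

truth <- cohort$ec_outlier[match(qc$subject_id, cohort$subject_id)]
cat(sprintf("excluded %d of %d subjects (%.2f%%)\n",
            sum(!qc$include), nrow(qc), 100 * mean(!qc$include)))
cat(sprintf("sensitivity vs planted outliers: %.3f; false exclusions: %.4f\n",
            mean(!qc$include[truth]), mean(!qc$include[!truth])))
cat("wrote results/qc_report.csv\n")
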