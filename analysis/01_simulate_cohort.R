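#!/usr/bin/env Rscript
# Simulate the emulated plasma MALDI cohort: 90 case + 90 control patients,
# quintuplicate spectra, 1,752 nominal m/z channels (250-2001), five planted
# marker channels at a 3-sigma case shift and ten planted dependency groups
# (20 dependent member channels). Writes the feature table and the planted
# ground truth under results/.

library(maldimarkers)

seed <- 1L
spec <- synthetic_spec()
coh <- generate_cohort(spec, seed = seed)

dir.create("results", showWarnings = FALSE)
write_feature_table(coh$matrix, "results/cohort_features.csv")
write_truth(coh$truth, "results/cohort_truth.json")
write.csv(coh$subjects, "results/cohort_subjects.csv", row.names = FALSE)

print(coh$matrix)
cat(sprintf("subjects: %d case (BMI %.1f +/- %.1f), %d control (BMI %.1f +/- %.1f)\n",
            sum(coh$subjects$class == "case"),
            mean(coh$subjects$bmi[coh$subjects$class == "case"]),
            sd(coh$subjects$bmi[coh$subjects$class == "case"]),
            sum(coh$subjects$class == "control"),
            mean(coh$subjects$bmi[coh$subjects$class == "control"]),
            sd(coh$subjects$bmi[coh$subjects$class == "control"])))
cat("planted marker channels:",
    paste(coh$truth$marker_channels$mz, collapse = ", "), "\n")
cat("planted dependent members:",
    paste(coh$truth$dependent_groups$member_mz, collapse = ", "), "\n")
cat("wrote results/cohort_features.csv, cohort_truth.json, cohort_subjects.csv\n")
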