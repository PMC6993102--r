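#!/usr/bin/env Rscript
# Normalize the cohort and eliminate linearly dependent channels by
# Gauss-Jordan elimination (fit-partition rows only, so test vectors never
# shape the feature space). With far more channels (1,752) than fit vectors
# (820) the column rank is bounded by the row count, so beyond the 20 planted
# dependent members a large block of incidentally rank-deficient channels is
# eliminated as well -- the same regime as any spectra-wide table with more
# channels than spectra.

library(maldimarkers)

seed <- 1L
x <- read_feature_table("results/cohort_features.csv")
truth <- jsonlite::read_json("results/cohort_truth.json",
                             simplifyVector = TRUE)

x <- normalize_rows(x)
pt <- patient_table(x)
plan <- split_fit_test(pt$patient, pt$class, test_fraction = 0.2, seed = seed)
fit_rows <- rows_for_patients(x, unlist(plan$fit))

red <- find_dependent_groups(x, pivot_tolerance = 1e-8, rows = fit_rows)
print(red)

removed <- setdiff(x$mz, red$representatives)
planted <- truth$dependent_groups$member_mz
cat(sprintf("planted dependent members removed: %d of %d\n",
            sum(planted %in% removed), length(planted)))
cat(sprintf("incidental (rank-bound) eliminations: %d\n",
            length(removed) - sum(planted %in% removed)))

write_reduction(red, "results/reduction.json")
cat("wrote results/reduction.json\n")
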