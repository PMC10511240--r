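#!/usr/bin/env Rscript
# Plate-reader reporter analysis: blank-subtract and per-cell normalise
# the fluorescence table, compute fold induction under Pi starvation and
# run the group comparisons with the star coding of the figure
# annotations.

suppressPackageStartupMessages(library(ippdyn))
dir.create("results", showWarnings = FALSE)

pf <- generate_plate_fixture(seed = 1, induction_fold = 8)
norm <- normalize_plate(pf$records, pf$blanks)
print(norm[, c("well", "condition", "fluorescence", "norm_fluor")], digits = 3)

fold <- induction_ratio(norm$norm_fluor[norm$condition == "starved"],
                        norm$norm_fluor[norm$condition == "replete"])
message(sprintf("Fold induction (-Pi / +Pi): %.2f (generator truth %.0f)",
                fold, pf$truth$induction_fold))

tests <- rbind(
  cbind(method = "student_t",
        compare_groups(split(norm$norm_fluor, norm$condition), "student_t")),
  cbind(method = "mann_whitney",
        compare_groups(split(norm$norm_fluor, norm$condition), "mann_whitney"))
)
message("Condition comparisons:")
print(tests, digits = 3)

write.csv(norm, "results/plate_normalized.csv", row.names = FALSE)
write.csv(tests, "results/plate_tests.csv", row.names = FALSE)
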