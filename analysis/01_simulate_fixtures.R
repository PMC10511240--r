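#!/usr/bin/env Rscript
# Generate every synthetic fixture the downstream analyses consume:
# MRM peak tables for the replete strain panel and the wild-type
# starvation time course, two microscopy fields (replete / starved), the
# paired decay-relocation time course and a plate-reader table. All
# ground truths are saved alongside.

suppressPackageStartupMessages(library(ippdyn))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("MRM fixtures (noise-free worked examples + noisy replicates) ...")
write_ms_fixture(generate_ms_fixture(canned_scenario("mutants_replete")),
                 out, "mutants_replete")
write_ms_fixture(generate_ms_fixture(canned_scenario("wt_starvation")),
                 out, "wt_starvation")
write_ms_fixture(generate_ms_fixture(canned_scenario("wt_starvation_noisy")),
                 out, "wt_starvation_noisy")

message("Microscopy fields (replete vs starved reporter distribution) ...")
for (cond in c("replete", "starved")) {
  fix <- generate_image_fixture(canned_field_spec(cond, seed = 7))
  write_image_fixture(fix, out, paste0("field_", cond))
}

message("Relocation time course and plate table ...")
tc <- generate_relocation_timecourse(seed = 1, conc_noise_sd = 0.3,
                                     ratio_noise_sd = 0.05)
write.csv(tc$concentration, file.path(out, "conc_timecourse.csv"),
          row.names = FALSE)
write.csv(tc$relocation, file.path(out, "relocation_timecourse.csv"),
          row.names = FALSE)
pf <- generate_plate_fixture(seed = 1)
write.csv(rbind(pf$records, pf$blanks), file.path(out, "plate.csv"),
          row.names = FALSE)

message("done; fixtures under ", out)
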