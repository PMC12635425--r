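#!/usr/bin/env Rscript
# Step 1: generate the study cohort.
#
# Simulates 24 patients (14/24 latent TP-resistant, the evaluable cohort
# composition the screen was validated on), each with a preliminary Cmax
# plate over the ten-drug panel and a secondary six-point fourfold titration
# of the selected candidates plus the TP pair; triplicate wells, lognormal
# signal noise CV 0.08, clinical labels faithful to the latent class.
# Writes the plate tables, clinical records and the generative truth.

library(grscreen)

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

reg <- load_registry("table2")
co <- simulate_cohort(sim_cohort(n_patients = 24), reg,
                      sim_design("SECONDARY", noise_cv = 0.08), seed = seed)

write_screen_csv(co$preliminary, file.path(out_dir, "preliminary_wells.csv"))
write_screen_csv(co$secondary, file.path(out_dir, "secondary_wells.csv"))
write.csv(co$clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
write.csv(co$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

cat(sprintf(
  "simulated %d patients (seed %d): %d latent-resistant, %d NAT-group\n",
  nrow(co$truth), seed, sum(co$truth$latent_class == "RESISTANT"),
  sum(co$clinical$group == "NAT")))
cat(sprintf("preliminary wells: %d, secondary wells: %d\n",
            nrow(co$preliminary$wells), nrow(co$secondary$wells)))
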