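#!/usr/bin/env Rscript
# Step 2: preliminary screen at Cmax.
#
# Computes endpoint viability (treated/NC ATP ratio) per organoid and drug
# and applies the selection rule: viability <= 20%, keep the three strongest
# inhibitors, always carry paclitaxel + cisplatin forward.

library(grscreen)

reg <- load_registry("table2")
prelim <- read_screen_csv("results/preliminary_wells.csv", "PRELIMINARY", reg)

organoids <- sort(unique(prelim$wells$organoid_id))
viab <- list(); cand <- list()
for (org in organoids) {
  prof <- compute_viability(prelim, org)
  cs <- select_candidates(prof)
  viab[[org]] <- cbind(organoid_id = org, as.data.frame(prof))
  cand[[org]] <- data.frame(
    organoid_id = org,
    candidates = paste(cs$candidates, collapse = ";"),
    secondary_panel = paste(cs$secondary_panel, collapse = ";"),
    flags = paste(cs$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
viab <- do.call(rbind, viab)
cand <- do.call(rbind, cand)
write.csv(viab, "results/preliminary_viability.csv", row.names = FALSE)
write.csv(cand, "results/candidates.csv", row.names = FALSE)

cat(sprintf("profiled %d organoids over %d drugs\n",
            length(organoids), length(unique(viab$drug))))
n_cand <- lengths(strsplit(cand$candidates, ";"))
n_cand[cand$candidates == ""] <- 0L
cat(sprintf("candidates per organoid: median %d (range %d-%d); %d organoid(s) with none\n",
            median(n_cand), min(n_cand), max(n_cand), sum(n_cand == 0)))
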