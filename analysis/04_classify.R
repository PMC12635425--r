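#!/usr/bin/env Rscript
# Step 4: response calls.
#
# AUCsum chemoresistance call at the 1.134 operating point, the per-drug
# GR100/GRmax/Cmax decision tree, and the Cmax/GR100 alternative-therapy
# ranking per organoid.

library(grscreen)

reg <- load_registry("table2")
cfg <- classifier_config()  # aucsum_threshold 1.134, grmax_cutoff -0.5
metrics <- read.csv("results/gr_metrics.csv", stringsAsFactors = FALSE)
metrics$flags[is.na(metrics$flags)] <- ""
class(metrics) <- c("drug_response_summary", "data.frame")
scores <- read.csv("results/aucsum.csv", stringsAsFactors = FALSE)

calls <- metrics[, c("organoid_id", "drug", "grmax", "gr100",
                     "cmax_over_gr100")]
calls$call <- vapply(seq_len(nrow(metrics)), function(i) {
  classify_drug(metrics[i, ], registry_drug(reg, metrics$drug[i]), cfg)$label
}, character(1))

patients <- do.call(rbind, lapply(split(metrics, metrics$organoid_id),
                                  function(sm) {
  r <- rank_alternatives(sm)
  s <- scores$auc_sum[scores$organoid_id == sm$organoid_id[1]]
  data.frame(organoid_id = sm$organoid_id[1],
             auc_sum = s,
             aucsum_class = classify_aucsum(s, cfg),
             recommended_drug = r$recommendation,
             recommended_index = r$ranking$cmax_over_gr100[1],
             ranking_flags = paste(r$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}))
rownames(patients) <- NULL

write.csv(calls, "results/drug_calls.csv", row.names = FALSE)
write.csv(patients, "results/patient_calls.csv", row.names = FALSE)

cat(sprintf("drug calls: %s\n",
            paste(sprintf("%s %d", names(table(calls$call)),
                          table(calls$call)), collapse = ", ")))
n_res <- sum(patients$aucsum_class == "PREDICTED_RESISTANT")
cat(sprintf("%d/%d organoids predicted TP-resistant at AUCsum > %.3f\n",
            n_res, nrow(patients), cfg$aucsum_threshold))
if (n_res > 0) {
  top <- patients[patients$aucsum_class == "PREDICTED_RESISTANT", ]
  cat(sprintf("alternative for resistant organoids: %s (Cmax/GR100 up to %.1f)\n",
              paste(unique(top$recommended_drug), collapse = ", "),
              max(top$recommended_index)))
}
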