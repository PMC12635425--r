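#!/usr/bin/env Rscript
# Step 5: concordance of the organoid DST calls with clinical response.
#
# Confusion-matrix statistics (positive class: clinically GOOD responder
# predicted sensitive), ROC AUC of the continuous AUCsum, and the
# Youden-optimal AUCsum threshold for this cohort, compared against the
# default 1.134 operating point.

library(grscreen)
library(jsonlite)

patients <- read.csv("results/patient_calls.csv", stringsAsFactors = FALSE)
clinical <- read.csv("results/clinical.csv", stringsAsFactors = FALSE)

pred <- data.frame(patient_id = patients$organoid_id,
                   predicted = patients$aucsum_class,
                   stringsAsFactors = FALSE)
cr <- concordance_stats(pred, clinical)
print(cr)

obs <- clinical_response(clinical)
ord <- match(clinical$patient_id, patients$organoid_id)
auc <- roc_auc(patients$auc_sum[ord], obs)
yt <- youden_threshold(patients$auc_sum[ord], obs)
cat(sprintf("ROC AUC of AUCsum: %.3f\n", auc))
cat(sprintf("Youden-optimal AUCsum threshold for this cohort: %.3f (J = %.2f)\n",
            yt$threshold, yt$j))
cat("default operating point: 1.134\n")

write_json(list(
  confusion = list(tp = cr$tp, fn = cr$fn, tn = cr$tn, fp = cr$fp),
  sensitivity = cr$sensitivity, specificity = cr$specificity,
  accuracy = cr$accuracy, roc_auc = auc,
  youden_threshold = yt$threshold,
  n_evaluable = cr$n_evaluable, n_excluded = cr$n_excluded
), "results/concordance.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/concordance.json\n")
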