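# Concordance of organoid drug-sensitivity calls with clinical response:
# histological grade mapping, confusion-matrix statistics, ROC AUC and
# Youden threshold selection.

#' Map a JSED histological grade to a binary response
#'
#' Japanese Society for Esophageal Disease grades 2 ("moderately effective")
#' and 3 ("markedly effective") define a GOOD response to neoadjuvant
#' chemotherapy; grades 0, 1a and 1b define a POOR response.
#'
#' @param grade one of `"G0"`, `"G1a"`, `"G1b"`, `"G2"`, `"G3"` (vectorised).
#' @return `"GOOD"` or `"POOR"` per element.
#' @export
jsed_to_binary <- function(grade) {
  valid <- c(G0 = "POOR", G1a = "POOR", G1b = "POOR", G2 = "GOOD", G3 = "GOOD")
  bad <- setdiff(unique(grade), names(valid))
  if (length(bad)) {
    stop("unknown JSED grade token(s): ", paste(bad, collapse = ", "))
  }
  unname(valid[grade])
}

#' Resolve the observed clinical response of each record
#'
#' NAT (neoadjuvant) patients are scored from their post-surgical JSED
#' grade; treatment-naive patients carry a follow-up response directly.
#' Records resolving to neither are left `NA` (lost to follow-up) and are
#' excluded from concordance.
#'
#' @param records data frame with columns `patient_id`, `group` (`"NAT"` or
#'   `"TREATMENT_NAIVE"`), `jsed_grade`, `response`.
#' @return Character vector (`"GOOD"`, `"POOR"` or `NA`) aligned to rows.
#' @export
clinical_response <- function(records) {
  out <- rep(NA_character_, nrow(records))
  is_nat <- records$group == "NAT" & !is.na(records$jsed_grade) &
    records$jsed_grade != ""
  if (any(is_nat)) out[is_nat] <- jsed_to_binary(records$jsed_grade[is_nat])
  rest <- is.na(out) & !is.na(records$response) & records$response != ""
  out[rest] <- records$response[rest]
  bad <- !is.na(out) & !out %in% c("GOOD", "POOR")
  if (any(bad)) stop("invalid response value(s): ",
                     paste(unique(out[bad]), collapse = ", "))
  out
}

#' Concordance of DST predictions with clinical response
#'
#' The positive class is a clinically GOOD responder predicted sensitive by
#' the organoid screen: `tp` counts GOOD/PREDICTED_SENSITIVE,
#' `fn` GOOD/PREDICTED_RESISTANT, `tn` POOR/PREDICTED_RESISTANT,
#' `fp` POOR/PREDICTED_SENSITIVE. Records without an observed response are
#' dropped and tallied in `n_excluded`. The mirrored statistics (resistant
#' as positive class) are reported alongside.
#'
#' @param predictions data frame with `patient_id` and `predicted`
#'   (`"PREDICTED_SENSITIVE"` / `"PREDICTED_RESISTANT"`).
#' @param records clinical records as in [clinical_response()].
#' @return A `concordance_report`: list with the confusion counts,
#'   `sensitivity`, `specificity`, `accuracy`, their mirrored counterparts,
#'   `n_evaluable` and `n_excluded`.
#' @export
concordance_stats <- function(predictions, records) {
  obs <- clinical_response(records)
  m <- merge(data.frame(patient_id = records$patient_id, observed = obs,
                        stringsAsFactors = FALSE),
             predictions, by = "patient_id")
  n_excluded <- sum(is.na(m$observed))
  m <- m[!is.na(m$observed), ]
  if (!nrow(m)) stop("no evaluable patients")
  bad <- !m$predicted %in% c("PREDICTED_SENSITIVE", "PREDICTED_RESISTANT")
  if (any(bad)) stop("invalid prediction label(s)")
  tp <- sum(m$observed == "GOOD" & m$predicted == "PREDICTED_SENSITIVE")
  fn <- sum(m$observed == "GOOD" & m$predicted == "PREDICTED_RESISTANT")
  tn <- sum(m$observed == "POOR" & m$predicted == "PREDICTED_RESISTANT")
  fp <- sum(m$observed == "POOR" & m$predicted == "PREDICTED_SENSITIVE")
  n <- tp + fn + tn + fp
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    accuracy = (tp + tn) / n,
    mirrored = list(sensitivity = frac(tn, tn + fp),
                    specificity = frac(tp, tp + fn)),
    n_evaluable = n,
    n_excluded = n_excluded
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<concordance_report> n=%d (excluded %d)\n",
    "  tp=%d fn=%d tn=%d fp=%d\n",
    "  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n"),
    x$n_evaluable, x$n_excluded, x$tp, x$fn, x$tn, x$fp,
    100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

# core pair-counting AUC: probability that a positive outranks a negative,
# ties counting one half
.pairwise_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  if (!length(pos) || !length(neg)) {
    stop("ROC AUC needs both classes present")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC AUC of a resistance score against binary response
#'
#' Rank/pair-counting (Mann-Whitney) statistic with ties contributing one
#' half. By default the score is an AUCsum-like resistance score — higher
#' means more resistant — and the positive class is the GOOD responder, so
#' the score sign is flipped internally and the AUC measures how well low
#' scores pick out good responders. Set `higher_is_positive = TRUE` for
#' scores already oriented with the positive class.
#'
#' @param scores numeric score per patient.
#' @param labels class labels aligned to `scores`.
#' @param positive label treated as the positive class (default `"GOOD"`).
#' @param higher_is_positive orientation of `scores` (default `FALSE`:
#'   higher score argues against the positive class).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "GOOD",
                    higher_is_positive = FALSE) {
  stopifnot(length(scores) == length(labels))
  is_pos <- labels == positive
  s <- if (higher_is_positive) scores else -scores
  .pairwise_auc(s, is_pos)
}

#' Youden-optimal threshold for an AUCsum-like score
#'
#' Scans the midpoints of adjacent sorted unique scores (plus outer
#' sentinels) under the rule "predict the positive class when the score is
#' at or below the threshold" and returns the cut maximising Youden's
#' J = sensitivity + specificity - 1; ties resolve toward the smaller
#' threshold.
#'
#' @param scores numeric resistance scores (higher = more resistant).
#' @param labels class labels aligned to `scores`.
#' @param positive positive-class label (default `"GOOD"`, predicted by low
#'   scores).
#' @return List with `threshold`, `j`, `sensitivity`, `specificity` at the
#'   optimum and `flags` (`"inseparable"` when the best J is 0).
#' @export
youden_threshold <- function(scores, labels, positive = "GOOD") {
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cand <- c(u[1] - 1, cand, u[length(u)] + 1)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[is_pos] <= t)
    spec <- mean(scores[!is_pos] > t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, j = j, sensitivity = sens,
                   specificity = spec, flags = character(0))
    }
  }
  if (best$j <= 1e-12) best$flags <- "inseparable"
  best
}
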