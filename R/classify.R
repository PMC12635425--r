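# Response calls: AUCsum chemoresistance classification, the per-drug
# GR100/GRmax/Cmax decision tree, Cmax/GR100 ranking, and the end-to-end
# two-step orchestration.

#' Classifier constants
#'
#' `aucsum_threshold` separates predicted TP-resistant (above) from
#' predicted TP-sensitive organoids; the default 1.134 is the screen's
#' published operating point. `grmax_cutoff` is the maximal-effect bound of
#' the per-drug decision tree: a drug is called SENSITIVE only if its
#' observed GRmax falls below it (default -0.5, i.e. the drug must at least
#' halve the net growth, pushing into the cytotoxic range).
#'
#' @param aucsum_threshold AUCsum cutoff in (0, 2), default 1.134.
#' @param grmax_cutoff GRmax cutoff in (-1, 1), default -0.5.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(aucsum_threshold = 1.134, grmax_cutoff = -0.5) {
  if (!is.finite(aucsum_threshold) || aucsum_threshold <= 0 ||
      aucsum_threshold >= 2) {
    stop("aucsum_threshold must lie in (0, 2)")
  }
  if (!is.finite(grmax_cutoff) || grmax_cutoff <= -1 || grmax_cutoff >= 1) {
    stop("grmax_cutoff must lie in (-1, 1)")
  }
  structure(list(aucsum_threshold = aucsum_threshold,
                 grmax_cutoff = grmax_cutoff),
            class = "classifier_config")
}

#' Patient-level chemoresistance call from AUCsum
#'
#' `PREDICTED_RESISTANT` iff the AUCsum exceeds the threshold; equality is
#' assigned to the sensitive side.
#'
#' @param score a `patient_score` from [auc_sum()], or a bare AUCsum number.
#' @param cfg a [classifier_config()].
#' @return `"PREDICTED_RESISTANT"` or `"PREDICTED_SENSITIVE"`.
#' @export
#' @examples
#' classify_aucsum(1.21)  # resistant
#' classify_aucsum(0.77)  # sensitive
classify_aucsum <- function(score, cfg = classifier_config()) {
  s <- if (inherits(score, "patient_score")) score$auc_sum else as.numeric(score)
  if (!is.finite(s)) stop("invalid AUCsum")
  if (s > cfg$aucsum_threshold) "PREDICTED_RESISTANT" else "PREDICTED_SENSITIVE"
}

#' Per-drug response call: the GR100/GRmax/Cmax decision tree
#'
#' RESISTANT if the complete-inhibition concentration GR100 exceeds the
#' clinically attainable Cmax (or is never reached, treated as infinite):
#' the drug cannot stop net growth at exposures a patient can receive.
#' SENSITIVE if GR100 is attainable (`gr100 < cmax`) and the maximal
#' observed effect is strongly cytotoxic (`grmax < grmax_cutoff`). PARTIAL
#' otherwise, including the exact boundary `gr100 == cmax`.
#'
#' @param summary a one-row `drug_response_summary` from [gr_metrics()].
#' @param spec the drug's registry row.
#' @param cfg a [classifier_config()].
#' @return A `drug_call`: list with `label` (one of `"SENSITIVE"`,
#'   `"PARTIAL"`, `"RESISTANT"`) and `basis` (gr100, grmax, cmax used).
#' @export
classify_drug <- function(summary, spec, cfg = classifier_config()) {
  stopifnot(nrow(summary) == 1L, nrow(spec) == 1L)
  if (!identical(summary$drug, spec$name)) {
    stop("summary is for ", summary$drug, " but spec is for ", spec$name)
  }
  gr100 <- summary$gr100
  grmax <- summary$grmax
  if (!is.finite(grmax)) stop("missing grmax in summary")
  cmax <- spec$cmax_uM
  label <- if (is.na(gr100) || gr100 > cmax) {
    "RESISTANT"
  } else if (gr100 < cmax && grmax < cfg$grmax_cutoff) {
    "SENSITIVE"
  } else {
    "PARTIAL"
  }
  structure(list(label = label,
                 basis = list(gr100 = gr100, grmax = grmax, cmax = cmax)),
            class = "drug_call")
}

#' Rank alternative therapies by Cmax/GR100
#'
#' Sorts drugs by descending `cmax_over_gr100` — how far below the clinical
#' exposure complete growth inhibition is achieved; the top drug is the
#' recommended alternative. Ties keep registry order and are flagged; a
#' ranking where no drug has a positive index is flagged
#' `"no-effective-agent"`.
#'
#' @param summaries `drug_response_summary` rows (rbind-able) for one
#'   organoid.
#' @return A `ranked_alternatives`: list with `ranking` (data frame `drug`,
#'   `cmax_over_gr100`), `recommendation`, `flags`.
#' @export
rank_alternatives <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (!nrow(summaries)) stop("no drug summaries to rank")
  # stable sort: ties keep the incoming (registry) order
  ord <- order(-summaries$cmax_over_gr100)
  ranking <- summaries[ord, c("drug", "cmax_over_gr100"), drop = FALSE]
  rownames(ranking) <- NULL
  flags <- character(0)
  if (anyDuplicated(summaries$cmax_over_gr100)) flags <- c(flags, "ties")
  if (all(summaries$cmax_over_gr100 == 0)) flags <- c(flags, "no-effective-agent")
  structure(list(ranking = ranking,
                 recommendation = ranking$drug[1],
                 flags = flags),
            class = "ranked_alternatives")
}

#' @export
print.ranked_alternatives <- function(x, ...) {
  cat("<ranked_alternatives> recommendation:", x$recommendation, "\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("  %d. %-28s Cmax/GR100 = %.4g\n", i, x$ranking$drug[i],
                x$ranking$cmax_over_gr100[i]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full two-step screen for every organoid
#'
#' Orchestrates both stages: preliminary viability at Cmax and candidate
#' selection, then — for each organoid's secondary panel (selected
#' candidates plus the TP pair) — GR profiling, sigmoid fitting, GR metrics,
#' per-drug decision-tree calls, the AUCsum score with its chemoresistance
#' call, and the Cmax/GR100 alternative ranking. Deterministic given its
#' inputs.
#'
#' @param prelim a PRELIMINARY `screen_dataset`.
#' @param secondary a SECONDARY `screen_dataset` covering at least the TP
#'   drugs for every organoid in `prelim`.
#' @param cfg a [classifier_config()].
#' @return A `two_step_report`: list with per-organoid entries (each holding
#'   `viability`, `candidates`, `summaries`, `calls`, `score`,
#'   `aucsum_class`, `alternatives`) plus the `config` used and a pooled
#'   `summary_table`.
#' @export
run_two_step <- function(prelim, secondary, cfg = classifier_config()) {
  stopifnot(inherits(prelim, "screen_dataset"),
            inherits(secondary, "screen_dataset"))
  registry <- secondary$registry
  organoids <- sort(unique(prelim$wells$organoid_id))
  entries <- lapply(organoids, function(org) {
    prof <- compute_viability(prelim, org)
    cand <- select_candidates(prof)
    sec_drugs <- setdiff(unique(
      secondary$wells$drug[secondary$wells$organoid_id == org]), NC_TAG)
    if (!all(tp_drugs() %in% sec_drugs)) {
      stop("secondary screen for ", org,
           " must include cisplatin and paclitaxel (AUCsum undefined)")
    }
    panel <- intersect(registry$name,
                       union(cand$secondary_panel, sec_drugs))
    panel <- intersect(panel, sec_drugs)
    summaries <- do.call(rbind, lapply(panel, function(d) {
      p <- gr_profile(secondary, org, d)
      f <- fit_gr_curve(p)
      gr_metrics(f, p, registry_drug(registry, d))
    }))
    calls <- lapply(seq_len(nrow(summaries)), function(i) {
      classify_drug(summaries[i, ], registry_drug(registry, summaries$drug[i]),
                    cfg)
    })
    names(calls) <- summaries$drug
    score <- auc_sum(
      summaries$norm_auc[summaries$drug == "Cisplatin"],
      summaries$norm_auc[summaries$drug == "Paclitaxel"],
      organoid_id = org
    )
    list(organoid_id = org,
         viability = prof,
         candidates = cand,
         summaries = summaries,
         calls = calls,
         score = score,
         aucsum_class = classify_aucsum(score, cfg),
         alternatives = rank_alternatives(summaries))
  })
  names(entries) <- organoids
  pooled <- do.call(rbind, lapply(entries, function(e) e$summaries))
  rownames(pooled) <- NULL
  structure(list(organoids = entries, config = cfg, summary_table = pooled),
            class = "two_step_report")
}

#' Patient-level score table from a two-step report
#'
#' @param report a `two_step_report`.
#' @return Data frame with one row per organoid: `organoid_id`, `auc_sum`,
#'   `aucsum_class`, `recommended_drug`, `recommended_index`.
#' @export
report_scores <- function(report) {
  stopifnot(inherits(report, "two_step_report"))
  out <- do.call(rbind, lapply(report$organoids, function(e) {
    data.frame(organoid_id = e$organoid_id,
               auc_sum = e$score$auc_sum,
               aucsum_class = e$aucsum_class,
               recommended_drug = e$alternatives$recommendation,
               recommended_index = e$alternatives$ranking$cmax_over_gr100[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
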