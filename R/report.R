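# Human-readable rendering of a two-step report.

#' Render a two-step report as text
#'
#' One block per organoid: preliminary viability at Cmax, the selected
#' candidates, GR metrics per secondary drug with its decision-tree call,
#' the AUCsum score and chemoresistance class, and the recommended
#' alternative by Cmax/GR100. The classifier constants in force are echoed
#' so every decision is traceable.
#'
#' @param report a `two_step_report` from [run_two_step()], optionally with
#'   a `concordance` element attached.
#' @param file connection or path passed to [base::cat()]; default prints.
#' @return The rendered lines, invisibly.
#' @export
render_report <- function(report, file = "") {
  stopifnot(inherits(report, "two_step_report"))
  out <- character(0)
  say <- function(...) out <<- c(out, sprintf(...))
  say("== two-step GR drug screen ==")
  say("config: aucsum_threshold=%.4g grmax_cutoff=%.4g",
      report$config$aucsum_threshold, report$config$grmax_cutoff)
  if (!length(report$organoids)) {
    say("no organoids")
  }
  for (e in report$organoids) {
    say("")
    say("-- %s --", e$organoid_id)
    v <- e$viability
    say("preliminary viability at Cmax: %s",
        paste(sprintf("%s %.2f", v$drug, v$viability), collapse = ", "))
    say("candidates: [%s]%s", paste(e$candidates$candidates, collapse = ", "),
        if (length(e$candidates$flags))
          paste0("  flags: ", paste(e$candidates$flags, collapse = ","))
        else "")
    s <- e$summaries
    for (i in seq_len(nrow(s))) {
      say("  %-28s GRmax %+.2f  GR100 %s uM  nAUC %.3f  Cmax/GR100 %.3g  -> %s",
          s$drug[i], s$grmax[i],
          if (is.na(s$gr100[i])) "inf" else sprintf("%.3g", s$gr100[i]),
          s$norm_auc[i], s$cmax_over_gr100[i], e$calls[[s$drug[i]]]$label)
    }
    say("AUCsum %.3f -> %s; recommended alternative: %s (Cmax/GR100 %.3g)",
        e$score$auc_sum, e$aucsum_class, e$alternatives$recommendation,
        e$alternatives$ranking$cmax_over_gr100[1])
  }
  if (!is.null(report$concordance)) {
    cr <- report$concordance
    say("")
    say("-- clinical concordance (n=%d, excluded %d) --",
        cr$n_evaluable, cr$n_excluded)
    say("tp=%d fn=%d tn=%d fp=%d", cr$tp, cr$fn, cr$tn, cr$fp)
    say("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%",
        100 * cr$sensitivity, 100 * cr$specificity, 100 * cr$accuracy)
  }
  cat(paste(out, collapse = "\n"), "\n", sep = "", file = file)
  invisible(out)
}
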