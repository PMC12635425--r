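# Stage 1: endpoint viability at Cmax and candidate-drug selection.

#' Per-drug endpoint viability from a preliminary screen
#'
#' Viability is the ratio of mean drug-treated ATP signal to mean
#' negative-control signal for one organoid; the replicate SD of the treated
#' wells, scaled by the NC mean, is carried as dispersion. No day-0
#' normalisation is applied at this stage (endpoint assay).
#'
#' @param dataset a PRELIMINARY `screen_dataset`.
#' @param organoid_id organoid to profile.
#' @return A `viability_profile`: data frame with one row per drug
#'   (`drug`, `concentration_uM`, `viability`, `sd`, `n_replicates`) and the
#'   organoid id as attribute.
#' @export
compute_viability <- function(dataset, organoid_id) {
  stopifnot(inherits(dataset, "screen_dataset"))
  if (dataset$stage != "PRELIMINARY") {
    stop("compute_viability expects a PRELIMINARY dataset")
  }
  w <- dataset$wells[dataset$wells$organoid_id == organoid_id &
                       dataset$wells$timepoint == "TEND", ]
  if (!nrow(w)) stop("no wells for organoid ", organoid_id)
  nc <- w$signal[w$drug == NC_TAG]
  if (!length(nc) || mean(nc) <= 0) {
    stop("degenerate control: organoid ", organoid_id,
         " has no positive NC signal")
  }
  nc_mean <- mean(nc)
  treated <- w[w$drug != NC_TAG, ]
  if (!nrow(treated)) stop("no treated wells for organoid ", organoid_id)
  agg <- do.call(rbind, lapply(split(treated, treated$drug), function(d) {
    data.frame(
      drug = d$drug[1],
      concentration_uM = d$concentration_uM[1],
      viability = mean(d$signal) / nc_mean,
      sd = if (nrow(d) > 1) stats::sd(d$signal) / nc_mean else NA_real_,
      n_replicates = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  # present drugs in registry order so downstream tie-breaks are stable
  agg <- agg[order(match(agg$drug, dataset$registry$name)), ]
  rownames(agg) <- NULL
  structure(agg, organoid_id = organoid_id,
            class = c("viability_profile", "data.frame"))
}

#' Select candidate drugs for the secondary screen
#'
#' Applies the preliminary selection rule: drugs whose viability at Cmax is
#' at or below `cutoff` (boundary inclusive) qualify; the three with the
#' strongest inhibition (lowest viability) are kept, ties broken by registry
#' order. The TP regimen drugs (paclitaxel and cisplatin) always proceed to
#' the secondary screen regardless of their preliminary viability.
#'
#' @param profile a `viability_profile` from [compute_viability()].
#' @param cutoff viability threshold (default 0.20).
#' @param max_candidates cap on selected drugs (default 3).
#' @param always_included drugs carried forward unconditionally; default the
#'   TP pair.
#' @return A `candidate_set`: list with `organoid_id`, `candidates` (ordered,
#'   ascending viability), `always_included`, `secondary_panel` (union, in
#'   screen order) and advisory `flags` (`"no-candidate"`, `"tie-truncated"`).
#' @export
select_candidates <- function(profile, cutoff = 0.20, max_candidates = 3L,
                              always_included = tp_drugs()) {
  stopifnot(inherits(profile, "viability_profile"))
  if (!nrow(profile)) stop("empty viability profile")
  flags <- character(0)
  # no rounding before the comparison; the boundary itself qualifies
  ok <- profile[profile$viability <= cutoff, , drop = FALSE]
  ord <- order(ok$viability)  # profile rows already in registry order
  ok <- ok[ord, , drop = FALSE]
  if (nrow(ok) > max_candidates) {
    kept <- ok$viability[seq_len(max_candidates)]
    cut_v <- kept[max_candidates]
    if (any(ok$viability[-seq_len(max_candidates)] == cut_v)) {
      flags <- c(flags, "tie-truncated")
    }
    ok <- ok[seq_len(max_candidates), , drop = FALSE]
  }
  candidates <- ok$drug
  if (!length(candidates)) flags <- c(flags, "no-candidate")
  panel <- union(candidates, always_included)
  structure(
    list(organoid_id = attr(profile, "organoid_id"),
         candidates = candidates,
         always_included = always_included,
         secondary_panel = panel,
         flags = flags),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %s: [%s] + TP {%s}%s\n",
              x$organoid_id,
              paste(x$candidates, collapse = ", "),
              paste(x$always_included, collapse = ", "),
              if (length(x$flags)) paste0("  flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}
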