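# Generative model of the screen: organoids with known division rates and
# per-drug GR truths, noisy ATP plates for both stages, and patient cohorts
# with clinical labels. The generator is the exact inverse of the GR
# transform: with zero noise the pipeline recovers the truth parameters.

#' Plate simulation design
#'
#' @param stage `"PRELIMINARY"` or `"SECONDARY"`.
#' @param duration treatment window in days (default 4).
#' @param replicates wells per condition (default 3, triplicate).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on luminescence (default 0.08).
#' @return A `sim_design` list.
#' @export
sim_design <- function(stage = c("SECONDARY", "PRELIMINARY"), duration = 4,
                       replicates = 3L, noise_cv = 0.08) {
  stage <- match.arg(stage)
  if (duration <= 0) stop("duration must be positive")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(stage = stage, duration = duration,
                 replicates = as.integer(replicates), noise_cv = noise_cv),
            class = "sim_design")
}

# lognormal multiplier with unit mean and the requested CV
.noise_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw a synthetic organoid
#'
#' An organoid is its control division rate `k0` (doublings/day), a
#' baseline per-well luminescence, and a ground-truth sigmoid
#' (`gr_inf`, `gec50`, `hill`) for every registry drug. Default ranges span
#' the regimes the fitter must handle: `gec50` log-uniform over
#' 0.01-100 uM, `hill` 0.5-4, `gr_inf` -1 to 0.5.
#'
#' @param organoid_id identifier string.
#' @param registry a `drug_registry`.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   state (used when a caller manages the stream).
#' @param truth optional data frame (`drug`, `gr_inf`, `gec50_uM`, `hill`)
#'   fixing the response truths instead of drawing them.
#' @param k0_range division-rate range, doublings/day.
#' @param t0_range baseline-signal range (log-uniform draw).
#' @param gr_inf_range,gec50_range,hill_range truth-parameter ranges.
#' @return A `sim_organoid`: list with `organoid_id`, `k0`,
#'   `t0_signal_mean`, `drug_truths` (data frame).
#' @export
simulate_organoid <- function(organoid_id, registry = load_registry("table2"),
                              seed = NULL, truth = NULL,
                              k0_range = c(0.3, 0.8),
                              t0_range = c(5e3, 2e4),
                              gr_inf_range = c(-1, 0.5),
                              gec50_range = c(0.01, 100),
                              hill_range = c(0.5, 4)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(gec50_range > 0), all(hill_range > 0),
            all(gr_inf_range >= -1), all(gr_inf_range <= 1),
            all(k0_range > 0), all(t0_range > 0))
  k0 <- stats::runif(1, k0_range[1], k0_range[2])
  t0 <- exp(stats::runif(1, log(t0_range[1]), log(t0_range[2])))
  if (is.null(truth)) {
    n <- nrow(registry)
    truth <- data.frame(
      drug = registry$name,
      gr_inf = stats::runif(n, gr_inf_range[1], gr_inf_range[2]),
      gec50_uM = exp(stats::runif(n, log(gec50_range[1]), log(gec50_range[2]))),
      hill = stats::runif(n, hill_range[1], hill_range[2]),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("drug", "gr_inf", "gec50_uM", "hill") %in% names(truth)))
  }
  structure(list(organoid_id = organoid_id, k0 = k0, t0_signal_mean = t0,
                 drug_truths = truth),
            class = "sim_organoid")
}

#' Ground-truth GR of a synthetic organoid at given doses
#'
#' @param org a `sim_organoid`.
#' @param drug drug name present in its truth table.
#' @param conc concentrations (uM).
#' @return True GR values.
#' @export
sim_gr_true <- function(org, drug, conc) {
  tr <- org$drug_truths[org$drug_truths$drug == drug, ]
  if (nrow(tr) != 1L) stop("no truth parameters for drug ", drug)
  gr_curve(conc, tr$gr_inf, tr$gec50_uM, tr$hill)
}

#' Ground-truth endpoint viability at given doses
#'
#' Viability after the treatment window follows from the growth model:
#' `v = 2^(k0 * duration * (log2(GR + 1) - 1))` — the treated/control signal
#' ratio when treated wells grow at rate `k0 * log2(GR + 1)`.
#'
#' @param org a `sim_organoid`.
#' @param drug drug name.
#' @param conc concentrations (uM).
#' @param duration treatment window in days.
#' @return True viability fractions.
#' @export
sim_viability_true <- function(org, drug, conc, duration = 4) {
  gr <- sim_gr_true(org, drug, conc)
  2^(org$k0 * duration * (log2(pmax(gr + 1, 0)) - 1))
}

#' Simulate one screening plate for one organoid
#'
#' Treated growth rate is `k(c) = k0 * log2(GR_true(c) + 1)`, so the
#' end-of-treatment signal is `x0 * 2^(k(c) * duration)` and applying
#' [gr_value()] to a noiseless plate returns `GR_true` exactly. NC wells
#' grow at `k0`. Multiplicative lognormal noise with CV `design$noise_cv` is
#' applied per well. Secondary plates carry T0 and TEND NC reads plus the
#' full dilution series per drug; preliminary plates are TEND-only at each
#' drug's Cmax. Signals that would underflow to zero (complete kill) are
#' floored at a tiny positive epsilon.
#'
#' @param org a `sim_organoid`.
#' @param design a [sim_design()] (its `stage` selects the plate type).
#' @param registry a `drug_registry`.
#' @param drugs drugs to plate (default: the whole registry).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A `screen_dataset`.
#' @export
simulate_screen <- function(org, design, registry = load_registry("table2"),
                            drugs = registry$name, seed = NULL) {
  stopifnot(inherits(org, "sim_organoid"), inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  reps <- design$replicates
  t0 <- org$t0_signal_mean
  dur <- design$duration
  floor_sig <- t0 * 1e-9
  end_signal <- function(gr) {
    k <- org$k0 * log2(pmax(gr + 1, 0))
    pmax(t0 * 2^(k * dur), floor_sig)
  }
  rows <- list()
  add <- function(drug, conc, timepoint, signal) {
    rows[[length(rows) + 1L]] <<- data.frame(
      organoid_id = org$organoid_id, drug = drug, concentration_uM = conc,
      timepoint = timepoint, replicate = seq_len(reps),
      signal = signal * .noise_mult(reps, design$noise_cv),
      stringsAsFactors = FALSE
    )
  }
  if (design$stage == "SECONDARY") {
    add(NC_TAG, 0, "T0", t0)
    add(NC_TAG, 0, "TEND", end_signal(1))
    for (d in drugs) {
      spec <- registry_drug(registry, d)
      for (conc in dilution_series(spec)) {
        add(d, conc, "TEND", end_signal(sim_gr_true(org, d, conc)))
      }
    }
  } else {
    add(NC_TAG, 0, "TEND", end_signal(1))
    for (d in drugs) {
      spec <- registry_drug(registry, d)
      add(d, spec$cmax_uM, "TEND",
          end_signal(sim_gr_true(org, d, spec$cmax_uM)))
    }
  }
  screen_dataset(do.call(rbind, rows), stage = design$stage,
                 registry = registry)
}

#' Cohort simulation specification
#'
#' @param n_patients cohort size (default 24, the evaluable cohort size the
#'   screen was validated on).
#' @param resistant_fraction probability that a patient's latent class is
#'   TP-resistant (default 14/24).
#' @param label_flip_prob probability that the recorded clinical response
#'   contradicts the latent class (default 0: labels faithful).
#' @param nat_fraction probability of belonging to the neoadjuvant (NAT)
#'   group, scored by JSED grade rather than follow-up (default 9/26).
#' @return A `sim_cohort` list.
#' @export
sim_cohort <- function(n_patients = 24L, resistant_fraction = 14 / 24,
                       label_flip_prob = 0, nat_fraction = 9 / 26) {
  stopifnot(n_patients >= 2L,
            resistant_fraction >= 0, resistant_fraction <= 1,
            label_flip_prob >= 0, label_flip_prob <= 1,
            nat_fraction >= 0, nat_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 resistant_fraction = resistant_fraction,
                 label_flip_prob = label_flip_prob,
                 nat_fraction = nat_fraction),
            class = "sim_cohort")
}

# truth-parameter regimes for the TP drugs by latent class, and for the
# off-regimen drugs; ranges relative to each drug's Cmax
.draw_truths <- function(registry, latent_resistant, rescue_drug) {
  n <- nrow(registry)
  gr_inf <- numeric(n); gec50 <- numeric(n); hill <- stats::runif(n, 1, 3)
  for (i in seq_len(n)) {
    d <- registry$name[i]; cmax <- registry$cmax_uM[i]
    if (d %in% tp_drugs()) {
      if (latent_resistant) {
        gr_inf[i] <- stats::runif(1, -0.1, 0.3)
        gec50[i] <- cmax * exp(stats::runif(1, log(4), log(50)))
      } else {
        gr_inf[i] <- stats::runif(1, -0.9, -0.55)
        gec50[i] <- cmax * exp(stats::runif(1, log(1 / 50), log(1 / 5)))
      }
    } else if (identical(d, rescue_drug) && latent_resistant) {
      gr_inf[i] <- stats::runif(1, -0.9, -0.6)
      gec50[i] <- cmax * exp(stats::runif(1, log(1 / 100), log(1 / 10)))
    } else {
      gr_inf[i] <- stats::runif(1, -0.6, 0.4)
      gec50[i] <- cmax * exp(stats::runif(1, log(1 / 10), log(20)))
    }
  }
  data.frame(drug = registry$name, gr_inf = gr_inf, gec50_uM = gec50,
             hill = hill, stringsAsFactors = FALSE)
}

#' Simulate a patient cohort with clinical labels
#'
#' Draws a latent TP-resistance class per patient, builds an organoid whose
#' cisplatin/paclitaxel truths sit in the matching regime (resistant:
#' near-flat response with `gec50` far above Cmax; sensitive: strongly
#' cytotoxic with `gec50` far below Cmax), gives resistant patients one
#' potent off-regimen drug (doxorubicin, mirroring the repurposing use
#' case), simulates both plate stages, and records a clinical response equal
#' to the latent class flipped with probability `label_flip_prob`. NAT-group
#' patients are labelled through a consistent JSED grade instead of a
#' follow-up response. The secondary plate covers the panel the preliminary
#' rule would select on noiseless data, plus the TP pair.
#'
#' @param cohort a [sim_cohort()].
#' @param registry a `drug_registry`.
#' @param design a [sim_design()] whose `duration`/`replicates`/`noise_cv`
#'   apply to both stages.
#' @param seed integer seed; all randomness flows through it.
#' @return List with pooled `preliminary` and `secondary` `screen_dataset`s,
#'   `clinical` records (patient_id, group, jsed_grade, response), `truth`
#'   (per-patient latent class, true response and organoid parameters) and
#'   `organoids` (the `sim_organoid` objects).
#' @export
simulate_cohort <- function(cohort = sim_cohort(),
                            registry = load_registry("table2"),
                            design = sim_design("SECONDARY"),
                            seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(seed)
  rescue <- "Doxorubicin hydrochloride"
  ids <- sprintf("SIM%02d", seq_len(cohort$n_patients))
  latent <- stats::rbinom(cohort$n_patients, 1, cohort$resistant_fraction) == 1
  flip <- stats::rbinom(cohort$n_patients, 1, cohort$label_flip_prob) == 1
  nat <- stats::rbinom(cohort$n_patients, 1, cohort$nat_fraction) == 1
  prelim_design <- sim_design("PRELIMINARY", duration = design$duration,
                              replicates = design$replicates,
                              noise_cv = design$noise_cv)
  organoids <- list()
  prelim_wells <- list(); sec_wells <- list()
  clinical <- list(); truth <- list()
  for (i in seq_along(ids)) {
    tr <- .draw_truths(registry, latent[i], rescue)
    org <- simulate_organoid(ids[i], registry, truth = tr)
    organoids[[ids[i]]] <- org
    prelim_wells[[i]] <-
      simulate_screen(org, prelim_design, registry)$wells
    # panel the preliminary rule would pick on the noiseless truths + TP
    v_true <- vapply(registry$name, function(d) {
      sim_viability_true(org, d, registry_drug(registry, d)$cmax_uM,
                         design$duration)
    }, numeric(1))
    hits <- registry$name[v_true <= 0.20]
    hits <- hits[order(v_true[v_true <= 0.20])]
    panel <- union(utils::head(hits, 3L), tp_drugs())
    sec_wells[[i]] <-
      simulate_screen(org, design, registry, drugs = panel)$wells
    # clinical label: latent class, possibly contradicted
    good <- !latent[i]
    if (flip[i]) good <- !good
    grade <- if (nat[i]) {
      if (good) sample(c("G2", "G3"), 1) else sample(c("G0", "G1a", "G1b"), 1)
    } else NA_character_
    clinical[[i]] <- data.frame(
      patient_id = ids[i],
      group = if (nat[i]) "NAT" else "TREATMENT_NAIVE",
      jsed_grade = grade,
      response = if (nat[i]) NA_character_ else if (good) "GOOD" else "POOR",
      stringsAsFactors = FALSE
    )
    tp_tr <- tr[tr$drug %in% tp_drugs(), ]
    truth[[i]] <- data.frame(
      patient_id = ids[i],
      latent_class = if (latent[i]) "RESISTANT" else "SENSITIVE",
      true_response = if (good) "GOOD" else "POOR",
      label_flipped = flip[i],
      k0 = org$k0,
      cisplatin_gr_inf = tp_tr$gr_inf[tp_tr$drug == "Cisplatin"],
      cisplatin_gec50_uM = tp_tr$gec50_uM[tp_tr$drug == "Cisplatin"],
      paclitaxel_gr_inf = tp_tr$gr_inf[tp_tr$drug == "Paclitaxel"],
      paclitaxel_gec50_uM = tp_tr$gec50_uM[tp_tr$drug == "Paclitaxel"],
      stringsAsFactors = FALSE
    )
  }
  list(
    preliminary = screen_dataset(do.call(rbind, prelim_wells),
                                 "PRELIMINARY", registry),
    secondary = screen_dataset(do.call(rbind, sec_wells),
                               "SECONDARY", registry),
    clinical = do.call(rbind, clinical),
    truth = do.call(rbind, truth),
    organoids = organoids
  )
}
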