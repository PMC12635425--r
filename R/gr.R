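# Growth-rate-inhibition analytics: the GR transform, sigmoidal curve
# fitting, GR metrics (GRmax/GR50/GR100), normalized AUC and AUCsum.

#' Growth-rate inhibition from paired ATP reads
#'
#' `GR = 2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1`, where `x0` is the ATP
#' signal at treatment start, `x_ctrl` the end-of-treatment negative-control
#' signal and `x_c` the end-of-treatment treated signal. GR is 1 when the
#' treated wells grow like the control, 0 at complete cytostasis and -1 at
#' complete kill; unlike endpoint viability it is invariant to the
#' division rate of the untreated culture.
#'
#' @param x0 start-of-treatment signal (> 0).
#' @param x_ctrl end-of-treatment control signal (must exceed `x0`: the
#'   control population has to grow for GR to be defined).
#' @param x_c end-of-treatment treated signal (vectorised). Non-positive
#'   values are clamped to the complete-kill floor of -1 with a warning.
#' @return Numeric vector of GR values in (-1, Inf), same length as `x_c`.
#' @export
#' @examples
#' gr_value(100, 400, 400)  # 1: treated equals control
#' gr_value(100, 400, 100)  # 0: perfect cytostasis
#' gr_value(100, 400, 200)  # sqrt(2) - 1
gr_value <- function(x0, x_ctrl, x_c) {
  if (!is.finite(x0) || x0 <= 0) stop("x0 must be positive")
  if (!is.finite(x_ctrl) || x_ctrl <= x0) {
    stop("no-growth control: x_ctrl must exceed x0 for GR to be defined")
  }
  out <- rep(NA_real_, length(x_c))
  bad <- !is.finite(x_c) | x_c <= 0
  if (any(bad)) {
    warning("non-positive treated signal(s) clamped to GR = -1")
    out[bad] <- -1
  }
  k <- log2(x_c[!bad] / x0) / log2(x_ctrl / x0)
  out[!bad] <- 2^k - 1
  out
}

#' Sigmoidal GR dose-response model
#'
#' `GR(c) = gr_inf + (1 - gr_inf) / (1 + (c / gec50)^hill)`: GR falls from 1
#' at vanishing dose to the asymptote `gr_inf` at saturating dose, with
#' half-maximal effect at `gec50`.
#'
#' @param conc concentrations (uM), vectorised.
#' @param gr_inf asymptotic GR at infinite dose.
#' @param gec50 half-maximal-effect concentration (uM, > 0).
#' @param hill slope (> 0).
#' @return GR values at `conc`.
#' @export
gr_curve <- function(conc, gr_inf, gec50, hill) {
  gr_inf + (1 - gr_inf) / (1 + (conc / gec50)^hill)
}

#' Per-concentration GR profile for one organoid/drug pair
#'
#' Aggregates a secondary screen: `x0` is the mean of the organoid's T0
#' reads, `x_ctrl` the mean end-of-treatment NC signal, and every treated
#' well is converted to a GR value; replicate GRs are kept alongside their
#' per-concentration mean. Endpoint viability (treated / NC at TEND) is
#' carried too, as the raw material of the normalized AUC.
#'
#' @param dataset a SECONDARY `screen_dataset`.
#' @param organoid_id organoid to profile.
#' @param drug registry drug name.
#' @return A `gr_profile`: list with `points` (data frame, descending
#'   concentration: `concentration_uM`, `gr`, `gr_sd`, `viability`,
#'   `n_replicates`), `replicate_gr` (long data frame), `x0`, `x_ctrl`.
#' @export
gr_profile <- function(dataset, organoid_id, drug) {
  stopifnot(inherits(dataset, "screen_dataset"))
  if (dataset$stage != "SECONDARY") {
    stop("gr_profile expects a SECONDARY dataset")
  }
  w <- dataset$wells[dataset$wells$organoid_id == organoid_id, ]
  if (!nrow(w)) stop("no wells for organoid ", organoid_id)
  x0 <- mean(w$signal[w$drug == NC_TAG & w$timepoint == "T0"])
  x_ctrl <- mean(w$signal[w$drug == NC_TAG & w$timepoint == "TEND"])
  if (!is.finite(x0) || !is.finite(x_ctrl)) {
    stop("organoid ", organoid_id, " lacks T0 or TEND NC wells")
  }
  treated <- w[w$drug == drug & w$timepoint == "TEND", ]
  if (!nrow(treated)) {
    stop("no secondary wells for drug ", drug, " on organoid ", organoid_id)
  }
  treated$gr <- gr_value(x0, x_ctrl, treated$signal)
  pts <- do.call(rbind, lapply(split(treated, treated$concentration_uM),
                               function(d) {
    data.frame(
      concentration_uM = d$concentration_uM[1],
      gr = mean(d$gr),
      gr_sd = if (nrow(d) > 1) stats::sd(d$gr) else NA_real_,
      viability = mean(d$signal) / x_ctrl,
      n_replicates = nrow(d)
    )
  }))
  pts <- pts[order(-pts$concentration_uM), ]
  rownames(pts) <- NULL
  structure(list(organoid_id = organoid_id, drug = drug, points = pts,
                 replicate_gr = treated[, c("concentration_uM", "replicate",
                                            "signal", "gr")],
                 x0 = x0, x_ctrl = x_ctrl),
            class = "gr_profile")
}

#' Fit the sigmoidal GR model to a profile
#'
#' Least-squares fit of [gr_curve()] on the log10 concentration axis
#' (Levenberg-Marquardt), on the per-concentration mean GR values with
#' uniform weights. Profiles with too little dynamic range to constrain a
#' sigmoid, and fits that fail to converge, fall back to the flat model
#' `GR(c) = mean(GR)` with `converged = FALSE`.
#'
#' @param profile a `gr_profile`, or a data frame with columns
#'   `concentration_uM` and `gr`.
#' @param min_points minimum number of distinct concentrations (default 4).
#' @param flat_range GR range below which the profile is declared flat and
#'   not fitted (default 0.1).
#' @return A `gr_curve_fit`: list with `gr_inf`, `gec50`, `hill`,
#'   `converged`, `rss`, `n`.
#' @export
fit_gr_curve <- function(profile, min_points = 4L, flat_range = 0.1) {
  pts <- if (inherits(profile, "gr_profile")) profile$points else profile
  pts <- pts[is.finite(pts$gr) & pts$concentration_uM > 0, ]
  pts <- pts[!duplicated(pts$concentration_uM), ]
  if (nrow(pts) < min_points) {
    stop("insufficient data: need >= ", min_points,
         " distinct concentrations, got ", nrow(pts))
  }
  lc <- log10(pts$concentration_uM)
  gr <- pts$gr
  flat <- function() {
    structure(list(gr_inf = mean(gr), gec50 = NA_real_, hill = NA_real_,
                   converged = FALSE, rss = sum((gr - mean(gr))^2),
                   n = nrow(pts)),
              class = "gr_curve_fit")
  }
  if (diff(range(gr)) < flat_range) return(flat())
  resid_fn <- function(p) {
    gr - (p[1] + (1 - p[1]) / (1 + 10^((lc - p[2]) * p[3])))
  }
  lower <- c(-1, min(lc) - 4, 0.05)
  upper <- c(1, max(lc) + 4, 15)
  # The sigmoid surface has local minima when the half-effect point sits
  # near the range edge, so seed Levenberg-Marquardt from a profiled grid:
  # for fixed (gec50, hill) the model is linear in gr_inf, whose conditional
  # optimum is closed form.
  grid_l <- seq(min(lc) - 2, max(lc) + 2, length.out = 61)
  grid_h <- exp(seq(log(0.05), log(15), length.out = 33))
  start <- c(min(gr), stats::median(lc), 1)
  best_rss <- Inf
  for (L in grid_l) for (h in grid_h) {
    u <- 1 / (1 + 10^((lc - L) * h))
    denom <- sum((1 - u)^2)
    g <- if (denom > 0) sum((gr - u) * (1 - u)) / denom else 0
    g <- min(max(g, -1), 1)
    rss <- sum((gr - g - (1 - g) * u)^2)
    if (rss < best_rss) {
      best_rss <- rss
      start <- c(g, L, h)
    }
  }
  best <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL
  )
  if (is.null(best) || !best$info %in% 1:4) return(flat())
  p <- best$par
  # a slope or half-effect point pinned at its box bound is not an interior
  # optimum: the curve shape is unidentified, report honestly
  pinned <- p[2] <= lower[2] + 1e-8 || p[2] >= upper[2] - 1e-8 ||
    p[3] <= lower[3] + 1e-8 || p[3] >= upper[3] - 1e-8
  if (pinned) return(flat())
  # identifiability: a sigmoid is pinned down only if at least two points
  # sit in the transition zone between the control level and the asymptote
  n_transition <- sum(gr > p[1] + 0.05 & gr < 1 - 0.05)
  if (n_transition < 2L) return(flat())
  structure(list(gr_inf = p[1], gec50 = 10^p[2], hill = p[3],
                 converged = TRUE, rss = best$deviance, n = nrow(pts)),
            class = "gr_curve_fit")
}

#' @export
print.gr_curve_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<gr_curve_fit> gr_inf=%.3f gec50=%.4g uM hill=%.3f rss=%.3g\n",
                x$gr_inf, x$gec50, x$hill, x$rss))
  } else {
    cat(sprintf("<gr_curve_fit> flat fallback, gr_inf=%.3f (not converged)\n",
                x$gr_inf))
  }
  invisible(x)
}

#' Concentration at which a fitted GR curve reaches a level
#'
#' Closed-form inversion of the sigmoid: the curve crosses `level` at
#' `gec50 * ((1 - level) / (level - gr_inf))^(1 / hill)`, provided the
#' asymptote lies below the level (`gr_inf < level`); otherwise the level is
#' never reached and `NA` is returned. `level = 0` gives GR100 (complete
#' growth-rate inhibition), `level = 0.5` gives GR50.
#'
#' @param fit a converged `gr_curve_fit`.
#' @param level GR level in (-1, 1).
#' @return Concentration in uM, or `NA` if the curve never reaches `level`.
#' @export
gr_level_concentration <- function(fit, level) {
  if (!fit$converged) return(NA_real_)
  if (fit$gr_inf >= level) return(NA_real_)
  fit$gec50 * ((1 - level) / (level - fit$gr_inf))^(1 / fit$hill)
}

# log-linear interpolation of the measured points at a GR level; used when
# the sigmoid fit is unavailable but the data themselves cross the level
.interpolate_level <- function(pts, level) {
  pts <- pts[order(pts$concentration_uM), ]
  gr <- pts$gr
  cross <- which(diff(sign(gr - level)) != 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  lc1 <- log10(pts$concentration_uM[i]); lc2 <- log10(pts$concentration_uM[i + 1])
  g1 <- gr[i]; g2 <- gr[i + 1]
  10^(lc1 + (level - g1) * (lc2 - lc1) / (g2 - g1))
}

#' GR summary metrics for one organoid/drug pair
#'
#' Combines the observed profile and the fitted curve into the screen's
#' reporting quantities: `grmax` (minimum mean GR over tested
#' concentrations, the observed maximal effect), `gr50` and `gr100`
#' (concentrations where the fitted curve reaches GR 0.5 and 0, closed form
#' via [gr_level_concentration()]; `NA` when the asymptote never gets
#' there), the normalized dose-response AUC of the endpoint viabilities, and
#' the potency index `cmax_over_gr100` (0 when GR100 is never reached). When
#' the sigmoid fit did not converge but the measured points cross a level,
#' the crossing is log-linearly interpolated and flagged `"interpolated"`.
#' Crossings more than one dilution step outside the tested range are
#' flagged `"gr100-extrapolated"` / `"gr50-extrapolated"`, with a warning
#' beyond two steps.
#'
#' @param fit a `gr_curve_fit` for the profile.
#' @param profile the `gr_profile` it was fitted to.
#' @param spec the drug's registry row (for Cmax and the dilution factor).
#' @return A `drug_response_summary`: one-row data frame with columns
#'   `organoid_id`, `drug`, `grmax`, `gr50`, `gr100`, `norm_auc`,
#'   `cmax_over_gr100`, `converged`, `flags`.
#' @export
gr_metrics <- function(fit, profile, spec) {
  stopifnot(inherits(profile, "gr_profile"), nrow(spec) == 1L)
  if (!identical(profile$drug, spec$name)) {
    stop("profile is for ", profile$drug, " but spec is for ", spec$name)
  }
  pts <- profile$points
  flags <- character(0)
  grmax <- min(pts$gr)

  solve_level <- function(level, tag) {
    conc <- gr_level_concentration(fit, level)
    if (!fit$converged && is.na(conc)) {
      conc <- .interpolate_level(pts, level)
      if (!is.na(conc)) flags <<- c(flags, "interpolated")
    }
    if (!is.na(conc)) {
      lo <- min(pts$concentration_uM); hi <- max(pts$concentration_uM)
      step <- spec$dilution_factor
      if (conc < lo / step || conc > hi * step) {
        flags <<- c(flags, paste0(tag, "-extrapolated"))
        if (conc < lo / step^2 || conc > hi * step^2) {
          warning(profile$organoid_id, "/", profile$drug, ": ", tag,
                  " lies far outside the tested range (", signif(conc, 3),
                  " uM)")
        }
      }
    }
    conc
  }
  gr50 <- solve_level(0.5, "gr50")
  gr100 <- solve_level(0, "gr100")

  nauc <- normalized_auc(pts$concentration_uM, pts$viability)
  if (isTRUE(attr(nauc, "clipped"))) flags <- c(flags, "viability-clipped")

  out <- data.frame(
    organoid_id = profile$organoid_id,
    drug = profile$drug,
    grmax = grmax,
    gr50 = gr50,
    gr100 = gr100,
    norm_auc = as.numeric(nauc),
    cmax_over_gr100 = if (is.na(gr100)) 0 else spec$cmax_uM / gr100,
    converged = fit$converged,
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("drug_response_summary", "data.frame")
  out
}

#' Normalized dose-response AUC
#'
#' Trapezoidal integral of the viability fraction over log10 concentration,
#' divided by the maximal possible area (viability 1 across the full log10
#' span), so that 1 means fully resistant and 0 fully sensitive. Computed on
#' the raw mean viabilities, not a fitted curve; invariant under reversal of
#' the concentration order. Viabilities are clipped to [0, 1] before
#' integration; clipping is recorded in the `"clipped"` attribute.
#'
#' @param conc concentrations (uM, > 0), at least two distinct values.
#' @param viability viability fractions matching `conc`.
#' @return Normalized AUC in [0, 1] with attribute `clipped`.
#' @export
#' @examples
#' co <- 50 / 4^(0:5)
#' normalized_auc(co, c(0, 0, 0, 0.5, 1, 1))  # 0.4
normalized_auc <- function(conc, viability) {
  if (length(conc) != length(viability)) stop("length mismatch")
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be positive and finite")
  }
  if (length(unique(conc)) < 2) {
    stop("normalized AUC needs at least two distinct concentrations")
  }
  ord <- order(conc)
  x <- log10(conc[ord])
  v <- viability[ord]
  clipped <- any(v < 0 | v > 1)
  v <- pmin(pmax(v, 0), 1)
  area <- sum(diff(x) * (v[-1] + v[-length(v)]) / 2)
  structure(area / (max(x) - min(x)), clipped = clipped)
}

#' AUCsum chemoresistance score
#'
#' Sum of the normalized AUCs of cisplatin and paclitaxel for one organoid
#' — the screen's patient-level score for the TP regimen, in [0, 2]; high
#' values mean resistance to both drugs.
#'
#' @param cisplatin_auc normalized AUC of cisplatin, in [0, 1].
#' @param paclitaxel_auc normalized AUC of paclitaxel, in [0, 1].
#' @param organoid_id optional organoid identifier.
#' @return A `patient_score`: list with `organoid_id`, `auc_sum`,
#'   `components`.
#' @export
auc_sum <- function(cisplatin_auc, paclitaxel_auc, organoid_id = NA_character_) {
  for (v in c(cisplatin_auc, paclitaxel_auc)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("both normalized AUC components are mandatory and must lie in [0, 1]")
    }
  }
  structure(list(organoid_id = organoid_id,
                 auc_sum = cisplatin_auc + paclitaxel_auc,
                 components = c(cisplatin = cisplatin_auc,
                                paclitaxel = paclitaxel_auc)),
            class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  cat(sprintf("<patient_score> %s AUCsum=%.3f (cisplatin %.3f + paclitaxel %.3f)\n",
              x$organoid_id, x$auc_sum, x$components["cisplatin"],
              x$components["paclitaxel"]))
  invisible(x)
}

#' Constrained log-logistic viability fit
#'
#' Two-free-parameter log-logistic `v(c) = 1 / (1 + (c / ec50)^hill)` with
#' the activity range pinned to 100%..0% (top and bottom fixed), for
#' plotting and reporting of endpoint viability curves. The normalized AUC
#' is computed from the raw points, not from this fit.
#'
#' @param conc concentrations (uM, > 0).
#' @param viability viability fractions.
#' @return List with `ec50`, `hill`, `top` (1), `bottom` (0), `converged`,
#'   `rss`.
#' @export
fit_viability_curve <- function(conc, viability) {
  keep <- is.finite(conc) & conc > 0 & is.finite(viability)
  conc <- conc[keep]; viability <- pmin(pmax(viability[keep], 0), 1)
  if (length(conc) < 3) stop("need at least 3 points to fit a viability curve")
  lc <- log10(conc)
  resid_fn <- function(p) viability - 1 / (1 + 10^((lc - p[1]) * p[2]))
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(stats::median(lc), h0), fn = resid_fn,
                         lower = c(min(lc) - 4, 0.05),
                         upper = c(max(lc) + 4, 15),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(out) || !out$info %in% 1:4) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) {
    return(list(ec50 = NA_real_, hill = NA_real_, top = 1, bottom = 0,
                converged = FALSE, rss = NA_real_))
  }
  list(ec50 = 10^best$par[1], hill = best$par[2],
       top = 1, bottom = 0, converged = TRUE, rss = best$deviance)
}
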