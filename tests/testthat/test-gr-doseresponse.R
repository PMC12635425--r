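test_that("gr_value matches its closed forms and limits", {
  expect_equal(gr_value(100, 400, 400), 1)
  expect_equal(gr_value(100, 400, 100), 0)
  expect_equal(gr_value(100, 400, 200), sqrt(2) - 1)
  # approaches complete kill from above as the treated signal vanishes
  expect_gt(gr_value(100, 400, 1e-8), -1)
  expect_equal(gr_value(100, 400, 1e-8), -1, tolerance = 1e-3)
  # monotone increasing in the treated signal
  xs <- sort(runif(50, 1, 1000))
  expect_true(all(diff(gr_value(100, 400, xs)) > 0))
})

test_that("gr_value rejects non-growing controls and clamps dead wells", {
  expect_error(gr_value(100, 100, 50), "no-growth")
  expect_error(gr_value(100, 90, 50), "no-growth")
  expect_error(gr_value(0, 400, 50), "x0")
  expect_warning(g <- gr_value(100, 400, 0), "clamped")
  expect_equal(g, -1)
})

test_that("noiseless sigmoid data are recovered by the fitter", {
  prof <- truth_profile(gr_inf = -0.6, gec50 = 1.0, hill = 2)
  fit <- fit_gr_curve(prof)
  expect_true(fit$converged)
  expect_equal(fit$gr_inf, -0.6, tolerance = 0.01)
  expect_equal(fit$gec50, 1.0, tolerance = 0.01)
  expect_equal(fit$hill, 2, tolerance = 0.01)
})

test_that("inert drugs fall back to the flat model", {
  prof <- truth_profile(gr_inf = 1, gec50 = 1, hill = 1)  # GR == 1 everywhere
  fit <- fit_gr_curve(prof)
  expect_false(fit$converged)
  expect_equal(fit$gr_inf, 1, tolerance = 1e-9)
  expect_error(fit_gr_curve(truth_profile(-0.5, 1, 1, n = 3)),
               "insufficient")
})

test_that("GR50/GR100 closed forms agree with bisection on the curve", {
  set.seed(77)
  for (i in 1:50) {
    fit <- structure(list(gr_inf = runif(1, -1, -0.05),
                          gec50 = 10^runif(1, -2, 2),
                          hill = runif(1, 0.5, 4), converged = TRUE),
                     class = "gr_curve_fit")
    for (level in c(0, 0.5)) {
      conc <- gr_level_concentration(fit, level)
      f <- function(lc) gr_curve(10^lc, fit$gr_inf, fit$gec50, fit$hill) - level
      root <- stats::uniroot(f, c(log10(conc) - 5, log10(conc) + 5),
                             tol = 1e-13)$root
      expect_equal(conc, 10^root, tolerance = 1e-9)
    }
  }
})

test_that("worked sigmoid example: GR100 at 2 uM, GRmax and the ratio", {
  prof <- truth_profile(gr_inf = -0.5, gec50 = 1, hill = 1,
                        drug = "Cisplatin")
  prof$points$viability <- pmax(prof$points$gr, 0)  # any valid viabilities
  fit <- fit_gr_curve(prof)
  expect_true(fit$converged)
  spec <- registry_drug(load_registry("table2"), "Cisplatin")
  sm <- gr_metrics(fit, prof, spec)
  expect_equal(sm$gr100, 2.0, tolerance = 1e-6)
  expect_equal(sm$gr50, 1 * (0.5 / 1)^(1), tolerance = 1e-6)
  expect_equal(sm$grmax, min(prof$points$gr))
  expect_equal(sm$cmax_over_gr100, 13.67 / sm$gr100, tolerance = 1e-6)
})

test_that("curves that never reach cytostasis report no GR100", {
  prof <- truth_profile(gr_inf = 0.2, gec50 = 1, hill = 1, drug = "Cisplatin")
  prof$points$viability <- prof$points$gr
  fit <- fit_gr_curve(prof)
  sm <- gr_metrics(fit, prof, registry_drug(load_registry("table2"),
                                            "Cisplatin"))
  expect_true(is.na(sm$gr100))
  expect_equal(sm$cmax_over_gr100, 0)
  # GR50 still exists (asymptote 0.2 < 0.5)
  expect_false(is.na(sm$gr50))
})

test_that("crossings far below the tested range are flagged extrapolated", {
  # very potent drug: GR100 near 0.0025 uM, far below the 0.049 uM ladder floor
  prof <- truth_profile(gr_inf = -0.8, gec50 = 0.002, hill = 1,
                        drug = "Doxorubicin hydrochloride")
  prof$points$viability <- pmax(prof$points$gr, 0)
  fit <- structure(list(gr_inf = -0.8, gec50 = 0.002, hill = 1,
                        converged = TRUE, rss = 0, n = 6L),
                   class = "gr_curve_fit")
  spec <- registry_drug(load_registry("table2"), "Doxorubicin hydrochloride")
  # both the GR100 and the GR50 crossings sit far below the ladder
  w <- capture_warnings(sm <- gr_metrics(fit, prof, spec))
  expect_true(any(grepl("outside the tested range", w)))
  expect_true(grepl("gr100-extrapolated", sm$flags))
  expect_gt(sm$cmax_over_gr100, 1)
})

test_that("non-converged fits with an empirical crossing interpolate it", {
  conc <- 50 / 4^(0:5)
  # a profile the sigmoid cannot fit (non-monotone) that still crosses zero
  gr <- c(-0.4, -0.35, -0.45, 0.3, 0.8, 0.9)  # descending concentration
  prof <- truth_profile(-0.5, 1, 1, drug = "Cisplatin")
  prof$points$gr <- gr
  prof$points$viability <- pmax(gr, 0)
  fit <- structure(list(gr_inf = mean(gr), gec50 = NA_real_, hill = NA_real_,
                        converged = FALSE, rss = 0, n = 6L),
                   class = "gr_curve_fit")
  sm <- gr_metrics(fit, prof, registry_drug(load_registry("table2"),
                                            "Cisplatin"))
  expect_true(grepl("interpolated", sm$flags))
  # crossing bracketed between 0.78125 (gr 0.3) and 3.125 (gr -0.45) uM
  expect_gt(sm$gr100, 0.78125)
  expect_lt(sm$gr100, 3.125)
})

test_that("normalized AUC matches the hand trapezoid and the oracle", {
  conc <- 50 / 4^(0:5)
  expect_equal(as.numeric(normalized_auc(conc, rep(1, 6))), 1)
  expect_equal(as.numeric(normalized_auc(conc, rep(0, 6))), 0)
  expect_equal(as.numeric(normalized_auc(conc, c(0, 0, 0, 0.5, 1, 1))), 0.4)
  # order invariance
  expect_equal(as.numeric(normalized_auc(rev(conc), c(1, 1, 0.5, 0, 0, 0))),
               0.4)
  set.seed(99)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    co <- sort(10^runif(n, -3, 3))
    v <- runif(n, -0.2, 1.3)  # exercises clipping
    got <- normalized_auc(co, v)
    expect_equal(as.numeric(got), oracle_norm_auc(co, v), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(as.numeric(normalized_auc(co[perm], v[perm])),
                 as.numeric(got), tolerance = 1e-12)
  }
  expect_true(attr(normalized_auc(c(1, 10), c(-0.5, 0.5)), "clipped"))
  expect_error(normalized_auc(1, 0.5), "two distinct")
  expect_error(normalized_auc(c(0, 1), c(0.5, 0.5)), "positive")
})

test_that("AUCsum adds the two TP components and validates them", {
  expect_equal(auc_sum(1, 1)$auc_sum, 2)
  s <- auc_sum(0.5, 0.7, organoid_id = "X")
  expect_equal(s$auc_sum, 1.2)
  expect_equal(s$auc_sum, sum(s$components), tolerance = 1e-12)
  expect_error(auc_sum(NA, 0.5), "mandatory")
  expect_error(auc_sum(1.2, 0.5), "mandatory")
})

test_that("constrained viability fit recovers a log-logistic truth", {
  conc <- 50 / 4^(0:5)
  v <- 1 / (1 + (conc / 2)^1.5)
  fit <- fit_viability_curve(conc, v)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 2, tolerance = 0.01)
  expect_equal(fit$hill, 1.5, tolerance = 0.01)
  expect_identical(c(fit$top, fit$bottom), c(1, 0))
})

test_that("full profile path: simulated plate to GR metrics, zero noise", {
  reg <- load_registry("table2")
  tr <- data.frame(drug = reg$name, gr_inf = -0.6, gec50_uM = 2, hill = 1.5)
  org <- simulate_organoid("GP1", reg, seed = 5, truth = tr)
  ds <- simulate_screen(org, sim_design("SECONDARY", noise_cv = 0), reg,
                        drugs = "Cisplatin")
  prof <- gr_profile(ds, "GP1", "Cisplatin")
  expect_equal(prof$points$gr,
               sim_gr_true(org, "Cisplatin", prof$points$concentration_uM),
               tolerance = 1e-9)
  fit <- fit_gr_curve(prof)
  expect_equal(fit$gec50, 2, tolerance = 0.01)
  sm <- gr_metrics(fit, prof, registry_drug(reg, "Cisplatin"))
  want_gr100 <- 2 * ((1 - 0) / (0 + 0.6))^(1 / 1.5)
  expect_equal(sm$gr100, want_gr100, tolerance = 1e-3)
})
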