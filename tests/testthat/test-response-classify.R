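make_summary <- function(drug, gr100, grmax, cmax_over_gr100 = 0,
                         organoid = "ORG1") {
  structure(data.frame(organoid_id = organoid, drug = drug, grmax = grmax,
                       gr50 = NA_real_, gr100 = gr100, norm_auc = 0.5,
                       cmax_over_gr100 = cmax_over_gr100, converged = TRUE,
                       flags = "", stringsAsFactors = FALSE),
            class = c("drug_response_summary", "data.frame"))
}

test_that("AUCsum classification reproduces the published calls", {
  expect_identical(classify_aucsum(1.21), "PREDICTED_RESISTANT")
  expect_identical(classify_aucsum(0.77), "PREDICTED_SENSITIVE")
  # the boundary goes to the sensitive side
  expect_identical(classify_aucsum(1.134), "PREDICTED_SENSITIVE")
  cfg <- classifier_config(aucsum_threshold = 0.5)
  expect_identical(classify_aucsum(0.77, cfg), "PREDICTED_RESISTANT")
  expect_error(classifier_config(aucsum_threshold = 2.5), "0, 2")
})

test_that("AUCsum classification is monotone in the score", {
  set.seed(41)
  s <- sort(runif(100, 0, 2))
  calls <- vapply(s, classify_aucsum, character(1))
  # once resistant, always resistant as the score grows
  expect_true(all(diff(calls == "PREDICTED_RESISTANT") >= 0))
})

test_that("the decision tree reproduces its printed branches", {
  reg <- load_registry("table2")
  spec <- registry_drug(reg, "Paclitaxel")
  cmax <- spec$cmax_uM
  expect_identical(
    classify_drug(make_summary("Paclitaxel", 2 * cmax, -0.8), spec)$label,
    "RESISTANT")
  expect_identical(
    classify_drug(make_summary("Paclitaxel", 0.5 * cmax, -0.8), spec)$label,
    "SENSITIVE")
  expect_identical(
    classify_drug(make_summary("Paclitaxel", 0.5 * cmax, -0.2), spec)$label,
    "PARTIAL")
  # GR100 never reached => resistant; exact boundary => partial
  expect_identical(
    classify_drug(make_summary("Paclitaxel", NA_real_, -0.8), spec)$label,
    "RESISTANT")
  expect_identical(
    classify_drug(make_summary("Paclitaxel", cmax, -0.8), spec)$label,
    "PARTIAL")
  expect_error(classify_drug(make_summary("Paclitaxel", 1, NA_real_), spec),
               "grmax")
})

test_that("the three branches partition the (gr100, grmax) plane", {
  reg <- load_registry("table2")
  spec <- registry_drug(reg, "Paclitaxel")
  cfg <- classifier_config()
  set.seed(4242)
  n <- 10000
  gr100 <- ifelse(runif(n) < 0.1, NA_real_, 10^runif(n, -3, 3))
  grmax <- runif(n, -1, 1)
  # occasionally land exactly on the boundaries
  gr100[sample(n, 200)] <- spec$cmax_uM
  grmax[sample(n, 200)] <- cfg$grmax_cutoff
  s <- make_summary("Paclitaxel", 1, -0.5)
  got <- character(n)
  for (i in seq_len(n)) {
    s$gr100 <- gr100[i]
    s$grmax <- grmax[i]
    got[i] <- classify_drug(s, spec, cfg)$label
  }
  # brute-force re-evaluation of the two printed predicates
  resistant <- is.na(gr100) | gr100 > spec$cmax_uM
  sensitive <- !resistant & gr100 < spec$cmax_uM & grmax < cfg$grmax_cutoff
  want <- ifelse(resistant, "RESISTANT",
                 ifelse(sensitive, "SENSITIVE", "PARTIAL"))
  expect_identical(got, want)
  # exactly one branch fires every time
  expect_true(all(resistant + sensitive + (!resistant & !sensitive) == 1L))
})

test_that("alternative ranking reproduces the published orderings", {
  s <- rbind(make_summary("Doxorubicin hydrochloride", 6.90 / 76.73, -0.9,
                          76.73),
             make_summary("Cisplatin", 13.67 / 0.07, -0.1, 0.07),
             make_summary("Paclitaxel", 5.10 / 0.3, -0.2, 0.3))
  r <- rank_alternatives(s)
  expect_identical(r$ranking$drug,
                   c("Doxorubicin hydrochloride", "Paclitaxel", "Cisplatin"))
  expect_identical(r$recommendation, "Doxorubicin hydrochloride")
  expect_equal(r$ranking$cmax_over_gr100, c(76.73, 0.3, 0.07))

  s2 <- rbind(make_summary("Doxorubicin hydrochloride", 1, -0.9, 32.83),
              make_summary("Cisplatin", 1, -0.1, 0.05),
              make_summary("Paclitaxel", 1, -0.2, 0.2))
  expect_identical(rank_alternatives(s2)$recommendation,
                   "Doxorubicin hydrochloride")

  # degenerate: nothing works
  s3 <- rbind(make_summary("Cisplatin", NA_real_, 0.1, 0),
              make_summary("Paclitaxel", NA_real_, 0.2, 0))
  r3 <- rank_alternatives(s3)
  expect_true("no-effective-agent" %in% r3$flags)
  expect_setequal(r3$ranking$drug, c("Cisplatin", "Paclitaxel"))
})

test_that("ranking is a permutation of its input, non-increasing", {
  set.seed(88)
  reg <- load_registry("table2")
  for (i in 1:50) {
    drugs <- sample(reg$name, sample(2:10, 1))
    s <- do.call(rbind, lapply(drugs, function(d)
      make_summary(d, 1, -0.5, sample(c(0, round(10^runif(1, -2, 2), 2)), 1))))
    r <- rank_alternatives(s)
    expect_setequal(r$ranking$drug, drugs)
    expect_true(all(diff(r$ranking$cmax_over_gr100) <= 0))
    expect_identical(r$recommendation, r$ranking$drug[1])
  }
})

test_that("run_two_step recovers the latent class of simulated organoids", {
  reg <- load_registry("table2")
  co <- simulate_cohort(sim_cohort(n_patients = 6), reg,
                        sim_design("SECONDARY", noise_cv = 0.05), seed = 1301)
  rep <- suppressWarnings(run_two_step(co$preliminary, co$secondary))
  sc <- report_scores(rep)
  m <- merge(sc, co$truth, by.x = "organoid_id", by.y = "patient_id")
  want <- ifelse(m$latent_class == "RESISTANT",
                 "PREDICTED_RESISTANT", "PREDICTED_SENSITIVE")
  expect_identical(m$aucsum_class, want)
  # resistant organoids carry the potent off-regimen drug as recommendation
  res <- m[m$latent_class == "RESISTANT", ]
  expect_true(all(res$recommended_drug == "Doxorubicin hydrochloride"))
  expect_true(all(res$auc_sum > rep$config$aucsum_threshold))
})

test_that("run_two_step insists on the TP drugs in the secondary screen", {
  reg <- load_registry("table2")
  org <- simulate_organoid("TP1", reg, seed = 9)
  pre <- simulate_screen(org, sim_design("PRELIMINARY", noise_cv = 0), reg)
  sec <- simulate_screen(org, sim_design("SECONDARY", noise_cv = 0), reg,
                         drugs = c("Cisplatin", "Docetaxel"))
  expect_error(run_two_step(pre, sec), "paclitaxel")
  # with both TP drugs present the minimal pathway works even with
  # an empty candidate set
  sec2 <- simulate_screen(org, sim_design("SECONDARY", noise_cv = 0), reg,
                          drugs = tp_drugs())
  rep <- run_two_step(pre, sec2)
  e <- rep$organoids[["TP1"]]
  expect_setequal(e$summaries$drug, tp_drugs())
  expect_true(is.finite(e$score$auc_sum))
})
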