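---
title: "Two-step GR-based organoid drug screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step GR-based organoid drug screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscreen)
```

## The problem

Patients with locally advanced oesophageal squamous cell carcinoma receive
perioperative chemotherapy — usually the TP regimen, paclitaxel (taxol) plus
cisplatin — but a substantial fraction derive little benefit, and the window
for switching therapy after surgery is short (about 30 days). Patient-derived
organoids (PDOs) grown from the resected tumour can be drug-tested ex vivo,
but a conventional screen of ten drugs at six concentrations in triplicate
needs weeks of expansion culture. The two-step design implemented here cuts
that down: a **preliminary screen** tests every drug once, at its maximum
plasma concentration (Cmax), on a minimal number of cells; only the few drugs
that look active — plus the TP pair, always — go into a full **secondary
titration** scored with growth-rate-inhibition (GR) metrics.

## The GR transform

Endpoint viability (treated/control ATP at the end of treatment) confounds a
drug's effect with how fast the untreated culture happens to divide: slowly
dividing organoids look spuriously resistant. The GR value removes that
confound by working on the scale of division rates. With `x0` the ATP signal
at treatment start, `x_ctrl` the end-of-treatment vehicle-control signal and
`x(c)` the treated signal at concentration `c`,

$$\mathrm{GR}(c) = 2^{\,\log_2(x(c)/x_0)\,/\,\log_2(x_{ctrl}/x_0)} - 1 .$$

GR is the ratio of treated to control growth rate, mapped so that 1 means no
effect, 0 complete cytostasis (the treated population neither grows nor
shrinks) and −1 complete kill. It is exactly invariant to `k0`, the control
division rate, as long as growth is exponential over the assay window — which
is also the regime the synthetic generator simulates (below). `gr_value()`
requires a growing control (`x_ctrl > x0`); a non-growing control makes the
exponent undefined and is reported as an error rather than silently patched.

## Dose–response model and fitting

Mean GR per concentration is fitted with the three-parameter sigmoid

$$\mathrm{GR}(c) = GR_{inf} + \frac{1 - GR_{inf}}{1 + (c/GEC_{50})^{h}}$$

by least squares on the log10 concentration axis (`fit_gr_curve()`), with
uniform weights and replicate GR values averaged before fitting. Numerical
choices that matter:

* **Optimisation.** Levenberg–Marquardt (`minpack.lm::nls.lm`) seeded from a
  profiled grid: for fixed `(GEC50, h)` the model is linear in `GRinf`, whose
  conditional optimum is closed-form, so a coarse 61 × 33 grid over
  `log10 GEC50` (tested range ± 2 decades) and `h` (0.05–15, log-spaced)
  locates the global basin cheaply before a single polish run. Box bounds:
  `GRinf` ∈ [−1, 1], `h` ∈ [0.05, 15], `log10 GEC50` within the tested range
  ± 4 decades.
* **Honest convergence.** Profiles whose GR range is below 0.1 carry no
  curve information and return the flat model (`GRinf` = mean GR,
  `converged = FALSE`). A fit whose slope or half-effect point lands on a box
  bound, or with fewer than two points in the transition zone between the
  control level and the asymptote, is likewise declared non-converged: three
  parameters cannot be identified from one informative point, and a
  confidently wrong sigmoid is worse than an honest fallback.
* At least 4 distinct concentrations are required; fewer is an error, not a
  degraded fit.

Endpoint viability curves, used for plotting and reporting only, are fitted
with the activity range pinned to 100%–0% and two free parameters (EC50 and
slope) in `fit_viability_curve()`.

## GR metrics

`gr_metrics()` reduces a fitted pair (curve, profile) to the screen's
reporting quantities:

* **GRmax** — the minimum of the mean GR over the tested concentrations: the
  observed maximal effect. Using the observed minimum rather than the fitted
  asymptote keeps the statistic robust to asymptote extrapolation.
* **GR50 / GR100** — the concentrations at which the *fitted* curve reaches
  GR = 0.5 and GR = 0, solved in closed form:
  $c_L = GEC_{50}\left(\frac{1-L}{L-GR_{inf}}\right)^{1/h}$ for level $L$,
  defined only when $GR_{inf} < L$. **GR100 is defined as the concentration
  of complete growth-rate inhibition (GR = 0).** The name is used without a
  formula in the screening literature this package implements; this reading
  is the only one under which the decision rule "GR100 > Cmax ⇒ resistant"
  compares like with like — both are concentrations. When the asymptote never
  reaches the level, the metric is absent (treated as +∞ downstream). When
  the sigmoid fit is unavailable but the measured points bracket the level,
  the crossing is log-linearly interpolated and flagged `"interpolated"`.
* **Extrapolation policy.** A fitted crossing more than one dilution step
  (fourfold) outside the tested range is still reported — suppressing it
  would destroy the Cmax/GR100 ranking for strong inhibitors, whose GR100
  can sit far below the lowest tested dose — but flagged
  `"gr100-extrapolated"`, with a hard warning beyond two steps.
* **Normalized AUC** — trapezoidal integral of the raw mean endpoint
  viabilities over log10 concentration, divided by the maximal possible area
  (viability ≡ 1 over the same span), so 1 is fully resistant and 0 fully
  sensitive. It is computed from the raw points, not the fitted curve; the
  implementation sorts internally, so it is invariant to ascending or
  descending dose order. Viabilities are clipped to [0, 1] first and the
  clipping is flagged.
* **Cmax/GR100** — the potency index used for repurposing: values ≫ 1 mean
  complete growth inhibition is reached well below clinically attainable
  exposure. Defined as 0 when GR100 is absent, so a drug that never stops
  net growth can never be recommended.

## Patient-level scoring and calls

**AUCsum** is the sum of the cisplatin and paclitaxel normalized AUCs
(∈ [0, 2]); both components are mandatory, which is why the TP pair is
always carried into the secondary screen. The chemoresistance call is
`AUCsum > 1.134 ⇒ PREDICTED_RESISTANT`; 1.134 is the published operating
point, kept as the default constant (how it was originally derived is not
stated; `youden_threshold()` provides a data-driven alternative for new
cohorts). The boundary itself goes to the sensitive side — the published
analysis never evaluates a tie, so the convention is ours and is documented
here.

The per-drug **decision tree** partitions the (GR100, GRmax) plane:

* RESISTANT — `GR100 > Cmax`, or GR100 absent;
* SENSITIVE — `GR100 < Cmax` and `GRmax < −0.5`;
* PARTIAL — everything else, including the exact boundary `GR100 = Cmax`.

The −0.5 GRmax cutoff demands a clearly cytotoxic maximal effect, not mere
growth slowing. `rank_alternatives()` orders drugs by descending Cmax/GR100
with ties kept in registry order (and flagged); the top entry is the
recommended alternative.

## Preliminary-screen rules

Viability at Cmax is `mean(treated)/mean(NC)` per drug, arithmetic mean over
triplicates, no outlier rejection, no day-0 normalisation (the preliminary
stage is an endpoint assay by design). Selection keeps drugs with viability
≤ 0.20 — boundary inclusive, compared without rounding — sorted ascending,
truncated to three. "Most significant inhibitory effects" is read as
point-estimate ranking; no statistical test against NC is described for this
stage, so none is invented. Ties at the truncation boundary break by the
stable order of the drug registry and raise a `"tie-truncated"` advisory
flag; determinism here is a testability requirement, not a scientific claim.

## Concordance with clinical outcome

Neoadjuvant-group patients are scored by the post-surgical JSED histological
grade (grades 2–3 = GOOD response, 0–1a–1b = POOR); treatment-naive patients
by follow-up response. Records with neither are excluded and tallied. The
positive class is fixed to *clinically GOOD responder, predicted sensitive*:
with 10 good responders and 14 non-responders in an evaluable cohort of 24,
this is the only orientation under which sensitivity 80%, specificity 85.7%
and accuracy 83.3% are simultaneously ratios of integers (8/10, 12/14,
20/24) — the mirrored statistics are reported alongside for transparency.
ROC AUC is the rank/pair-counting statistic on the continuous AUCsum (ties
count one half), computed with low AUCsum oriented toward the GOOD class;
`pROC` is used in the test suite as an independent cross-check, never as the
implementation.

## The synthetic generator

No raw plate data are publicly deposited for this screen, so the package
carries a generative model that is the exact inverse of the GR transform.
An organoid is a division rate `k0` (doublings/day), a baseline ATP signal,
and a ground-truth sigmoid per drug. Treated wells grow at
`k(c) = k0 · log2(GR_true(c) + 1)`, giving end-of-treatment signal
`x0 · 2^(k(c)·duration)`; NC wells grow at `k0`. With zero noise,
`gr_value()` applied to a simulated plate returns `GR_true` to machine
precision, and preliminary viability equals
`2^(k0·duration·(log2(GR_true+1) − 1))` — the two stages are mutually
consistent by construction. Measurement noise is multiplicative lognormal
per well (standard for ATP luminescence), mean 1, default CV 0.08 — the
order of magnitude of the replicate SDs reported for this assay class.

Cohort defaults are fixed once to the validated study conditions: 24
evaluable patients, resistant fraction 14/24, NAT fraction 9/26, 4-day
treatment window, triplicate wells. Latent TP-resistant patients draw
near-flat TP truths (`GRinf` ∈ [−0.1, 0.3], `GEC50` 4–50 × Cmax), sensitive
patients strongly cytotoxic ones (`GRinf` ∈ [−0.9, −0.55], `GEC50`
Cmax/50–Cmax/5), and resistant patients additionally carry one potent
off-regimen drug (doxorubicin) so the repurposing path is exercised.
Clinical labels equal the latent class flipped with probability
`label_flip_prob` (default 0). All randomness flows through one seed;
repeated runs are byte-identical.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: spatial plate effects (edge evaporation,
gradients), drug degradation and pharmacokinetics within the well,
drug–drug interactions (AUCsum is additive by definition, synergy and
antagonism are out of scope), intra-tumour heterogeneity of the organoid
population, and label noise structure beyond a symmetric flip. A perfect
concordance on faithful-label synthetic cohorts is a correctness check of
the pipeline, not a claim about clinical accuracy.

## Problem sizes and tolerances

The test suite runs desk-scale: closed-form GR identities exactly; the
normalized-AUC oracle on 1,000 random curves at 1e-12; the decision-tree
partition on 10,000 random metric triples; ROC against all-pairs counting
on instances of n ≤ 50; parameter recovery on 200 noiseless six-point
curves (converged fits recover `GRinf`, `GEC50`, `h` within 1%); and a
24-patient noisy cohort (CV 0.08, faithful labels) required to reach ROC
AUC ≥ 0.95. GR50/GR100 closed forms are checked against bisection at 1e-9
relative tolerance. The analysis scripts under `analysis/` use the same
24-patient cohort.

## Known limitations

* GR metrics need a growing control over the window; very slow cultures
  (few doublings in 4 days) make the transform noisy in practice even
  though the simulator's exponential-growth assumption keeps it exact.
* GR100 values extrapolated far outside the titration are reported for
  ranking continuity but should be read as order-of-magnitude statements.
* The 1.134 threshold is carried verbatim; it is an operating point tuned
  on one cohort, and `youden_threshold()` exists precisely because it
  should be re-derived before use on a different population.
* Only single-interval GR is implemented (one start and one end read); no
  time-course GR, no GR-static/GR-toxic decomposition, no GR AOC.
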