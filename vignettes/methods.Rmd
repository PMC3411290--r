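---
title: "Methods: competing-hazard life tables for imaging radiation risk in lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-hazard life tables for imaging radiation risk in lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphorad)
```

## The question

Imaging follow-up of malignant lymphoma concentrates an unusual amount of
diagnostic radiation on one patient: the paediatric Hodgkin-disease (HD)
protocol implies 12 CTs and 2 PETs within five years of diagnosis, the
adult DLBCL protocol 7 CTs and 1 PET within 2.5 years. The package asks
what that exposure costs in mortality terms — what fraction of patients
will eventually die of a radiation-induced cancer (REID), and how many
days of life expectancy the imaging removes — and, centrally, how those
answers change once the lymphoma's own mortality is allowed to compete
with the late radiation risk.

## Dose accumulation

Per-exam organ doses, effective dose and (CT) total-body dose are carried
for six phantom age categories in `load_dose_table()`. Doses at
intermediate ages are component-wise linear interpolations between
anchors; the table gives no age for its adult column, so the package
anchors it at 18 years — the age bound of the paediatric protocols — and
interpolates linearly from the 15-year anchor (`adult_anchor_age`,
configurable). Exam offsets within the therapy phase are likewise not
published; defaults place the two therapy CTs at 2 and 4 months and the
post-therapy PET at 6 months (children) / 3 months (adults). Cumulative
doses are insensitive to these offsets for adults (dose plateau) and move
by under 1 mSv for children.

One genuine ambiguity deserves note: the tabulated paediatric strategy
assigns 5 whole-body and 7 neck–chest CTs, while the accompanying text
reverses the split. The package defaults to the tabulated assignment —
the one that reproduces the published cumulative doses (its five
whole-body CTs at 0, 2, 4, 36 and 60 months put the two late, higher-dose
exams on the whole-body column) — and exposes the other reading as
`standard_protocol(followup = "swapped")`.

Organ doses are tabulated in mSv; all exposures are photon/positron, so
the equivalent dose equals the absorbed dose numerically (radiation
weighting factor 1) and dose vectors enter the risk models as mGy.

## Risk model

Site-specific excess relative risk for solid-cancer mortality uses the
BEIR VII preferred model form
$$\mathrm{ERR}_s = \beta_{s,\mathrm{sex}}\, d\, e^{\gamma e^*}\,(a/60)^{\eta},
\qquad e^* = \min\{(e-30)/10,\,0\},$$
linear in dose, decaying with attained age $a$, and with risk per unit
dose increasing for younger ages at exposure $e$ up to the age-30
plateau. Leukaemia is linear–quadratic in marrow dose with a time-since-
exposure decay. The fit parameters are bundled in
`err_parameters()` and can be overridden by CSV.

Decisions the source material leaves open:

* **DDREF.** Whether a dose and dose-rate effectiveness factor was applied
  is not recoverable. The package divides solid-site ERR by a default
  DDREF of 1.5 — the committee's own value for low acute doses like these
  (5–35 mSv per exam) — configurable to 1.0 via `risk_config()`.
  Leukaemia is never divided; its curvature already encodes the
  dose-rate effect.
* **Latency.** Defaults of 5 years (solid) and 2 years (leukaemia), the
  conventional values in lifetime-risk calculators; configurable.
* **Thyroid.** No thyroid *mortality* ERR fit exists; the thyroid row
  carries the incidence-model parameters applied to baseline thyroid
  cancer mortality, flagged as an approximation. `thyroid_mode` can
  instead use the other-solid parameters or drop the site. Thyroid
  baseline mortality is tiny, so the choice is immaterial in the bundled
  analyses.
* **Transport.** Pure ERR transport (no ERR/EAR weighting): multiple
  exposures add on the ERR scale and multiply baseline site-specific
  cancer mortality, giving the excess rate
  $M_{rad}(a) = \sum_s \lambda_s(a)\sum_i \mathrm{ERR}_s(d_i, e_i, a)$.
  Sex-specific sites (breast, uterus, ovary, prostate) contribute only
  for the applicable sex.

## The disease hazard

Published survival anchors — 10-year HD survival 94%, 5-year DLBCL
survival 58% — are converted to a constant excess hazard
$h = -\log S(T)/T$ by `calibrate_disease_hazard()`. The time profile of
lymphoma mortality beyond the anchor is not published, and two natural
readings exist: a *cure* model (excess hazard on $[0,T]$, zero after) and
a *lifelong* constant hazard. Both reproduce survival at the horizon
exactly ($S(T) \times S_{background}(T)$), so the horizon-survival row
cannot discriminate them. The published corrected life expectancies can:
a cure model leaves a corrected newborn HD life expectancy within ~5
years of the uncorrected one, whereas the published gap is ~16 years
(5 800–6 600 days of disease-related reduction), which only a hazard
acting over the whole remaining lifetime produces. The package therefore
defaults to the lifelong hazard (`cure_after_years = Inf`) and retains
the cure model as an option. The lifelong reading is epidemiologically
conservative for HD — it ignores late cure — but it is the model the
published corrected columns embody, and the package's comparisons
(`analysis/05_compare_published.R`) are made under it.

## Life-table mechanics

`build_life_table()` follows the cohort from the age at diagnosis to 110
years in annual steps (configurable). Numerical conventions:

* Hazards are evaluated at interval midpoints and held constant over the
  interval, so the death probability is $q = 1 - e^{-\mu\,\Delta}$ —
  exact for piecewise-constant hazards, and keeping annual and monthly
  tables within a fraction of a percent of each other (asserted in the
  test suite).
* Deaths within an interval are attributed to background, radiation and
  disease in proportion to their hazard components — the standard
  competing-risks partition; intervals with zero total hazard attribute
  nothing.
* Life expectancy uses the half-interval (trapezoid) person-year
  convention $\sum_a l(a)(1-q(a)/2)\Delta$; survivors at 110 are treated
  as dying there. REID is the summed radiation-attributed death
  probability. Reductions of life expectancy are differences against
  counterfactual tables with the relevant hazard removed, reported in
  days (365.25 d/y).
* Radiation-induced mortality is *added* to, not subtracted from, the
  background table. The excess is below 10^-3 of background everywhere
  in the bundled analyses, so the double-counting error is negligible.
* Cohort summaries average categories with unweighted arithmetic means,
  consistent with how the published per-age values round to their
  published summary figures (checked in the test suite).

The cohort conservation identity (attributed deaths + survivors = 1, to
1e-9), exactness of the three-age hand-computed worked example
(`make_toy_worked_example()`, matched to 1e-12 against an independent
re-derivation), and the closed-form exponential life expectancy under a
constant hazard are all enforced as tests.

## Synthetic mortality inputs

The analyses need two tables the package cannot redistribute: a
European background all-cause mortality table and Euro-American baseline
cancer mortality by site. The synthetic module emulates both:

* `make_background_table()`: Gompertz–Makeham hazard
  $\mu(a) = c + A e^{ba}$ per sex. Defaults ($c = 8\times10^{-4}$,
  $A = 4\times10^{-5}$, $b = 0.092$ male; $c = 5\times10^{-4}$,
  $A = 1.8\times10^{-5}$, $b = 0.096$ female) were calibrated once to
  life expectancies at birth of 75.9 / 82.1 years, matching the
  European values the published life tables imply.
* `make_cancer_rate_tables()`: per-site power-law-above-onset rates
  $\lambda_s(a) = r_{70}\,((a-a_0)/(70-a_0))^p$, with scales set to a
  realistic Euro-American site mix (male lung ≈ 2.6×10⁻³/yr at 70,
  female breast with earlier onset and shallower rise, leukaemia with a
  small rate from birth), implying lifetime cancer mortality of ~29%
  (male) and ~19% (female). The generator validates that summed cancer
  mortality stays below all-cause mortality at every age.

What the synthetic tables do *not* capture: infant and young-adult
mortality humps (the Makeham term is flat, so synthetic childhood
mortality is slightly high and a corrected paediatric 10-year survival of
93.x% can round to 93 where real Eurostat tables give 94), cohort trends,
country stratification, and the fine age structure of real cancer
registries (the power law underestimates very-old-age plateaus). Passing
the bundled comparisons therefore demonstrates the machinery and the
relative structure of the results — sex ordering, corrected-vs-
uncorrected contraction, paediatric-vs-adult gap — not agreement of
absolute life expectancies, which inherit whatever mortality tables the
user supplies (`load_rate_table()` accepts Eurostat/ICRP-format CSV
exports directly).

## Problem sizes

The bundled analyses run annual life tables (50–110 rows per table, four
tables per category, 16 categories across both diseases and correction
states) and a monthly table in the discretization check; the full test
suite and analysis scripts complete in well under a minute on a single
CPU. These sizes are the analysis as designed — the method is exact given
its inputs, not simulation-limited.

## Known limitations

Morbidity (incidence) risk is out of scope — only fatal outcomes are
counted. ERR parameter uncertainty is not propagated; results are point
estimates. The disease hazard is a single constant per disease: no stage,
subtype, response adaptation or secular survival improvement. Attenuation-
correction low-dose CT, chest radiography and ultrasound are excluded
from the schedules. The printed dose table is taken as given, including
its visible rounding artefacts (identical PET organ doses across adjacent
age categories); interpolation operates on the printed values verbatim.
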