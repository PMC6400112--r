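---
title: "Modelling the costs and benefits of dementia screening with hybrid PET/MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the costs and benefits of dementia screening with hybrid PET/MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demscreen)
```

`demscreen` evaluates a population screening programme for
lifestyle-attributable dementia: an imaging test applied to older adults
with modifiable risk factors, on the premise that detecting future cases
years before cognitive decline enables lifestyle change and therapy that
delay onset. This vignette is the package's own account of its models,
their assumptions, and the design decisions taken where the problem was
genuinely open.

## The decision model

One screened subject has future dementia with probability $p$ and receives
a positive test with probability $Se$ if diseased, $1 - Sp$ if not. Each
of the four outcomes carries a currency consequence per subject:

$$E = U_{TP}\,Se\,p + U_{FP}(1-Sp)(1-p) + U_{TN}\,Sp\,(1-p) + U_{FN}(1-Se)\,p.$$

The utility matrix prices a detected case through two benefit streams that
accrue for each of the $d$ years of delayed onset — averted direct care
costs and a monetised quality-of-life difference — less the therapy given
to all test-positives and the scan price paid by everyone:

* $U_{TP} = (c_{care} + q)\,d - c_{tx} - c_{scan}$
* $U_{FP} = -c_{tx} - c_{scan}$
* $U_{TN} = U_{FN} = -c_{scan}$

where $q$ is the annual QALY value: willingness to pay per QALY (quoted in
base-year USD), inflated to the analysis year, converted to CAD, and
multiplied by the quality-weight difference between the non-demented and
demented states.

```{r}
params <- economic_params()
qaly_annual_value(params)
build_utility_matrix(params)
expected_value(test_characteristics(0.9, 0.9, 0.1), build_utility_matrix(params))
```

Assumptions worth making explicit:

* **A missed case costs only the scan.** $U_{FN}$ carries no penalty for
  the missed diagnosis — the subject simply follows the natural history
  they would have followed unscreened. This is deliberately conservative
  bookkeeping of benefits, not a claim that missing a case is harmless;
  the `fn_penalty` parameter (default 0) prices it if desired.
* **Streams are summed undiscounted.** The five-year care-savings and QALY
  streams enter at face value; `discount_rate` (default 0) applies a
  standard annuity factor when set.
* **The test price, not the test cost, enters the matrix.** The scan is
  booked at its assumed price ($2,000); the independent cost build-up
  below shows this price is conservative.

Two printed-source discrepancies are resolved in favour of the arithmetic:
the converted willingness to pay is $80{,}000 \times 1.10 \times 1.3 =
114{,}400$ CAD (sometimes quoted rounded as 114,000), and the package
computes with full precision throughout, rounding only for display.

### Default parameters

| parameter | default | units | note |
|---|---|---|---|
| `se`, `sp` | 0.9 | — | attainable by current amyloid PET / MRI meta-analytic estimates |
| `p` | 0.1 | — | prevalence of future dementia among screened; matches the ~1-in-10 yield seen in asymptomatic amyloid screening |
| `wtp_base` | 80,000 | USD/QALY (2011) | Scandinavian estimate |
| `inflation_factor` | 1.10 | — | 2% per year to the analysis year |
| `fx_rate` | 1.30 | CAD/USD | |
| `qaly_weight` | 0.348 | — | non-demented vs demented quality difference |
| `delay_years` | 5 | years | achievable onset delay in detected cases |
| `annual_care_savings` | 27,000 | CAD/person/yr | averted direct care cost |
| `therapy_cost_annual` | 4,800 | CAD/person/yr | upper-limit drug estimate |
| `scan_cost` | 2,000 | CAD/exam | assumed screening price |

All defaults live in one place (`default_parameters()`); no numeric
literal is scattered through the code.

## The onset-delay cohort model

`project_cohort()` propagates expected counts of non-demented and demented
persons over single-year ages. A delay of $d$ years is an age-shift of the
incidence schedule, $r_d(a) = r(a-d)$ (ages below the schedule floor get
rate 0) — the standard reading of "delaying age-specific onset by $d$
years". Within each simulated year the order of operations is fixed:

1. **incidence** among the non-demented at the (shifted) age-specific rate,
2. **mortality** — all-cause for the non-demented, all-cause × hazard
   ratio for the demented,
3. **aging** by one year, with an absorbing top age and zero entry cohorts.

The source material is silent on intra-year ordering; one defensible
convention is chosen and documented rather than left implicit. Rates per
1,000 person-years are used directly as annual probabilities (clamped at
1), adequate at the magnitudes involved. The model is deterministic; a
binomial-draw mode (`stochastic = TRUE`, seed required) exists for
variance exploration. Expected-count propagation was chosen over
individual-level simulation because the published anchors are aggregate
counts, expectations reproduce them exactly, and the model becomes
testable against closed-form difference equations to machine precision.

Entry cohorts default to zero, making this a *closed cohort* — a real
simplification (no immigration, no one turns 40 after the start year)
whose consequences the calibration below absorbs.

## Demographic arithmetic

Age bands are printed inclusively ("60–79") and handled internally as
half-open intervals $[lo, hi+1)$; an open-ended top band is `Inf`. Rates
are uniform within a band, so intersecting bands apportion counts linearly
in overlap width. Percentages reproduce printed tables under round-half-up
to one decimal; the per-scan cost is *truncated* to whole CAD (1,136.67 →
1,136) and scanner counts *round half-up* — each the unique convention
consistent with all printed values. One printed growth-ratio cell (Canada
80+, 1.937) appears itself truncated rather than rounded, so the
table-reproduction test compares ratios at an absolute tolerance of 1e-3.

The published anchor incidence rates (3.9 per 1,000 person-years at 60–64,
104.8 at 90+) are not exactly consistent with a single 6.3-year doubling
time (pure doubling from 62 gives ≈ 85 at 92). `doubling_schedule()` is
therefore offered as a generator of plausible schedules through one
anchor, not as a reproduction of any printed table. Similarly, the probe
cost is a direct parameter (default $500/exam) rather than derived from
the production-run arithmetic, whose printed inputs ($3,000 split over 10
subjects) do not reproduce it.

## The synthetic scenario generator

`generate_scenario()` emulates the inputs the cohort model needs:

* a population declining exponentially with age (`pyramid_decline`, default
  0.05/year — steeper than a mid-life cross-section because it blends the
  survivorship-driven collapse of the old-age pyramid into a single rate);
* incidence following the exponential age-doubling form through the
  3.9-at-62 anchor, or a sex-specific preset interpolating log-linearly
  through the printed female/male anchor rates at 40–44, 70–74 and 95+
  (exact at those bands; the female rate overtakes the male near age 82);
* Gompertz-like all-cause mortality, 10/1,000 person-years at 60 doubling
  every 8 years — **invented**: no mortality rates accompany the published
  dementia schedules, and these defaults matter only through the
  trajectory shapes they induce;
* an initial demented share per age equal to the *stationary cohort
  composition* of the scenario's own dynamics (a single cohort followed
  from the youngest age under the same ordering of operations — the fixed
  point a long burn-in converges to), scaled by
  `initial_prevalence_scale = 0.7`.

That last default deserves its justification. In a closed cohort whose
population profile declines at the same rate the life table does, starting
*at* the stationary composition makes total prevalence exactly flat — the
observed near-doubling of diagnosed prevalence over 20 years is
structurally unreachable. Two real features break the stalemate: diagnosed
prevalence runs some 30% below the level the dynamics sustain
(under-diagnosis is documented in the Canadian administrative data the
anchors come from), and the real age pyramid is steeper than endogenous
mortality alone implies. The generator encodes both, as defaults chosen
once on those grounds.

### Calibration

`calibrate_to_anchors()` tunes exactly two shape knobs — the overall
incidence scale and the dementia mortality hazard ratio — by a grid over
the hazard ratio with golden-section search over the log incidence scale,
then rescales the total population (a pure unit choice) to the anchor
levels by least squares. Two anchors leave the two knobs under-determined:
distinct (scale, hazard-ratio) pairs can fit the same 20-year growth
factor. Among candidates within tolerance the calibration prefers the one
that rescales the published incidence curve least (minimal
$|\log s|$) — a parsimony rule that also selects the epidemiologically
sensible branch, since diagnosed dementia carries substantial excess
mortality and diagnosed incidence runs below community incidence.

```{r, eval = FALSE}
cal <- calibrate_to_anchors(scenario_spec(),
  data.frame(year = c(2011, 2031), prevalence = c(340000, 674000)))
attr(cal, "calibration")$residual   # ~1e-7
```

On the calibrated scenario the baseline run reproduces the published
340,000 → 674,000 doubling; a five-year delay yields a 2031 prevalence
within a few percent of the published delayed projection, a growth factor
near 1.17 (published: 1.10) and a prevalence reduction of ~41% (published
estimates: 44–50%). These are properties of the synthetic cohort, not
reproductions: the underlying national micro-simulation (individual risk
factors, immigration, time-varying mortality) is not public, and the test
suite asserts the wide bands, not the point values. The published "45%
decrease of prevalence" is itself computed from cases *in care*
((522−291)/522 = 44.3%) though labelled prevalence ((674−374)/674 =
44.5%); `prevalence_reduction()` exposes both via its `measure` argument.

What passing these tests shows is that the delay machinery behaves
correctly on a cohort with the right gross structure — not that the
synthetic population matches any real one in detail (no migration, no
cohort-specific mortality trends, single-sex by default, time-invariant
rates).

## Sensitivity analysis

* **Sweeps and tornado tables** re-evaluate $E$ exactly; sweeping
  `delay_years` (or `therapy_cost_annual`) rescales total therapy cost
  with the delay, so $E(d)$ is affine with $E(0) = -c_{scan}$ and a
  break-even near $d = 0.39$ years at the defaults.
* **Thresholds** use bisection on the parameter's domain (probabilities on
  their natural bounds, delay on [0, 10] years, monetary parameters on
  [0, 10× base] as a generous finite interval), after a 21-point
  monotonicity check; non-monotone cases error explicitly, and a function
  that never crosses the target reports `"none in domain"`. Tolerance
  1e-6 relative, 200-iteration cap.
* **PSA** draws each parameter from its `dist_spec`: beta for
  probabilities (method-of-moments from mean and sd), lognormal for
  costs (natural-scale moments), uniform or point for anything —
  standard health-economics practice, since the source analysis states a
  point estimate only. One seed governs a single stream and parameters
  are drawn in sorted-name order in contiguous blocks, so results do not
  depend on the order specs are supplied. Point-mass specs reproduce the
  deterministic model exactly; truncation at zero applies to normal draws
  for non-negative parameters.

## Numerical conventions and problem sizes

Ties round away from zero everywhere a printed value is reproduced
(`round_half_up()`), since IEEE round-half-even disagrees on exact ties.
Counts are stored as plain reals; the packaged tables are in thousands as
printed, converted at the point of use. The test suite runs the cohort
model on populations of $10^6$–$2\times 10^6$ over 15–20 year horizons and
checks the decision model against Bernoulli simulations of $10^5$–$10^6$
subjects — sizes at which Monte-Carlo error is a few hundred CAD against
an expected value of ~24,000, and the whole suite completes in well under
a minute.

## Limitations

* The screened pool is treated as steady-state annual incidence; prior
  negative screens do not deplete it, and annual rescreening is the
  default (the `rescreen_interval_years` parameter halves demand at 2).
* The expected value applies to no specific jurisdiction: willingness to
  pay, care costs and therapy costs are drawn from different countries'
  literatures, exactly as in the source analysis.
* The cohort model is closed and time-invariant; it reproduces aggregate
  anchors, not the underlying individual-level dynamics.
* Scanner-physics questions (sensitivity, resolution, time-of-flight gain)
  are out of scope; only their economic consequences (dose, throughput,
  unit price) enter.
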