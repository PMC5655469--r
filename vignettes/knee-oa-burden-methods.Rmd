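---
title: "Methods: microsimulating the lifetime QALY burden of knee osteoarthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulating the lifetime QALY burden of knee osteoarthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaburden)
```

## The model

`oaburden` estimates the quality-adjusted life years (QALYs) lost over the
remaining lifetime of an adult population because of knee osteoarthritis
(OA). The population is tiled into 36 strata — nine 5-year age bands
covering ages 40–84, by sex and by ethnicity (Māori / non-Māori) — and for
every stratum two cohorts are simulated individual by individual: one with
prevalent knee OA, one without. A cohort enters at its band midpoint (an
integer age, e.g. 42 for 40–44) and each individual then passes through
annual cycles until death:

1. **Pain.** With OA, the individual's WOMAC pain score (0–100, 100 worst)
   advances by a normal annual increment and is collapsed into one of three
   severity levels: *no pain* (WOMAC < 1), *moderate* (1–70, a closed
   interval), *severe* (> 70). Without OA, a pain level is drawn from an
   age-band prevalence curve: in pain with probability `p_in_pain(band)`,
   and of those a share `moderate_share` (default 0.90) moderate, the rest
   severe.
2. **Utility.** The year begun accrues the full EQ-5D utility for the
   individual's current age band and pain level. There is no half-cycle
   correction and no discounting: the quantity of interest is health burden,
   not a discounted cost-effectiveness ratio, and QALYs are defined here as
   the plain sum of yearly utilities.
3. **Mortality.** Death is applied at year end with the annualised
   life-table probability (below). Life tables are closed at age 110
   (probability 1), so every simulated life is finite.

Averaging individual QALY totals within a stratum estimates its
quality-adjusted life expectancy (QALE), with a Monte Carlo standard error
reported alongside.

### From QALE to burden

For an ethnicity × sex group, the headline quantity is

> per-person loss = (counterfactual QALE) − (QALE with OA),

where both terms are weighted over age bands by the *age distribution of
prevalent OA cases* (prevalence × population counts, normalised). The
counterfactual term answers: what QALE would the people who have knee OA
have had without it? The whole-group "QALE without OA" column, by contrast,
is weighted by the full population age distribution — it describes the
general population, not the OA sub-population, and is reported for context
only. Population losses multiply the per-person loss by the number of
prevalent cases; band, group, and grand-total rows satisfy exact aggregation
identities (`build_burden_tables()` and its tests).

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| WOMAC initial mean / SD | points | 30 / 15 | mild-to-moderate prevalent OA pain with wide variation |
| annual increment mean / SD | points/yr | 0.5 / 5 | slowly progressing, relatively stable trajectories |
| pain level cuts | points | <1, 1–70, >70 | published categorisation; both edges read as stated |
| non-OA moderate share | — | 0.90 | base case; the PSA's uncertain parameter |
| transform exponent α | — | 1.61 | `u' = 1 − (1−u)^α`; see below |
| life-table closure | years | 110 | forces finite lifetimes; survival reaches 0 there |
| interval level (PSA) | — | 0.95 | empirical quantiles of the draws |

Out-of-range normal draws are **clamped** to [0, 100], not resampled: the
stated mean/SD stay meaningful as nominal parameters and every score remains
valid. Clamping shifts the initialisation mean by less than 0.05 points at
the defaults (the clamped-normal closed form is checked in the tests).

The utility table ends at band 80–84 while individuals survive beyond it;
ages above 84 reuse the 80–84 row (last observation carried forward — the
minimal assumption given no data beyond the table).

### The value-set transform

VAS-elicited EQ-5D values are known to sit lower than trade-off-based
(standard-gamble) valuations of the same states. The package maps between
them with the power transform `u' = 1 − (1 − u)^α`: α > 1 moves every
utility up toward 1 with 0 and 1 as fixed points, preserving the
within-band severity ordering and *compressing* the utility gaps between
pain levels — which is why transformed losses are systematically smaller
than VAS losses (the paired-seed comparison in the acceptance tests). The
published functional form behind the transformed values is not available, so
the exponent is configurable (default 1.61) and a fully transformed table
can be supplied directly as an input instead.

## Mortality and its annualisation

Life tables carry 5-year death probabilities `q5` per stratum band. Cycles
are annual, so `q5` is converted assuming a constant hazard within the band:

```
q1 = 1 − (1 − q5)^(1/5)
```

This is standard actuarial practice, exactly invertible (compounding five
annual cycles recovers `q5`), and tested by that inversion. Individuals age
across band boundaries mid-simulation; the mortality row, utility row, and
(for non-OA individuals) the pain draw update at band entry. Drawing the
non-OA pain level once per band occupancy rather than annually avoids
artificial year-to-year churn while still tracking the age trend; only the
band-level population distribution of pain is specified, so any within-band
persistence assumption is admissible and this is the simplest.

## Random numbers and reproducibility

All randomness flows from one master seed. Each individual draws from a
substream keyed by (master seed, stratum, individual index) through a
multiplicative hash, so results are independent of execution order and a
cohort of 100 is a strict prefix of a cohort of 200. The cohort arm is
deliberately *not* part of the key, and each stream draws its mortality
uniforms first (fixed count): matched OA / no-OA individuals therefore share
their death year, giving common-random-number pairing for the ordering
checks, and the no-OA arm's pain draws are identical across values of the
moderate-pain share. The PSA exploits this: the share enters only through
the pain-level thresholds, so OA cohorts are simulated once, the no-OA
cohorts' parameter-independent structure (death year, band occupancy,
per-band uniforms) is precomputed, and each prior draw re-thresholds it —
exactly equivalent to a full re-run under shared streams (asserted in the
tests via the degenerate prior). End-to-end pipeline runs with a fixed seed
are byte-identical.

## The synthetic generators

The analysis consumes four inputs that are not published with it; the
generators emulate their statistical structure:

* **Life tables** — Gompertz hazard `h(a) = level · e^{shape·a}` integrated
  in closed form over each band. Defaults were calibrated once to plausible
  national remaining life expectancies at 40 (non-Māori ≈ 39.7 M / 43.2 F
  years; Māori ≈ 32.8 M / 36.0 F years; shape 0.09), encoding the mortality
  differentials that drive the group ordering of losses. Monotonicity in
  age, closure, and agreement with numerical quadrature are tested.
* **Population counts** — geometric thinning with age (factor 0.85/band),
  sex split 0.51 female, Māori share 0.13, total 1.9 million aged 40–84;
  expected counts are rounded half-to-even for determinism.
* **Prevalence** — `base · slope^band` (defaults 0.01, 1.45), rising from
  ~1% to ~20% across bands like the published surface. The packaged
  published prevalence (PPV-adjusted) is the default for analysis runs.
* **Non-OA pain curve** — logistic in age through anchors 30% at 40 and
  55% at 85, deliberately on the high side as general-population pain
  surveys suggest; fully overridable from file.

What the generators do **not** emulate: cohort effects and period trends in
mortality, within-group heterogeneity in prevalence (the synthetic surface
is identical across sex/ethnicity), correlation between OA status and
mortality, and BMI (carried nowhere — no mechanistic pathway is specified).
Passing tests on synthetic inputs therefore validate the *machinery* —
arithmetic identities, monotonicities, convergence to closed forms — not the
absolute published magnitudes, which depend on the unpublished national
inputs.

## Numerical choices

* Pain-category boundaries are closed as stated: exactly 1 is moderate,
  exactly 70 is moderate, 70.01 severe.
* The WOMAC walk is computed by vectorised cumulative sum when the unclamped
  path stays inside [0, 100] (the common case), falling back to the exact
  sequential clamp otherwise — identical results, tested boundaries.
* PSA intervals are empirical quantiles with linear interpolation of order
  statistics (R's type 7), checked against a sorting-based oracle.
* Internal arithmetic is full double precision; published-table comparisons
  use the tables' two-decimal display precision (±0.01).
* Age-band labels are written with an ASCII hyphen; the reader normalises
  en- and em-dashes, BOMs, and CRLF endings, so typeset variants parse
  identically.

## Open design decisions taken

* **Counterfactual cohort**: the no-OA cohort never develops incident knee
  OA — it represents the "did not have knee OA" counterfactual, not a
  disease-free-at-baseline population at risk. The alternative would need an
  incidence model that is not specified here.
* **First cycle**: the initial WOMAC draw applies to the first year; the
  annual increment starts with the second year.
* **Prevalence is baseline-fixed** (closed cohorts of the base-year
  population, no new entrants), matching a burden snapshot of prevalent
  cases followed until death.
* **PPV adjustment** is multiplicative with a configurable scalar or
  per-group PPV (default 0.9). Note that a *scalar* PPV cancels out of the
  OA age weights, so it moves population losses (by 1/PPV) but not
  per-person losses; stratum-specific PPVs are required for the latter and
  can be supplied.

## Problem sizes

Default analysis runs use 1,000–2,000 individuals per stratum per arm
(Monte Carlo SE on group losses well under 0.1 QALYs); the simulator-vs-
closed-form agreement checks run at 20,000 replicates per configuration;
the PSA default is 500 draws, run at 200 draws × 150–300 individuals per
stratum in the test suite. These sizes were chosen so that the Monte Carlo
error bounds asserted by the tests (4 SE) are meaningfully tight.

## Limitations

* Absolute magnitudes depend on inputs the package can only emulate (life
  tables, census counts, the non-OA pain curve, stratum-specific PPVs);
  with synthetic defaults the outputs are structurally faithful, not
  national estimates.
* No treatment pathways, joint replacement, radiographic progression, or
  incident OA; pain is the only OA attribute carried.
* Utilities are cross-sectional population means per (band, level); no
  individual-level utility heterogeneity beyond pain level.
* Mortality is independent of OA status and pain, so the burden is entirely
  a quality-of-life, not a length-of-life, loss.
```{r demo, eval = FALSE}
# a small end-to-end run (seconds)
fit <- oa_burden(n_per_stratum = 200, seed = 42)
summary(fit)
plot(fit)
```
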