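---
title: "A six-phenotype evolutionary model of bone-metastatic prostate cancer under standard-of-care therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A six-phenotype evolutionary model of bone-metastatic prostate cancer under standard-of-care therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psadapt)
```

## The model

`psadapt` simulates bone-metastatic prostate cancer (BMPCa) as six
competing cell phenotypes sharing one bone-marrow niche: treatment-naive
cells (`NAIVE`, sensitive to every therapy), clones resistant to first- or
second-generation androgen deprivation therapy (`ADT1R`, `ADT2R`),
chemotherapy-resistant clones (`CTR`), and the doubly resistant
combinations (`ADT1R_CTR`, `ADT2R_CTR`). Time advances in whole days.
Each clone $T$ follows a discrete logistic recurrence

$$T_{d+1} = T_d + \left(1 - \frac{T_{\mathrm{total}}}{C_{\mathrm{cap}}}\right)(p - a)\,T_d,$$

where $p$ and $a$ are the clone's daily proliferation and apoptosis
fractions, $T_{\mathrm{total}}$ is the pre-step sum over all six clones
(every clone sees the same logistic factor), and $C_{\mathrm{cap}}$ is
the shared carrying capacity. While a therapy is active, each sensitive
clone is additionally reduced by a daily kill fraction $H_x$,

$$T_{d+1} = T_d - H_x\,T_d,$$

applied after growth, and a fraction $\mu$ of the surviving sensitive
cells converts to the matching resistant phenotype (mutation conserves
total cell number exactly). Surgery and radiotherapy are one-time debulk
events that remove the same fraction of every clone: they reduce burden
without touching heterogeneity and create no resistance, as does
bisphosphonate palliation.

Serum PSA is the observable. The model treats it as a strictly linear
proxy for burden: one metastatic cell contributes $9.8\times10^{-9}$
ng/mL per 24 h, so 10 ng/mL corresponds to $1.02041\times10^{9}$ cells.
Counts are continuous non-negative reals (a deterministic mean-field
model); there is no stochastic birth–death component, so every function
in the package is reproducible bit-for-bit from its inputs.

## Parameters, units, and defaults

All constants live in `model_params()` and can be set from a YAML/JSON
configuration file (`load_config()`; the shipped
`inst/extdata/default_config.yaml` is a tested fixture equal to the
defaults).

* `psa_per_cell = 9.8e-9` ng/mL per cell per day — derived from reported
  PSA production per gram of carcinomatous tissue and typical cell mass.
* `ccap_psa = 1000` ng/mL — the carrying capacity, expressed in PSA
  units and converted exactly: `ccap_cells = 1000 / 9.8e-9` ≈
  $1.02\times10^{11}$ cells. Defining the capacity in PSA units makes
  the model self-consistent: the logistic factor at presentation
  (10 ng/mL) is exactly $1 - 10/1000 = 0.99$, and untreated growth
  plateaus at exactly 1000 ng/mL, which doubles as the conjectured
  clinical endpoint ("theoretical survival").
* `mutation_rate = 5e-7` per cell per day (0.00005%) — the probability
  that a cell surviving a matched therapy acquires resistance to it that
  day. Mutation is treatment-conditioned only; we do not model a
  background (off-treatment) conversion rate, so a never-treated tumor
  stays 100% naive forever.
* Growth rates are per-day *fractions*, not percents: naive cells use
  $p = 0.0204$, $a = 0.0076$. `ADT1R` uses the measured pre-abiraterone
  proliferative/apoptotic indices ($0.0242/0.0168$); `ADT2R` uses the
  post-abiraterone indices ($0.0109/0.0002$), which also serve as the
  growth-rate override for `ADT1R` cells while second-generation ADT is
  active. The remaining rate-table cells are not experimentally
  determined; we encode chemotherapy resistance as a growth cost of
  0.005/day of proliferation relative to the chemo-sensitive
  counterpart. These placeholders are configuration values, clearly
  separated from measured ones in the default config file.
* Kill fractions: ADT1 and ADT2 remove 3%/day of each sensitive clone
  (a configuration default chosen so that therapy outpaces naive net
  growth of 1.28%/day, producing the expected decline-then-escape
  kinetics). Chemotherapy kill is proportional to division attempts,
  $H_{CT} = k_{CT}\,p$ with $k_{CT} = 1.5$.
* Bisphosphonates are purely palliative: every clone's proliferation is
  multiplied by $1 - 0.3$ while they are given. We deliberately model
  them as growth damping rather than as a kill: any uniform positive
  kill would create a stable equilibrium strictly below the carrying
  capacity, whereas the damped tumor still grows toward capacity —
  matching the clinical observation that bisphosphonates palliate
  without improving survival — and keeps the endpoint reachable under
  palliative care.
* Debulk events default to removing 90% of all cells (the magnitude of
  a surgical/radiotherapy debulk is not experimentally constrained; it
  is a per-event field in the regimen schema).

## Numerical choices

* **Update order** within a day is growth → kill → mutation → debulk.
  Growth-then-kill and mutation-of-survivors are dictated by the model's
  construction; placing scheduled debulk events at the end of the day is
  our choice, made for determinism. The therapy administered on day $d$
  takes effect in the record of day $d+1$; intervals are half-open
  `[start_day, end_day)` in 0-based days from presentation.
* **Endpoint detection.** The discrete logistic recurrence approaches
  $C_{\mathrm{cap}}$ strictly from below, so a trajectory that saturates
  at capacity never satisfies PSA $\ge$ 1000 exactly in floating point.
  `time_to_endpoint()` therefore fires at the first day with PSA
  $\ge 1000(1 - 10^{-6})$; an exact crossing still returns its own day,
  and the tolerance is a scheduler parameter.
* **Clamping.** Counts are clamped at zero after the growth step; with
  all default rates this is never triggered (for net rates below 1 the
  logistic map cannot overshoot the capacity or undershoot zero), it
  only guards pathological user-supplied rates.
* **Ties.** The scheduler breaks ties between equally large clones by
  the fixed phenotype order (naive first); calibration breaks equal
  distances toward the lower resistant fraction, a conservative clinical
  prior (both are flippable).

## Calibrating initial heterogeneity

At presentation the tumor is assumed to be a blend of naive and `ADT1R`
cells only. `calibrate_patient()` simulates the 11 canonical mixes
(100:0, 90:10, …, 0:100) from the patient's first PSA measurement under
their recorded regimen and ranks them by the Euclidean distance between
the predicted PSA curve and the measured history, evaluated at the exact
measurement days in linear PSA space (a log-space option exists but is
not the default; the linear choice weights the late, high-burden part of
the course most heavily, which is where scenarios diverge). Because
every scenario is anchored to the first measurement, the day-0 residual
is always zero, and a single-measurement record is ill-posed (flagged
with a warning; the tie-break then selects 100% naive).

```{r calibration}
reg <- treatment_regimen(data.frame(kind = c("ADT1", "ADT2"),
                                    start_day = c(0, 280),
                                    end_day = c(280, 560)))
vp <- make_virtual_patient(synth_spec(
  initial_mix = c(NAIVE = 0.6, ADT1R = 0.4), regimen = reg,
  measurement_days = seq(0, 560, 56), noise_sigma = 0))
cal <- calibrate_patient(vp$record)
cal$scenarios[1:3, ]
```

## The resistance-informed scheduling algorithm

`run_adaptive()` implements a cyclic intervention policy with 28-day
cycles (21 days of therapy, 7-day holiday, both configurable). At each
cycle start, if total burden exceeds the cell equivalent of 1 ng/mL of
PSA ($1.02\times10^{8}$ cells), the algorithm applies the single therapy
targeting the *largest* clone: naive → ADT1, `ADT1R` → ADT2, `ADT2R`
(resistant to all ADTs) → chemotherapy, and pan-resistant disease →
bisphosphonate palliation. The mapping for `CTR` and `ADT1R_CTR` is not
dictated by the four clinical cases, so we assign the first-line ADT
still effective against them (ADT1 and ADT2 respectively), consistent
with the largest-susceptible-population principle; the whole map is a
configuration value. Below the threshold the entire cycle is a holiday,
and re-evaluation happens only at cycle boundaries (the holiday week is
part of the cycle, never a re-trigger opportunity). The holiday cadence
applies uniformly to all therapies.

```{r scheduler}
run <- run_adaptive(tumor_state(psa_to_cells(10) * c(NAIVE = 0.9, ADT1R = 0.1)))
run
```

With default parameters this run reaches the 1000 ng/mL endpoint at day
`r run$endpoint_day`, versus day
`r time_to_endpoint(simulate_tumor(c(NAIVE = 0.9, ADT1R = 0.1), 10, treatment_regimen(data.frame(kind = "ADT1", start_day = 0, end_day = 10000)), horizon = 10000))`
under sustained first-line ADT and day
`r time_to_endpoint(simulate_tumor(c(NAIVE = 0.9, ADT1R = 0.1), 10, horizon = 4000))`
untreated: cycling therapies on and off preserves a treatment-sensitive
population that competitively suppresses resistant clones within the
shared carrying capacity.

## What the synthetic cohort does and does not emulate

Real calibration targets are sparse, irregular serum PSA draws from
patients under interval-based regimens. `make_virtual_patient()`
reproduces that record *structure*: a known naive:`ADT1R` ground truth is
forward-simulated under a regimen, sampled at the specified measurement
days (default every 56 days), and corrupted with multiplicative
lognormal noise $\exp(N(0, \sigma^2))$, $\sigma = 0.1$ by default, with
observations floored at 0.01 ng/mL. The noise model is our choice — the
deterministic model itself has none — and is meant to stand in for assay
and physiological variability. The generator does *not* imitate real
cohorts' PSA magnitudes, censoring patterns, per-patient rate
variability, or departures from PSA–burden linearity (late-stage tumors
may secrete less PSA per cell). Passing recovery tests on this cohort
therefore demonstrates that the calibration machinery inverts the model
it assumes, not that the model captures any individual patient.

## Problem sizes used in the tests

The shipped test suite exercises: single-clone oracle agreement over
5000 days; untreated growth to capacity over 10,000 days; exact recovery
of all 11 grid mixes under three regimens (one with a debulk event);
noisy recovery over 200 replicates of 12 measurements in 600 days
($\sigma = 0.1$, success = within one grid step, required in at least
90%); and a 20-patient cohort comparison in which the median
time-to-endpoint under the adaptive policy must not fall below the
median under each patient's best sustained monotherapy over a
10,000-day horizon.

## Known limitations

* No pharmacokinetics, dose intensity, toxicity, or chemotherapy-cycle
  caps; one therapy at a time (no combinations), per the model's scope.
* The initial-heterogeneity grid spans naive vs `ADT1R` only; other
  resistant clones exist at presentation only if the configuration says
  so, and emerge otherwise solely through treatment.
* Growth rates are fixed per phenotype; there is no inter-patient rate
  variation and no data fitting of rates — only the initial mix is
  estimated, by grid search, so the estimate is never finer than 10
  percentage points.
* PSA linearity is assumed throughout; any biomarker with a per-cell
  production constant could be substituted via `psa_per_cell`.
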