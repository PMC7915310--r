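# psadapt

Simulation, calibration, and treatment-scheduling tools for the
evolutionary dynamics of bone-metastatic prostate cancer (BMPCa) under
standard-of-care therapy, using serum PSA as a linear proxy for tumor
burden.

Recurrent prostate cancer responds to androgen deprivation therapy
(ADT), but resistant subclones inevitably emerge. `psadapt` is for
modelers and clinical researchers who want to (i) track the unseen
clonal composition of a patient's disease from nothing more than routine
PSA measurements and a treatment history, and (ii) explore how
re-ordering and cycling the *existing* standard-of-care therapies could
delay the emergence of pan-resistant disease.

## The model

Six phenotypes — treatment-naive (`NAIVE`), first- and second-generation
ADT-resistant (`ADT1R`, `ADT2R`), chemo-resistant (`CTR`), and the
doubly resistant `ADT1R_CTR`, `ADT2R_CTR` — compete for one logistic
carrying capacity. Per day, each clone *T* updates as

    T[d+1] = T[d] + (1 - Ttotal/Ccap) * (p - a) * T[d]     (growth)
    T[d+1] = T[d] - Hx * T[d]                              (kill, if sensitive)

followed by mutation of a fraction μ = 5e-7 of surviving sensitive cells
into the matching resistant phenotype. One cell produces 9.8e-9 ng/mL of
PSA per day, so 10 ng/mL ≡ 1.02041e9 cells; the carrying capacity is the
cell equivalent of 1000 ng/mL, which doubles as the conjectured clinical
endpoint. Surgery/radiotherapy are one-time debulks that preserve
heterogeneity; bisphosphonates palliate (damp everyone's proliferation)
without creating resistance.

On top of the simulator sit:

* **Calibration** (`calibrate_patient()`): simulates the 11 canonical
  initial naive:`ADT1R` blends (100:0 … 0:100 in 10% steps) under the
  patient's recorded regimen and ranks them by Euclidean distance to the
  PSA history — an estimate of resistance at presentation.
* **Scheduling** (`run_adaptive()`): a resistance-informed
  intervention-decision algorithm; every 28-day cycle (21 on / 7
  holiday) it applies the one therapy hitting the largest subpopulation,
  or none while burden is below the cell equivalent of 1 ng/mL.
* **Virtual patients** (`make_virtual_patient()`, `make_cohort()`):
  seeded synthetic PSA records with known ground truth for testing
  calibration and scheduling without clinical data.

## Worked example

```r
library(psadapt)

# A presenting PSA of 10 ng/mL, 100% naive, untreated:
traj <- simulate_tumor(c(NAIVE = 1), psa0 = 10, horizon = 3)
round(traj$psa_ng_ml, 4)
#> [1] 10.0000 10.1267 10.2550 10.3849
```

Day 1 adds 1.29306e7 cells (1.02041e9 × 0.0128 × 0.99), i.e. ~0.1 ng/mL
of PSA — the model's anchor arithmetic. Left alone for 10,000 days this
tumor plateaus at the 1000 ng/mL carrying capacity.

Calibrating a noisy synthetic patient (truth: 60% naive / 40% ADT1R,
ADT1 for 280 days then ADT2, PSA drawn every 56 days with 10%
multiplicative noise):

```r
reg <- treatment_regimen(data.frame(kind = c("ADT1", "ADT2"),
                                    start_day = c(0, 280), end_day = c(280, 560)))
vp  <- make_virtual_patient(synth_spec(c(NAIVE = 0.6, ADT1R = 0.4),
         regimen = reg, measurement_days = seq(0, 560, 56),
         noise_sigma = 0.1, seed = 11))
calibrate_patient(vp$record)
#> Calibration for patient SYN001: best initial mix 60% naive : 40% ADT1R (distance 4.572)
```

The distance ranking separates adjacent 10%-steps cleanly: the true mix
wins at distance 4.57 against 9.54 for the runner-up (50:50).

Scheduling for a patient presenting at 10 ng/mL with 90:10
naive:ADT1R disease:

```r
run <- run_adaptive(tumor_state(psa_to_cells(10) * c(NAIVE = 0.9, ADT1R = 0.1)))
run$endpoint_day
#> [1] 6473
```

The algorithm cycles ADT1, transitions to ADT2 as `ADT1R` expands, then
to chemotherapy, and finally alternates chemotherapy with bisphosphonate
palliation. The same tumor reaches the 1000 ng/mL endpoint at day 1449
untreated and at day 2798 under sustained ADT1 monotherapy — the cyclic,
resistance-informed sequence more than doubles the theoretical time to
endpoint by preserving treatment-sensitive competitors inside the shared
niche.

## Command line

A thin wrapper over the same functions (see `inst/cli/psadapt.R`):

```sh
Rscript inst/cli/psadapt.R simulate --psa0 10 --mix naive=1.0 --days 30 --out traj.csv
Rscript inst/cli/psadapt.R calibrate --patient patient.json --out report.csv
Rscript inst/cli/psadapt.R optimize --mix naive=0.9,adt1r=0.1 --psa0 10 \
        --out-schedule sched.csv --out-trajectory traj.csv
Rscript inst/cli/psadapt.R synth --n 5 --seed 7 --out-prefix cohort/vp
```

Every subcommand accepts `--config <yaml|json>`;
`inst/extdata/default_config.yaml` documents every constant. Trajectory
CSVs have the fixed column order `day, naive, adt1r, adt2r, ctr,
adt1r_ctr, adt2r_ctr, total_cells, psa_ng_ml, active_treatment` and are
written in full precision for bit-stable round trips; the resolved
configuration hash is logged with each run.

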