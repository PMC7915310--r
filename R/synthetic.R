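# Virtual patients with known ground truth: sparse, irregular PSA sampling
# under interval-based regimens with optional multiplicative noise.

#' Specification of a virtual patient
#'
#' Defines the ground truth from which a synthetic PSA record is
#' generated: the initial naive:ADT1R blend, presentation PSA, treatment
#' regimen, measurement days, and a multiplicative lognormal measurement
#' noise `exp(N(0, sigma^2))` (the model itself is deterministic; noise
#' emulates assay and physiological variability in serum PSA draws).
#' The default cadence of one draw every 56 days (two treatment cycles)
#' emulates sparse clinical PSA monitoring.
#'
#' @param initial_mix Named fractions over phenotypes summing to 1.
#' @param psa0 Presentation PSA, ng/mL.
#' @param regimen A [treatment_regimen()].
#' @param measurement_days Strictly increasing integer days starting at 0.
#' @param noise_sigma Lognormal sigma (0 = noise-free).
#' @param seed Integer RNG seed; generation is reproducible given the seed.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(initial_mix = c(NAIVE = 0.9, ADT1R = 0.1),
                       psa0 = 10,
                       regimen = default_cohort_regimen(),
                       measurement_days = seq(0L, 560L, by = 56L),
                       noise_sigma = 0.1,
                       seed = 1L) {
  mix <- .full_counts(initial_mix)
  if (abs(sum(mix) - 1) > 1e-8) stop("initial_mix fractions must sum to 1")
  measurement_days <- as.integer(measurement_days)
  if (length(measurement_days) == 0 || measurement_days[1] != 0 ||
      any(diff(measurement_days) <= 0))
    stop("measurement_days must be strictly increasing and start at 0")
  stopifnot(psa0 >= 0, noise_sigma >= 0)
  structure(list(initial_mix = mix, psa0 = psa0, regimen = regimen,
                 measurement_days = measurement_days,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default regimen template for synthetic cohorts
#'
#' A standard-of-care-like sequence: 1st-generation ADT from presentation,
#' switched to 2nd-generation ADT at day 280.
#'
#' @return A [treatment_regimen()].
#' @export
default_cohort_regimen <- function() {
  treatment_regimen(intervals = data.frame(
    kind = c("ADT1", "ADT2"),
    start_day = c(0L, 280L),
    end_day = c(280L, 560L)))
}

#' Generate one virtual patient with known ground truth
#'
#' Forward-simulates the spec's ground truth under its regimen, samples
#' PSA at the measurement days, applies multiplicative lognormal noise
#' (observations floored at 0.01 ng/mL), and returns the patient record
#' together with the truth. The generating trajectory is never exposed to
#' calibration; it exists so tests can score recovery.
#'
#' @param spec A [synth_spec()].
#' @param params [model_params()].
#' @param patient_id Identifier for the record.
#' @return List with `record` (a [patient_record()]) and `truth` (list:
#'   `initial_mix`, `psa_true` at the measurement days, `trajectory`,
#'   `seed`).
#' @export
#' @examples
#' vp <- make_virtual_patient(synth_spec(noise_sigma = 0, seed = 7))
#' all.equal(vp$record$psa_series$psa_ng_ml, vp$truth$psa_true)  # noise-free
make_virtual_patient <- function(spec, params = model_params(),
                                 patient_id = "SYN001") {
  stopifnot(inherits(spec, "synth_spec"))
  horizon <- max(spec$measurement_days)
  traj <- simulate_tumor(spec$initial_mix, spec$psa0, spec$regimen,
                         params, horizon)
  idx <- match(spec$measurement_days, traj$day)
  psa_true <- traj$psa_ng_ml[idx]
  obs <- psa_true
  if (spec$noise_sigma > 0) {
    obs <- .with_seed(spec$seed, {
      psa_true * exp(stats::rnorm(length(psa_true), 0, spec$noise_sigma))
    })
    obs <- pmax(obs, 0.01)  # PSA reporting floor
  }
  record <- patient_record(
    patient_id = patient_id,
    psa_series = data.frame(day = spec$measurement_days, psa_ng_ml = obs),
    regimen = spec$regimen)
  list(record = record,
       truth = list(initial_mix = spec$initial_mix, psa_true = psa_true,
                    trajectory = traj, seed = spec$seed))
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded cohort of virtual patients
#'
#' Patient ground-truth mixes cycle through the 11-scenario grid
#' (100% naive, 90:10, ..., 100% ADT1R), and each patient's measurement
#' noise seed is derived deterministically from `seed`, so two calls with
#' the same arguments yield identical cohorts.
#'
#' @param n Number of patients, >= 1.
#' @param base_spec A [synth_spec()] providing psa0, regimen, measurement
#'   days and noise level; its mix and seed are replaced per patient.
#' @param seed Master seed.
#' @param params [model_params()].
#' @return List of `n` elements, each as returned by
#'   [make_virtual_patient()].
#' @export
#' @examples
#' cohort <- make_cohort(11, seed = 42)
#' cohort[[1]]$truth$initial_mix[["NAIVE"]]  # 1: first mix is 100% naive
make_cohort <- function(n, base_spec = synth_spec(), seed = 1L,
                        params = model_params()) {
  stopifnot(n >= 1)
  grid <- scenario_grid()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- ((i - 1) %% nrow(grid)) + 1
    spec_i <- base_spec
    spec_i$initial_mix <- .full_counts(c(NAIVE = grid$naive_frac[g],
                                         ADT1R = grid$adt1r_frac[g]))
    spec_i$seed <- as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483629)
    out[[i]] <- make_virtual_patient(spec_i, params,
                                     patient_id = sprintf("SYN%03d", i))
  }
  out
}
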