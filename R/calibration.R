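# Grid-search calibration of initial naive:ADT1R heterogeneity against a
# patient's PSA history, plus the patient-record formats.

#' Patient record: PSA history plus treatment regimen
#'
#' @param patient_id Identifier string.
#' @param psa_series data.frame with columns `day` (integer, strictly
#'   increasing, first day 0 = presentation) and `psa_ng_ml` (>= 0).
#' @param regimen A [treatment_regimen()].
#' @param death_day Optional integer day of death.
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(patient_id, psa_series,
                           regimen = treatment_regimen(), death_day = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1 || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  if (!is.data.frame(psa_series) ||
      !all(c("day", "psa_ng_ml") %in% names(psa_series)))
    stop("psa_series must be a data.frame with columns day and psa_ng_ml")
  psa_series <- data.frame(day = as.integer(psa_series$day),
                           psa_ng_ml = as.numeric(psa_series$psa_ng_ml))
  if (nrow(psa_series) == 0) stop("psa_series must be non-empty")
  if (psa_series$day[1] != 0)
    stop("the first PSA measurement must be at day 0 (presentation)")
  if (any(diff(psa_series$day) <= 0))
    stop("psa_series days must be strictly increasing")
  if (any(psa_series$psa_ng_ml < 0)) stop("PSA values must be non-negative")
  stopifnot(inherits(regimen, "treatment_regimen"))
  if (!is.null(death_day)) death_day <- as.integer(death_day)
  structure(list(patient_id = patient_id, psa_series = psa_series,
                 regimen = regimen, death_day = death_day),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %d PSA measurements over %d days; %d interval(s), %d event(s)%s\n",
              x$patient_id, nrow(x$psa_series), max(x$psa_series$day),
              nrow(x$regimen$intervals), nrow(x$regimen$events),
              if (is.null(x$death_day)) "" else sprintf("; died day %d", x$death_day)))
  invisible(x)
}

#' The canonical 11-scenario initial-heterogeneity grid
#'
#' At presentation the tumor is assumed to be a blend of treatment-naive
#' and ADT1-resistant cells only: 100% naive, mixtures in 10% increments,
#' down to 100% ADT1R.
#'
#' @return data.frame with 11 rows and columns `naive_frac`, `adt1r_frac`
#'   (summing to 1 in each row; adjacent rows differ by 0.1).
#' @export
#' @examples
#' scenario_grid()
scenario_grid <- function() {
  naive <- (10:0) / 10
  data.frame(naive_frac = naive, adt1r_frac = 1 - naive)
}

.as_psa_series <- function(psa_series) {
  if (is.data.frame(psa_series)) {
    if (!"psa_ng_ml" %in% names(psa_series) && "psa" %in% names(psa_series))
      names(psa_series)[names(psa_series) == "psa"] <- "psa_ng_ml"
    stopifnot(all(c("day", "psa_ng_ml") %in% names(psa_series)))
    return(psa_series[, c("day", "psa_ng_ml")])
  }
  stop("psa_series must be a data.frame with columns day and psa_ng_ml")
}

#' Euclidean distance between a simulated trajectory and a PSA history
#'
#' `sqrt(sum_i (PSA_sim(day_i) - psa_i)^2)` over all measurements, with
#' the simulated value taken at the exact integer measurement day.
#' Computed in linear PSA space by default; `log_space = TRUE` compares
#' `log10` PSA instead (values floored at 1e-12 ng/mL).
#'
#' @param traj A `tumor_trajectory` from [simulate_tumor()].
#' @param psa_series data.frame with columns `day`, `psa_ng_ml`.
#' @param log_space Compare log10 PSA instead of linear PSA.
#' @return Non-negative distance.
#' @export
trajectory_distance <- function(traj, psa_series, log_space = FALSE) {
  psa_series <- .as_psa_series(psa_series)
  idx <- match(psa_series$day, traj$day)
  if (anyNA(idx))
    stop("measurement day(s) beyond the simulated horizon: ",
         paste(psa_series$day[is.na(idx)], collapse = ", "))
  sim <- traj$psa_ng_ml[idx]
  obs <- psa_series$psa_ng_ml
  if (log_space) {
    sim <- log10(pmax(sim, 1e-12))
    obs <- log10(pmax(obs, 1e-12))
  }
  sqrt(sum((sim - obs)^2))
}

#' Estimate a patient's initial resistance by grid-search calibration
#'
#' Simulates the 11 canonical initial naive:ADT1R mixes from the
#' patient's first PSA measurement under their recorded regimen, computes
#' the Euclidean distance of each predicted PSA curve to the measured
#' history, and ranks scenarios by distance (ascending). Ties are broken
#' toward the lower ADT1R fraction (a conservative clinical prior; set
#' `tie_break_low_resistance = FALSE` to flip). The top-ranked mix is the
#' estimate of the tumor's heterogeneity at presentation.
#'
#' @param patient A [patient_record()].
#' @param params [model_params()].
#' @param grid Scenario mixes; defaults to the canonical [scenario_grid()].
#' @param log_space Passed to [trajectory_distance()].
#' @param tie_break_low_resistance Break distance ties toward fewer
#'   resistant cells.
#' @return Object of class `psa_calibration`: list with `patient_id`,
#'   `scenarios` (data.frame `naive_frac`, `adt1r_frac`, `distance`,
#'   `rank`, sorted by rank), `best_mix` (named fractions), and
#'   `trajectories` (list of simulated trajectories in grid order).
#' @export
#' @examples
#' reg <- treatment_regimen(data.frame(kind = "ADT1", start_day = 0, end_day = 300))
#' vp <- make_virtual_patient(synth_spec(
#'   initial_mix = c(NAIVE = 0.6, ADT1R = 0.4), regimen = reg,
#'   measurement_days = seq(0, 280, 56), noise_sigma = 0))
#' calibrate_patient(vp$record)$best_mix  # recovers 0.6 / 0.4
calibrate_patient <- function(patient, params = model_params(),
                              grid = scenario_grid(), log_space = FALSE,
                              tie_break_low_resistance = TRUE) {
  stopifnot(inherits(patient, "patient_record"))
  ps <- patient$psa_series
  if (nrow(ps) < 2)
    warning("fewer than 2 PSA measurements: the heterogeneity estimate is ill-posed ",
            "(every scenario is anchored to the first measurement)")
  horizon <- max(ps$day, patient$death_day %||% 0L)
  psa0 <- ps$psa_ng_ml[1]
  trajs <- vector("list", nrow(grid))
  dist <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mix <- c(NAIVE = grid$naive_frac[i], ADT1R = grid$adt1r_frac[i])
    trajs[[i]] <- simulate_tumor(mix, psa0, patient$regimen, params, horizon)
    dist[i] <- trajectory_distance(trajs[[i]], ps, log_space = log_space)
  }
  adt1r_key <- if (tie_break_low_resistance) grid$adt1r_frac else -grid$adt1r_frac
  ord <- order(dist, adt1r_key)
  scen <- data.frame(naive_frac = grid$naive_frac[ord],
                     adt1r_frac = grid$adt1r_frac[ord],
                     distance = dist[ord],
                     rank = seq_along(ord))
  structure(list(patient_id = patient$patient_id,
                 scenarios = scen,
                 best_mix = c(NAIVE = scen$naive_frac[1], ADT1R = scen$adt1r_frac[1]),
                 trajectories = trajs),
            class = "psa_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psa_calibration <- function(x, ...) {
  b <- x$scenarios[1, ]
  cat(sprintf("Calibration for patient %s: best initial mix %.0f%% naive : %.0f%% ADT1R (distance %.4g)\n",
              x$patient_id, 100 * b$naive_frac, 100 * b$adt1r_frac, b$distance))
  print(x$scenarios, row.names = FALSE)
  invisible(x)
}

#' Write / read a calibration report CSV
#'
#' Eleven rows with columns `naive_frac`, `adt1r_frac`, `distance`,
#' `rank`, sorted by rank.
#'
#' @param calibration A `psa_calibration` from [calibrate_patient()].
#' @param path File path.
#' @export
write_calibration_report <- function(calibration, path) {
  stopifnot(inherits(calibration, "psa_calibration"))
  .write_csv_precise(calibration$scenarios, path)
  invisible(path)
}

#' @rdname write_calibration_report
#' @return `read_calibration_report` returns the scenarios data.frame.
#' @export
read_calibration_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("naive_frac", "adt1r_frac", "distance", "rank") %in% names(df)))
    stop("calibration report must have columns naive_frac, adt1r_frac, distance, rank")
  df
}

#' Write / read a patient record as JSON
#'
#' @param patient A [patient_record()].
#' @param path File path.
#' @export
write_patient_json <- function(patient, path) {
  stopifnot(inherits(patient, "patient_record"))
  obj <- list(patient_id = patient$patient_id,
              psa_series = patient$psa_series,
              regimen = .regimen_to_list(patient$regimen),
              death_day = patient$death_day)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_patient_json
#' @return `read_patient_json` returns a [patient_record()].
#' @export
read_patient_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  patient_record(patient_id = obj$patient_id,
                 psa_series = as.data.frame(obj$psa_series),
                 regimen = .regimen_from_list(obj$regimen),
                 death_day = obj$death_day)
}

#' Write / read a patient record as a CSV pair
#'
#' The PSA file has columns `patient_id`, `day`, `psa_ng_ml`; the regimen
#' file follows [write_regimen_csv()]. The optional death day is not
#' represented in CSV form (use the JSON format to carry it).
#'
#' @param patient A [patient_record()].
#' @param psa_path,regimen_path File paths.
#' @export
write_patient_csv <- function(patient, psa_path, regimen_path) {
  stopifnot(inherits(patient, "patient_record"))
  df <- data.frame(patient_id = patient$patient_id,
                   day = patient$psa_series$day,
                   psa_ng_ml = patient$psa_series$psa_ng_ml)
  .write_csv_precise(df, psa_path)
  write_regimen_csv(patient$regimen, regimen_path)
  invisible(psa_path)
}

#' @rdname write_patient_csv
#' @return `read_patient_csv` returns a [patient_record()].
#' @export
read_patient_csv <- function(psa_path, regimen_path) {
  df <- utils::read.csv(psa_path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "day", "psa_ng_ml") %in% names(df)))
    stop("PSA CSV must have columns patient_id, day, psa_ng_ml")
  ids <- unique(df$patient_id)
  if (length(ids) != 1) stop("PSA CSV must describe exactly one patient")
  patient_record(patient_id = as.character(ids),
                 psa_series = df[, c("day", "psa_ng_ml")],
                 regimen = read_regimen_csv(regimen_path))
}
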