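# Resistance-informed intervention-decision algorithm: cyclic,
# threshold-triggered selection of the therapy hitting the largest
# susceptible subpopulation.

#' Parameters of the treatment-scheduling algorithm
#'
#' Decisions are made at the start of every `cycle_days`-day cycle
#' (default 28 days: 3 weeks of therapy, 1 week holiday). If total burden
#' exceeds `intervention_threshold_cells` (default the cell equivalent of
#' 1 ng/mL of PSA, ~1.02e8 cells), the algorithm picks the single therapy
#' targeting the largest subpopulation: naive -> ADT1, ADT1R -> ADT2,
#' ADT2R (resistant to all ADTs) -> CT, and a clone resistant to both
#' ADTs and chemo -> bisphosphonate palliation. `CTR` and `ADT1R_CTR`
#' are mapped to the first-line ADT still effective against them (ADT1
#' and ADT2 respectively); the whole mapping is overridable via
#' `case_map`. Below the threshold the whole cycle is a treatment
#' holiday. The run stops when PSA reaches `endpoint_psa` (the conjectured
#' clinical endpoint) or after `max_days`.
#'
#' @param intervention_threshold_cells Cell-count trigger; default
#'   `1 / 9.8e-9` (1 ng/mL of PSA).
#' @param cycle_days Cycle length in days.
#' @param on_days Days of therapy at the start of each cycle
#'   (`on_days <= cycle_days`; the remainder is a holiday).
#' @param endpoint_psa Endpoint PSA, ng/mL.
#' @param max_days Simulation horizon in days.
#' @param endpoint_rel_tol Relative tolerance for endpoint detection: the
#'   endpoint fires on the first day with
#'   `PSA >= endpoint_psa * (1 - endpoint_rel_tol)`. The discrete logistic
#'   model approaches carrying capacity (the default endpoint) strictly
#'   from below, so exact equality would never be attained; an exact
#'   crossing still returns its own day.
#' @param case_map Named character vector mapping each phenotype (when it
#'   is the largest clone) to the therapy applied.
#' @return Object of class `scheduler_params`.
#' @export
scheduler_params <- function(intervention_threshold_cells = 1 / 9.8e-9,
                             cycle_days = 28L,
                             on_days = 21L,
                             endpoint_psa = 1000,
                             max_days = 10000L,
                             endpoint_rel_tol = 1e-6,
                             case_map = c(NAIVE = "ADT1", ADT1R = "ADT2",
                                          ADT2R = "CT", CTR = "ADT1",
                                          ADT1R_CTR = "ADT2",
                                          ADT2R_CTR = "BISPH")) {
  stopifnot(intervention_threshold_cells > 0,
            cycle_days >= 1, on_days >= 0, on_days <= cycle_days,
            endpoint_psa > 0, max_days >= 1,
            endpoint_rel_tol >= 0, endpoint_rel_tol < 1)
  if (!identical(sort(names(case_map)), sort(PHENOTYPES)))
    stop("case_map must name all six phenotypes")
  bad <- setdiff(case_map, INTERVAL_TREATMENTS)
  if (length(bad)) stop("case_map values must be interval therapies; got: ",
                        paste(bad, collapse = ", "))
  structure(list(intervention_threshold_cells = intervention_threshold_cells,
                 cycle_days = as.integer(cycle_days),
                 on_days = as.integer(on_days),
                 endpoint_psa = endpoint_psa,
                 max_days = as.integer(max_days),
                 endpoint_rel_tol = endpoint_rel_tol,
                 case_map = case_map[PHENOTYPES]),
            class = "scheduler_params")
}

#' Choose the therapy for the next cycle
#'
#' If total burden is at or below the intervention threshold, no therapy
#' is applied (`"NONE"`); otherwise the therapy mapped from the largest
#' phenotype is chosen, ties broken by the fixed phenotype order
#' (`NAIVE` first).
#'
#' @param state A [tumor_state()] (or named counts vector).
#' @param sp [scheduler_params()].
#' @param susceptibility Susceptibility matrix used to sanity-check that
#'   the chosen therapy affects the targeted clone (palliation excepted).
#' @return A treatment kind.
#' @export
#' @examples
#' choose_treatment(tumor_state(c(NAIVE = 2e8, ADT1R = 1e7)))  # "ADT1"
#' choose_treatment(tumor_state(c(NAIVE = 1.0e8)))             # "NONE"
choose_treatment <- function(state, sp = scheduler_params(),
                             susceptibility = default_susceptibility()) {
  counts <- if (inherits(state, "tumor_state")) state$counts else .full_counts(state)
  if (sum(counts) <= sp$intervention_threshold_cells) return("NONE")
  largest <- PHENOTYPES[which.max(counts)]
  tx <- unname(sp$case_map[largest])
  if (tx != "BISPH" && !susceptibility[largest, tx])
    stop(sprintf("case_map sends %s to %s, which it is resistant to", largest, tx))
  tx
}

#' First day a trajectory reaches the endpoint PSA
#'
#' @param traj A `tumor_trajectory`.
#' @param endpoint_psa Endpoint PSA, ng/mL (inclusive boundary).
#' @param rel_tol Relative tolerance, see [scheduler_params()].
#' @return The first qualifying day, or `NA` if the trajectory never
#'   reaches the endpoint.
#' @export
time_to_endpoint <- function(traj, endpoint_psa = 1000, rel_tol = 1e-6) {
  hit <- which(traj$psa_ng_ml >= endpoint_psa * (1 - rel_tol))
  if (length(hit)) traj$day[hit[1]] else NA_integer_
}

#' Run the adaptive treatment-scheduling algorithm
#'
#' Starting from an initial state (typically the best calibration
#' scenario), the algorithm re-evaluates [choose_treatment()] at the start
#' of every cycle, administers the chosen therapy for `on_days`, then
#' holds (`NONE`) for the remainder of the cycle. Palliative and holiday
#' cycles follow the same cadence. The run is fully deterministic and
#' stops at the endpoint or at `max_days`.
#'
#' @param initial_state A [tumor_state()] or named counts vector (cells).
#' @param params [model_params()].
#' @param sp [scheduler_params()].
#' @return Object of class `adaptive_run`: list with `trajectory`
#'   (a `tumor_trajectory`), `schedule` (data.frame `cycle_start_day`,
#'   `treatment`), and `endpoint_day` (first day PSA reached the
#'   endpoint, or `NA`).
#' @export
#' @examples
#' run <- run_adaptive(tumor_state(c(NAIVE = psa_to_cells(10))),
#'                     sp = scheduler_params(max_days = 200))
#' head(run$schedule)
run_adaptive <- function(initial_state, params = model_params(),
                         sp = scheduler_params()) {
  counts <- if (inherits(initial_state, "tumor_state")) initial_state$counts
            else .full_counts(initial_state)
  eng <- .sim_engine(params)
  maxd <- sp$max_days
  psa_stop <- sp$endpoint_psa * (1 - sp$endpoint_rel_tol)
  n_cycles <- ceiling(maxd / sp$cycle_days)
  sched_day <- integer(n_cycles)
  sched_tx <- character(n_cycles)
  cmat <- matrix(0, nrow = maxd + 1, ncol = 6)
  active <- character(maxd + 1)
  x <- counts
  cmat[1, ] <- x
  endpoint_day <- NA_integer_
  choice <- "NONE"
  ci <- 0L
  d <- 0L
  while (d < maxd) {
    phase <- d %% sp$cycle_days
    if (phase == 0) {
      choice <- choose_treatment(stats::setNames(x, PHENOTYPES), sp,
                                 params$susceptibility)
      ci <- ci + 1L
      sched_day[ci] <- d
      sched_tx[ci] <- choice
    }
    a <- if (phase < sp$on_days) choice else "NONE"
    active[d + 1] <- a  # therapy administered on day d
    x <- .daily_step(x, match(a, TX_LEVELS), eng)
    d <- d + 1L
    cmat[d + 1, ] <- x
    if (sum(x) * params$psa_per_cell >= psa_stop) {
      endpoint_day <- d
      break
    }
  }
  active[d + 1] <- "NONE"  # nothing administered after the final record
  traj <- .as_trajectory(cmat[1:(d + 1), , drop = FALSE], active[1:(d + 1)], params)
  structure(list(trajectory = traj,
                 schedule = data.frame(cycle_start_day = sched_day[seq_len(ci)],
                                       treatment = sched_tx[seq_len(ci)],
                                       stringsAsFactors = FALSE),
                 endpoint_day = endpoint_day),
            class = "adaptive_run")
}

#' @export
print.adaptive_run <- function(x, ...) {
  cat(sprintf("Adaptive run: %d cycles over %d days; endpoint %s\n",
              nrow(x$schedule), max(x$trajectory$day),
              if (is.na(x$endpoint_day)) "not reached"
              else sprintf("reached at day %d", x$endpoint_day)))
  txs <- rle(x$schedule$treatment)
  cat("  Cycle choices: ",
      paste(sprintf("%s x%d", txs$values, txs$lengths), collapse = ", "), "\n")
  invisible(x)
}
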