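# Core discrete-time dynamics: PSA<->cell conversion, daily update steps,
# debulk events, and the forward simulator.

#' Convert a PSA concentration to an equivalent tumor-cell count
#'
#' PSA is used as a linear proxy for tumor burden: each metastatic cell
#' contributes `psa_per_cell` ng/mL per day, so a serum level of `psa`
#' corresponds to `psa / psa_per_cell` cells. With the defaults, 10 ng/mL
#' is 1.02041e9 cells and 1 ng/mL is 1.02e8 cells.
#'
#' @param psa PSA concentration(s), ng/mL; must be non-negative.
#' @param params [model_params()].
#' @return Cell count(s).
#' @seealso [cells_to_psa()]
#' @export
#' @examples
#' psa_to_cells(10)  # 1.02041e9
psa_to_cells <- function(psa, params = model_params()) {
  if (any(!is.finite(psa)) || any(psa < 0))
    stop("psa must be finite and non-negative")
  psa / params$psa_per_cell
}

#' Convert a tumor-cell count to its PSA equivalent
#'
#' @param cells Cell count(s); must be non-negative.
#' @inheritParams psa_to_cells
#' @return PSA concentration(s), ng/mL.
#' @export
#' @examples
#' cells_to_psa(1.02041e9)  # ~10 ng/mL
cells_to_psa <- function(cells, params = model_params()) {
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cells must be finite and non-negative")
  cells * params$psa_per_cell
}

#' Tumor state: per-phenotype cell counts at an integer day
#'
#' @param counts Named non-negative numeric vector of cell counts; names
#'   must be phenotype labels (any subset; missing phenotypes are zero).
#' @param day Integer day, >= 0.
#' @return Object of class `tumor_state`: list with `day` and a full
#'   six-phenotype `counts` vector.
#' @export
#' @examples
#' tumor_state(c(NAIVE = 1e9, ADT1R = 1e7))
tumor_state <- function(counts, day = 0) {
  counts <- .full_counts(counts)
  if (day < 0 || day != round(day)) stop("day must be a non-negative integer")
  structure(list(day = as.integer(day), counts = counts), class = "tumor_state")
}

.full_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 6) stop("counts must be named or of length 6")
    names(counts) <- PHENOTYPES
  }
  names(counts) <- toupper(names(counts))
  bad <- setdiff(names(counts), PHENOTYPES)
  if (length(bad))
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(PHENOTYPES, collapse = ", "))
  full <- stats::setNames(numeric(6), PHENOTYPES)
  full[names(counts)] <- as.numeric(counts)
  if (any(!is.finite(full)) || any(full < 0))
    stop("cell counts must be finite and non-negative")
  full
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("Tumor state at day %d (total %.4g cells):\n", x$day, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' One day of logistic growth for every clone
#'
#' Each phenotype grows by its effective net rate (p - a) scaled by the
#' shared logistic factor `1 - Ttotal/Ccap`, where `Ttotal` is the
#' pre-step total over all six phenotypes (the same factor for every
#' clone). While a therapy is active a phenotype may use overridden rates
#' (see [default_rate_overrides()]); bisphosphonates dampen everyone's
#' proliferation. The day counter is unchanged: callers advance it once per
#' full daily update.
#'
#' @param state A [tumor_state()].
#' @param active Active treatment: `"NONE"` or an interval therapy.
#' @param params [model_params()].
#' @return Updated `tumor_state` (same day).
#' @export
#' @examples
#' st <- tumor_state(c(NAIVE = psa_to_cells(10)))
#' sum(growth_step(st)$counts) - sum(st$counts)  # 1.29306e7 new cells
growth_step <- function(state, active = "NONE", params = model_params()) {
  active <- match.arg(active, TX_LEVELS)
  x <- state$counts
  r <- .effective_rates(params, active)
  tot <- sum(x)
  x <- x + x * (r[, "p"] - r[, "a"]) * (1 - tot / params$ccap_cells)
  x[x < 0] <- 0
  state$counts <- x
  state
}

#' One day of treatment kill on sensitive clones
#'
#' Applied after growth within a day: each phenotype is reduced by its
#' daily kill fraction for the active therapy (zero for resistant
#' phenotypes and for `NONE`; bisphosphonates kill nothing and act through
#' growth damping instead).
#'
#' @inheritParams growth_step
#' @return Updated `tumor_state` (same day).
#' @export
treatment_kill_step <- function(state, active = "NONE", params = model_params()) {
  active <- match.arg(active, TX_LEVELS)
  if (active != "NONE")
    state$counts <- state$counts * (1 - params$kill_fractions[, active])
  state
}

#' One day of mutation-driven resistance emergence
#'
#' Applied after the kill step (survivors mutate): for each phenotype
#' sensitive to the active therapy with a transition target in the graph,
#' `mutation_rate` of its cells move to the resistant target phenotype.
#' Total cell number is exactly conserved; no transitions occur for
#' `NONE`, `BISPH`, or debulking events.
#'
#' @inheritParams growth_step
#' @return Updated `tumor_state` (same day).
#' @export
#' @examples
#' st <- tumor_state(c(NAIVE = 1e9))
#' mutation_step(st, "ADT1")$counts[["ADT1R"]]  # 500 cells
mutation_step <- function(state, active = "NONE", params = model_params()) {
  active <- match.arg(active, TX_LEVELS)
  tr <- params$transitions
  rows <- which(tr$treatment == active)
  x <- state$counts
  if (length(rows)) {
    src <- match(tr$from[rows], PHENOTYPES)
    tgt <- match(tr$to[rows], PHENOTYPES)
    dm <- params$mutation_rate * x[src]
    x[src] <- x[src] - dm
    for (j in seq_along(tgt)) x[tgt[j]] <- x[tgt[j]] + dm[j]
  }
  state$counts <- x
  state
}

#' One-time tumor debulking (surgery / radiotherapy)
#'
#' Removes the same fraction of every phenotype, so PSA drops by
#' `fraction` while the relative clonal composition is exactly preserved;
#' debulking creates no resistance.
#'
#' @param state A [tumor_state()].
#' @param fraction Fraction of cells removed, in `[0, 1]`.
#' @return Updated `tumor_state`.
#' @export
debulk_event <- function(state, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("debulk fraction must be a number in [0, 1]")
  state$counts <- state$counts * (1 - fraction)
  state
}

# Treatment code administered on each day 0..horizon (index day + 1).
.active_codes <- function(regimen, horizon) {
  a <- rep(1L, horizon + 1)
  if (is.null(regimen)) return(a)
  iv <- regimen$intervals
  for (i in seq_len(nrow(iv))) {
    if (iv$start_day[i] > horizon) {
      warning(sprintf("treatment interval %s [%d, %d) starts beyond the horizon (%d); ignored",
                      iv$kind[i], iv$start_day[i], iv$end_day[i], horizon))
      next
    }
    d0 <- max(0L, iv$start_day[i])
    d1 <- min(horizon, iv$end_day[i] - 1L)
    a[(d0:d1) + 1L] <- match(iv$kind[i], TX_LEVELS)
  }
  a
}

# Multiplicative debulk survivor fraction per day 0..horizon.
.event_multipliers <- function(regimen, horizon, params) {
  ev <- rep(1, horizon + 1)
  if (is.null(regimen)) return(ev)
  e <- regimen$events
  for (i in seq_len(nrow(e))) {
    frac <- if (is.na(e$fraction[i])) params$debulk_fraction else e$fraction[i]
    if (e$day[i] > horizon) {
      warning(sprintf("debulk event %s at day %d is beyond the horizon (%d); ignored",
                      e$kind[i], e$day[i], horizon))
      next
    }
    ev[e$day[i] + 1L] <- ev[e$day[i] + 1L] * (1 - frac)
  }
  ev
}

.mix_to_counts <- function(initial_mix, psa0, params) {
  mix <- .full_counts(initial_mix)  # reuses validation; values are fractions here
  s <- sum(mix)
  if (abs(s - 1) > 1e-8) stop("initial_mix fractions must sum to 1 (got ", s, ")")
  psa_to_cells(psa0, params) * mix
}

#' Simulate the model forward under a treatment regimen
#'
#' Day 0 seeds `psa_to_cells(psa0)` cells split by `initial_mix`. Each
#' subsequent day applies, in order, logistic growth, treatment kill, and
#' mutation for the therapy administered on the previous day, then any
#' debulking event scheduled on the day being produced (events on day 0
#' are applied to the initial state). Treatment intervals are half-open
#' `[start_day, end_day)` in 0-based days from presentation.
#'
#' @param initial_mix Named fractions over phenotypes summing to 1
#'   (missing phenotypes are zero), e.g. `c(NAIVE = 0.9, ADT1R = 0.1)`.
#' @param psa0 PSA at presentation (day 0), ng/mL.
#' @param regimen A [treatment_regimen()] or `NULL` for no treatment.
#' @param params [model_params()].
#' @param horizon Number of days to simulate (the trajectory has
#'   `horizon + 1` daily records, days `0:horizon`).
#' @return A `tumor_trajectory`: data.frame with columns `day`, `naive`,
#'   `adt1r`, `adt2r`, `ctr`, `adt1r_ctr`, `adt2r_ctr`, `total_cells`,
#'   `psa_ng_ml`, and `active_treatment` (therapy administered that day).
#' @export
#' @examples
#' traj <- simulate_tumor(c(NAIVE = 1), psa0 = 10, horizon = 1)
#' round(traj$psa_ng_ml[2], 1)  # 10.1
simulate_tumor <- function(initial_mix, psa0, regimen = NULL,
                           params = model_params(), horizon) {
  if (!is.numeric(psa0) || length(psa0) != 1 || psa0 < 0)
    stop("psa0 must be a non-negative number")
  if (!is.numeric(horizon) || length(horizon) != 1 ||
      horizon < 0 || horizon != round(horizon))
    stop("horizon must be a non-negative integer number of days")
  horizon <- as.integer(horizon)
  x <- .mix_to_counts(initial_mix, psa0, params)
  eng <- .sim_engine(params)
  act <- .active_codes(regimen, horizon)
  ev <- .event_multipliers(regimen, horizon, params)
  if (ev[1] < 1) x <- x * ev[1]
  counts <- matrix(0, nrow = horizon + 1, ncol = 6)
  counts[1, ] <- x
  if (horizon > 0) for (d in 1:horizon) {
    x <- .daily_step(x, act[d], eng)
    f <- ev[d + 1]
    if (f < 1) x <- x * f
    counts[d + 1, ] <- x
  }
  .as_trajectory(counts, TX_LEVELS[act], params)
}

.as_trajectory <- function(counts, active, params) {
  total <- rowSums(counts)
  out <- data.frame(
    day = seq_len(nrow(counts)) - 1L,
    naive = counts[, 1], adt1r = counts[, 2], adt2r = counts[, 3],
    ctr = counts[, 4], adt1r_ctr = counts[, 5], adt2r_ctr = counts[, 6],
    total_cells = total,
    psa_ng_ml = total * params$psa_per_cell,
    active_treatment = active,
    stringsAsFactors = FALSE)
  class(out) <- c("tumor_trajectory", "data.frame")
  out
}

# Counts matrix (days x phenotypes) from a trajectory.
.traj_counts <- function(traj) {
  as.matrix(traj[, c("naive", "adt1r", "adt2r", "ctr", "adt1r_ctr", "adt2r_ctr")])
}
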