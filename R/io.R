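# Configuration files (YAML/JSON), trajectory CSV, and CSV helpers.

# Full-precision CSV writer: numerics are serialized with 17 significant
# digits so write/read round-trips are bit-exact.
.write_csv_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- out[[nm]]
      out[[nm]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a simulated trajectory as CSV
#'
#' Columns, in fixed order: `day`, `naive`, `adt1r`, `adt2r`, `ctr`,
#' `adt1r_ctr`, `adt2r_ctr`, `total_cells`, `psa_ng_ml`,
#' `active_treatment`. Numerics are written in full precision, so the
#' round trip is exact.
#'
#' @param traj A `tumor_trajectory` from [simulate_tumor()].
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tumor_trajectory"))
  .write_csv_precise(as.data.frame(traj), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns a `tumor_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "naive", "adt1r", "adt2r", "ctr", "adt1r_ctr",
            "adt2r_ctr", "total_cells", "psa_ng_ml", "active_treatment")
  if (!identical(names(df), need))
    stop("trajectory CSV must have columns, in order: ",
         paste(need, collapse = ", "))
  class(df) <- c("tumor_trajectory", "data.frame")
  df
}

.MODEL_KEYS <- c("psa_per_cell", "ccap_psa", "mutation_rate", "adt1_kill",
                 "adt2_kill", "ct_kill_coef", "bisph_damp", "debulk_fraction",
                 "baseline_rates", "rate_overrides", "kill_fractions",
                 "resistant_to", "transitions")
.SCHED_KEYS <- c("intervention_threshold_psa", "intervention_threshold_cells",
                 "cycle_days", "on_days", "endpoint_psa", "max_days",
                 "endpoint_rel_tol", "case_map")

.reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s' under %s (permitted: %s)",
                 bad[1], where, paste(allowed, collapse = ", ")))
}

#' Load a run configuration from YAML or JSON
#'
#' Every model and scheduler constant can be set in a structured file;
#' absent keys take the documented defaults, so an empty file resolves to
#' the full default configuration. Unknown keys are rejected with the
#' offending key named. `path = NULL` returns the defaults directly.
#'
#' Layout (all keys optional):
#' \preformatted{
#' model:
#'   psa_per_cell: 9.8e-9      # ng/mL PSA per cell per day
#'   ccap_psa: 1000            # carrying capacity, ng/mL
#'   mutation_rate: 5.0e-7
#'   adt1_kill: 0.03
#'   adt2_kill: 0.03
#'   ct_kill_coef: 1.5
#'   bisph_damp: 0.3
#'   debulk_fraction: 0.9
#'   baseline_rates: {NAIVE: {p: 0.0204, a: 0.0076}, ...}
#'   rate_overrides: {ADT2: {ADT1R: {p: 0.0109, a: 0.0002}}}
#'   resistant_to: {NAIVE: [], ADT1R: [ADT1], ...}
#'   transitions: [{from: NAIVE, treatment: ADT1, to: ADT1R}, ...]
#' scheduler:
#'   intervention_threshold_psa: 1.0
#'   cycle_days: 28
#'   on_days: 21
#'   endpoint_psa: 1000
#'   max_days: 10000
#'   endpoint_rel_tol: 1.0e-6
#'   case_map: {NAIVE: ADT1, ...}
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL`.
#' @param verbose Echo the resolved configuration hash via [message()].
#' @return Object of class `run_config`: list with `model`
#'   ([model_params()]) and `scheduler` ([scheduler_params()]).
#' @export
load_config <- function(path = NULL, verbose = FALSE) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  .reject_unknown(raw, c("model", "scheduler"), "the top level")
  m <- raw$model %||% list()
  s <- raw$scheduler %||% list()
  .reject_unknown(m, .MODEL_KEYS, "model")
  .reject_unknown(s, .SCHED_KEYS, "scheduler")

  rates <- default_growth_rates()
  if (!is.null(m$baseline_rates)) {
    .reject_unknown(m$baseline_rates, PHENOTYPES, "model$baseline_rates")
    for (ph in names(m$baseline_rates)) {
      rates[ph, "p"] <- m$baseline_rates[[ph]]$p
      rates[ph, "a"] <- m$baseline_rates[[ph]]$a
    }
  }
  susceptibility <- default_susceptibility()
  if (!is.null(m$resistant_to)) {
    .reject_unknown(m$resistant_to, PHENOTYPES, "model$resistant_to")
    susceptibility <- matrix(TRUE, 6, 4,
                             dimnames = list(PHENOTYPES, INTERVAL_TREATMENTS))
    for (ph in names(m$resistant_to)) {
      res <- unlist(m$resistant_to[[ph]])
      bad <- setdiff(res, c("ADT1", "ADT2", "CT"))
      if (length(bad))
        stop("model$resistant_to$", ph, ": cannot resist ", bad[1])
      susceptibility[ph, res] <- FALSE
    }
  }
  transitions <- default_transitions()
  if (!is.null(m$transitions)) {
    tr <- do.call(rbind, lapply(m$transitions, function(t)
      data.frame(from = t$from, treatment = t$treatment, to = t$to,
                 stringsAsFactors = FALSE)))
    transitions <- tr
  }
  kill <- NULL
  if (!is.null(m$kill_fractions)) {
    .reject_unknown(m$kill_fractions, PHENOTYPES, "model$kill_fractions")
    kill <- matrix(0, 6, 4, dimnames = list(PHENOTYPES, INTERVAL_TREATMENTS))
    for (ph in names(m$kill_fractions)) {
      row <- m$kill_fractions[[ph]]
      .reject_unknown(row, INTERVAL_TREATMENTS,
                      paste0("model$kill_fractions$", ph))
      for (tx in names(row)) kill[ph, tx] <- row[[tx]]
    }
  }
  ov <- m$rate_overrides %||% default_rate_overrides()
  model <- model_params(
    psa_per_cell = m$psa_per_cell %||% 9.8e-9,
    ccap_psa = m$ccap_psa %||% 1000,
    mutation_rate = m$mutation_rate %||% 5e-7,
    baseline_rates = rates,
    adt1_kill = m$adt1_kill %||% 0.03,
    adt2_kill = m$adt2_kill %||% 0.03,
    ct_kill_coef = m$ct_kill_coef %||% 1.5,
    bisph_damp = m$bisph_damp %||% 0.3,
    kill_fractions = kill,
    rate_overrides = ov,
    susceptibility = susceptibility,
    transitions = transitions,
    debulk_fraction = m$debulk_fraction %||% 0.9)

  thr <- if (!is.null(s$intervention_threshold_cells)) s$intervention_threshold_cells
         else psa_to_cells(s$intervention_threshold_psa %||% 1, model)
  case_map <- scheduler_params()$case_map
  if (!is.null(s$case_map)) {
    .reject_unknown(s$case_map, PHENOTYPES, "scheduler$case_map")
    for (ph in names(s$case_map)) case_map[ph] <- s$case_map[[ph]]
  }
  sched <- scheduler_params(
    intervention_threshold_cells = thr,
    cycle_days = s$cycle_days %||% 28L,
    on_days = s$on_days %||% 21L,
    endpoint_psa = s$endpoint_psa %||% 1000,
    max_days = s$max_days %||% 10000L,
    endpoint_rel_tol = s$endpoint_rel_tol %||% 1e-6,
    case_map = case_map)

  cfg <- structure(list(model = model, scheduler = sched), class = "run_config")
  if (verbose)
    message("resolved configuration hash: ", config_hash(cfg))
  cfg
}

#' Save a run configuration to YAML or JSON
#'
#' Writes the fully resolved configuration (every constant explicit), so
#' `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param path Destination; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  m <- cfg$model; s <- cfg$scheduler
  rates <- lapply(stats::setNames(PHENOTYPES, PHENOTYPES), function(ph)
    list(p = m$baseline_rates[ph, "p"], a = m$baseline_rates[ph, "a"]))
  kill <- lapply(stats::setNames(PHENOTYPES, PHENOTYPES), function(ph)
    as.list(m$kill_fractions[ph, ]))
  resist <- lapply(stats::setNames(PHENOTYPES, PHENOTYPES), function(ph)
    as.list(colnames(m$susceptibility)[!m$susceptibility[ph, ]]))
  trans <- lapply(seq_len(nrow(m$transitions)), function(i)
    as.list(m$transitions[i, c("from", "treatment", "to")]))
  obj <- list(
    model = list(
      psa_per_cell = m$psa_per_cell, ccap_psa = m$ccap_psa,
      mutation_rate = m$mutation_rate, adt1_kill = m$adt1_kill,
      adt2_kill = m$adt2_kill, ct_kill_coef = m$ct_kill_coef,
      bisph_damp = m$bisph_damp, debulk_fraction = m$debulk_fraction,
      baseline_rates = rates, rate_overrides = m$rate_overrides,
      kill_fractions = kill, resistant_to = resist, transitions = trans),
    scheduler = list(
      intervention_threshold_cells = s$intervention_threshold_cells,
      cycle_days = s$cycle_days, on_days = s$on_days,
      endpoint_psa = s$endpoint_psa, max_days = s$max_days,
      endpoint_rel_tol = s$endpoint_rel_tol,
      case_map = as.list(s$case_map)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else
    writeLines(yaml::as.yaml(obj, precision = 15), path)
  invisible(path)
}

#' Short content hash of a run configuration
#'
#' A 32-bit polynomial rolling hash over the serialized resolved
#' configuration; logged by the CLI so any written trajectory can be
#' traced back to the exact constants that produced it.
#'
#' @param cfg A `run_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  bytes <- as.integer(serialize(cfg, connection = NULL, version = 3))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (hash ", config_hash(x), ")\n", sep = "")
  print(x$model)
  cat(sprintf("  Scheduler: threshold %.4g cells, cycle %d days (%d on), endpoint %g ng/mL, horizon %d days\n",
              x$scheduler$intervention_threshold_cells, x$scheduler$cycle_days,
              x$scheduler$on_days, x$scheduler$endpoint_psa, x$scheduler$max_days))
  invisible(x)
}
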