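# Model parameters: rates table, kill fractions, conversion constants.

#' Default per-phenotype daily growth rates
#'
#' Proliferation (`p`) and apoptosis (`a`) fractions per day. The naive
#' rates and the rates of cells growing under/after abiraterone come from
#' immunofluorescent proliferation/apoptotic indices of serial bone-biopsy
#' sections (phospho-histone H3 and cleaved caspase-3 in pan-cytokeratin+
#' cells): pre-treatment 2.42%/1.68% parameterize `ADT1R` (cells that have
#' failed 1st-generation ADT), post-treatment 1.09%/0.02% parameterize
#' `ADT2R`. Naive rates (0.0204/0.0076) are literature-derived constants
#' for hormone-sensitive disease. Chemotherapy resistance is a growth cost: each
#' chemo-resistant phenotype proliferates 0.005/day slower than its
#' chemo-sensitive counterpart. All values are configuration defaults and
#' can be overridden (see [load_config()]).
#'
#' @return 6 x 2 numeric matrix, rows [phenotype_levels()], columns `p`, `a`.
#' @export
default_growth_rates <- function() {
  m <- rbind(
    NAIVE     = c(0.0204, 0.0076),
    ADT1R     = c(0.0242, 0.0168),
    ADT2R     = c(0.0109, 0.0002),
    CTR       = c(0.0154, 0.0076),
    ADT1R_CTR = c(0.0192, 0.0168),
    ADT2R_CTR = c(0.0059, 0.0002))
  colnames(m) <- c("p", "a")
  m
}

#' Default treatment-conditioned growth-rate overrides
#'
#' While a therapy is active, a phenotype may grow with different rates
#' than its baseline. The single measured override: `ADT1R` cells exposed
#' to 2nd-generation ADT grow with the post-abiraterone indices
#' (p = 0.0109, a = 0.0002).
#'
#' @return Nested list `overrides[[treatment]][[phenotype]] = list(p, a)`.
#' @export
default_rate_overrides <- function() {
  list(ADT2 = list(ADT1R = list(p = 0.0109, a = 0.0002)))
}

# Kill-fraction table derived from the scalar knobs: flat ADT kills on
# sensitive phenotypes, chemo kill proportional to proliferation
# (effectiveness ~ division attempts), no kill for palliation (BISPH acts
# by damping proliferation instead; see model_params()).
.default_kill_fractions <- function(rates, susceptibility,
                                    adt1_kill, adt2_kill, ct_kill_coef) {
  k <- matrix(0, nrow = 6, ncol = 4,
              dimnames = list(PHENOTYPES, INTERVAL_TREATMENTS))
  k[susceptibility[, "ADT1"], "ADT1"] <- adt1_kill
  k[susceptibility[, "ADT2"], "ADT2"] <- adt2_kill
  sct <- susceptibility[, "CT"]
  k[sct, "CT"] <- ct_kill_coef * rates[sct, "p"]
  k
}

#' Model parameters for the tumor-evolution simulator
#'
#' Bundles every biological constant of the model. PSA is a linear proxy
#' for tumor burden: one metastatic prostate cancer cell produces
#' `psa_per_cell` ng/mL of serum PSA per 24 h (default 9.8e-9). The shared
#' logistic carrying capacity is specified in PSA units (`ccap_psa`,
#' default 1000 ng/mL, also the conjectured clinical endpoint) and
#' converted exactly: `ccap_cells = ccap_psa / psa_per_cell` (~1.02e11
#' cells). Under a matched therapy, `mutation_rate` of each surviving
#' sensitive cell population acquires resistance per day (default 5e-7,
#' i.e. 0.00005%).
#'
#' @param psa_per_cell ng/mL PSA produced per cell per day; > 0.
#' @param ccap_psa Carrying capacity in ng/mL of PSA; > 0.
#' @param mutation_rate Fraction of sensitive cells converting to the
#'   resistant phenotype per day under a matched treatment, in `[0, 1)`.
#' @param baseline_rates 6 x 2 matrix of per-day `p`/`a` fractions,
#'   see [default_growth_rates()].
#' @param adt1_kill,adt2_kill Daily kill fraction an ADT applies to each
#'   sensitive phenotype, in `[0, 1]`.
#' @param ct_kill_coef Chemotherapy kill coefficient: a sensitive
#'   phenotype's chemo kill fraction is `ct_kill_coef * p` (effectiveness
#'   proportional to division attempts).
#' @param bisph_damp Bisphosphonate palliation: proliferation of every
#'   phenotype is multiplied by `1 - bisph_damp` while BISPH is active, in
#'   `[0, 1)`. Sized so an otherwise-untreated naive clone still grows
#'   toward carrying capacity.
#' @param kill_fractions Optional explicit 6 x 4 kill-fraction matrix
#'   (phenotypes x interval treatments) replacing the derived defaults.
#' @param rate_overrides Treatment-conditioned growth-rate overrides,
#'   see [default_rate_overrides()].
#' @param susceptibility See [default_susceptibility()].
#' @param transitions See [default_transitions()].
#' @param debulk_fraction Default fraction of every phenotype removed by a
#'   one-time debulking event (surgery/radiotherapy), in `[0, 1]`.
#' @return Object of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' p$ccap_cells            # 1000 / 9.8e-9 cells
#' psa_to_cells(10, p)     # 1.02041e9 cells
model_params <- function(psa_per_cell = 9.8e-9,
                         ccap_psa = 1000,
                         mutation_rate = 5e-7,
                         baseline_rates = default_growth_rates(),
                         adt1_kill = 0.03,
                         adt2_kill = 0.03,
                         ct_kill_coef = 1.5,
                         bisph_damp = 0.3,
                         kill_fractions = NULL,
                         rate_overrides = default_rate_overrides(),
                         susceptibility = default_susceptibility(),
                         transitions = default_transitions(),
                         debulk_fraction = 0.9) {
  stopifnot(is.numeric(psa_per_cell), length(psa_per_cell) == 1, psa_per_cell > 0,
            is.numeric(ccap_psa), length(ccap_psa) == 1, ccap_psa > 0,
            is.numeric(mutation_rate), mutation_rate >= 0, mutation_rate < 1,
            is.numeric(bisph_damp), bisph_damp >= 0, bisph_damp < 1,
            is.numeric(debulk_fraction), debulk_fraction >= 0, debulk_fraction <= 1)
  baseline_rates <- .check_rates_matrix(baseline_rates)
  validate_resistance_structure(susceptibility, transitions)
  if (is.null(kill_fractions))
    kill_fractions <- .default_kill_fractions(baseline_rates, susceptibility,
                                              adt1_kill, adt2_kill, ct_kill_coef)
  if (!identical(dim(kill_fractions), c(6L, 4L)) ||
      any(kill_fractions < 0) || any(kill_fractions > 1))
    stop("kill_fractions must be a 6 x 4 matrix of fractions in [0, 1]")
  dimnames(kill_fractions) <- list(PHENOTYPES, INTERVAL_TREATMENTS)
  .check_overrides(rate_overrides)
  p <- structure(list(
    psa_per_cell = psa_per_cell,
    ccap_psa = ccap_psa,
    ccap_cells = ccap_psa / psa_per_cell,
    mutation_rate = mutation_rate,
    baseline_rates = baseline_rates,
    adt1_kill = adt1_kill,
    adt2_kill = adt2_kill,
    ct_kill_coef = ct_kill_coef,
    bisph_damp = bisph_damp,
    kill_fractions = kill_fractions,
    rate_overrides = rate_overrides,
    susceptibility = susceptibility,
    transitions = transitions,
    debulk_fraction = debulk_fraction), class = "model_params")
  p
}

.check_rates_matrix <- function(r) {
  r <- as.matrix(r)
  if (!identical(dim(r), c(6L, 2L)))
    stop("baseline_rates must be a 6 x 2 matrix (phenotypes x c(p, a))")
  if (is.null(rownames(r))) rownames(r) <- PHENOTYPES
  if (is.null(colnames(r))) colnames(r) <- c("p", "a")
  r <- r[PHENOTYPES, c("p", "a")]
  if (any(r < 0) || any(r >= 1))
    stop("growth rates must be daily fractions in [0, 1)")
  r
}

.check_overrides <- function(ov) {
  if (is.null(ov)) return(invisible(TRUE))
  bad_tx <- setdiff(names(ov), INTERVAL_TREATMENTS)
  if (length(bad_tx)) stop("rate_overrides for unknown treatment: ", bad_tx[1])
  for (tx in names(ov)) {
    bad_ph <- setdiff(names(ov[[tx]]), PHENOTYPES)
    if (length(bad_ph)) stop("rate_overrides for unknown phenotype: ", bad_ph[1])
    for (ph in names(ov[[tx]])) {
      o <- ov[[tx]][[ph]]
      if (!all(c("p", "a") %in% names(o)) ||
          o$p < 0 || o$p >= 1 || o$a < 0 || o$a >= 1)
        stop(sprintf("rate_overrides[[%s]][[%s]] must give p and a in [0, 1)", tx, ph))
    }
  }
  invisible(TRUE)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor evolution model parameters\n")
  cat(sprintf("  PSA per cell:       %.3g ng/mL/day\n", x$psa_per_cell))
  cat(sprintf("  Carrying capacity:  %g ng/mL  (%.5g cells)\n",
              x$ccap_psa, x$ccap_cells))
  cat(sprintf("  Mutation rate:      %.3g per cell per day under matched therapy\n",
              x$mutation_rate))
  cat("  Baseline rates (p, a) per day:\n")
  print(x$baseline_rates)
  invisible(x)
}

# Effective (p, a) table while `tx` is active: baseline, BISPH damping,
# then explicit treatment-conditioned overrides.
.effective_rates <- function(params, tx) {
  r <- params$baseline_rates
  if (tx == "BISPH") r[, "p"] <- r[, "p"] * (1 - params$bisph_damp)
  ov <- params$rate_overrides[[tx]]
  for (ph in names(ov)) {
    r[ph, "p"] <- ov[[ph]]$p
    r[ph, "a"] <- ov[[ph]]$a
  }
  r
}

# Precomputed per-treatment tables for the daily update loop.
# net:  5 x 6 effective (p - a) by TX_LEVELS x phenotype
# kill: 5 x 6 daily kill fractions (NONE row is zero)
# mut:  per treatment, integer source/target phenotype indices
.sim_engine <- function(params) {
  net <- matrix(0, nrow = 5, ncol = 6, dimnames = list(TX_LEVELS, PHENOTYPES))
  kill <- matrix(0, nrow = 5, ncol = 6, dimnames = list(TX_LEVELS, PHENOTYPES))
  mut <- vector("list", 5)
  names(mut) <- TX_LEVELS
  tr <- params$transitions
  for (tx in TX_LEVELS) {
    r <- .effective_rates(params, tx)
    net[tx, ] <- r[, "p"] - r[, "a"]
    if (tx != "NONE") kill[tx, ] <- params$kill_fractions[, tx]
    rows <- tr$treatment == tx
    mut[[tx]] <- list(src = match(tr$from[rows], PHENOTYPES),
                      tgt = match(tr$to[rows], PHENOTYPES))
  }
  list(net = net, kill = kill, mut = mut,
       mu = params$mutation_rate, ccap = params$ccap_cells,
       psa_per_cell = params$psa_per_cell)
}

# One full daily update (growth -> kill -> mutation) on a bare counts
# vector; `code` indexes TX_LEVELS. Debulk events are applied by callers.
.daily_step <- function(x, code, eng) {
  tot <- sum(x)
  x <- x + x * eng$net[code, ] * (1 - tot / eng$ccap)
  if (any(x < 0)) x[x < 0] <- 0  # defensive: a > p cannot overshoot, but clamp anyway
  k <- eng$kill[code, ]
  x <- x * (1 - k)
  m <- eng$mut[[code]]
  if (length(m$src)) {
    dm <- eng$mu * x[m$src]
    x[m$src] <- x[m$src] - dm
    # several sources can feed the same resistant phenotype: accumulate
    for (j in seq_along(m$tgt)) x[m$tgt[j]] <- x[m$tgt[j]] + dm[j]
  }
  x
}
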