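# Phenotype and treatment alphabets, susceptibility matrix, transition graph.

PHENOTYPES <- c("NAIVE", "ADT1R", "ADT2R", "CTR", "ADT1R_CTR", "ADT2R_CTR")
INTERVAL_TREATMENTS <- c("ADT1", "ADT2", "CT", "BISPH")
EVENT_TREATMENTS <- c("RT", "SURG")
# Daily-step treatment codes; index into the engine tables. NONE is row 1.
TX_LEVELS <- c("NONE", INTERVAL_TREATMENTS)

#' Phenotype labels of the six modeled subpopulations
#'
#' The model tracks six prostate-cancer phenotypes defined by their
#' resistance profile: treatment-naive cells (`NAIVE`, sensitive to all
#' therapies), cells resistant to 1st- or 2nd-generation androgen
#' deprivation therapy (`ADT1R`, `ADT2R`), chemotherapy-resistant cells
#' (`CTR`), and the doubly resistant combinations (`ADT1R_CTR`,
#' `ADT2R_CTR`). Every state vector and trajectory is indexed by all six,
#' in this fixed order (ties in the scheduler are broken toward the first).
#'
#' @return Character vector of the six phenotype labels.
#' @export
#' @examples
#' phenotype_levels()
phenotype_levels <- function() PHENOTYPES

#' Treatment kinds known to the model
#'
#' `ADT1`, `ADT2` (1st/2nd-generation androgen deprivation therapy), `CT`
#' (docetaxel/cabazitaxel chemotherapy) and `BISPH` (bisphosphonate
#' palliation) are interval therapies administered daily over half-open day
#' ranges; `RT` and `SURG` are one-time debulking events; `NONE` denotes
#' the absence of therapy.
#'
#' @param which `"all"`, `"interval"` (daily therapies) or `"event"`
#'   (one-time debulking).
#' @return Character vector of treatment labels.
#' @export
#' @examples
#' treatment_levels("interval")
treatment_levels <- function(which = c("all", "interval", "event")) {
  switch(match.arg(which),
    all = c("NONE", INTERVAL_TREATMENTS, EVENT_TREATMENTS),
    interval = INTERVAL_TREATMENTS,
    event = EVENT_TREATMENTS)
}

#' Default phenotype-by-treatment susceptibility matrix
#'
#' Logical matrix with one row per phenotype and one column per interval
#' therapy; `TRUE` means the therapy affects that phenotype. Naive cells are
#' sensitive to everything; each resistant phenotype is insensitive to the
#' therapies named in its label, and `ADT2R` (and `ADT2R_CTR`) escape both
#' generations of androgen deprivation since 2nd-generation agents operate
#' downstream of 1st-generation castration. Bisphosphonate palliation
#' dampens all phenotypes equally and creates no resistance.
#'
#' @return 6 x 4 logical matrix (phenotypes x interval treatments).
#' @seealso [default_transitions()], [is_sensitive()]
#' @export
default_susceptibility <- function() {
  m <- matrix(TRUE, nrow = 6, ncol = 4,
              dimnames = list(PHENOTYPES, INTERVAL_TREATMENTS))
  m["ADT1R", c("ADT1")] <- FALSE
  m["ADT2R", c("ADT1", "ADT2")] <- FALSE
  m["CTR", "CT"] <- FALSE
  m["ADT1R_CTR", c("ADT1", "CT")] <- FALSE
  m["ADT2R_CTR", c("ADT1", "ADT2", "CT")] <- FALSE
  m
}

#' Default resistance transition graph
#'
#' Under a matched therapy, a small fraction of surviving sensitive cells
#' acquires resistance each day; this table says which resistant phenotype
#' each (phenotype, therapy) pair spawns. Palliative treatments (`BISPH`)
#' and debulking events (`RT`, `SURG`) generate no resistance and have no
#' entries. The two transitions out of `CTR` are inferred to close the
#' graph (a chemo-resistant clone escaping an ADT must end up doubly
#' resistant) and can be edited via the configuration file.
#'
#' @return data.frame with columns `from`, `treatment`, `to`.
#' @seealso [resistance_target()], [validate_resistance_structure()]
#' @export
default_transitions <- function() {
  data.frame(
    from = c("NAIVE", "NAIVE", "NAIVE", "ADT1R", "ADT1R",
             "ADT2R", "CTR", "CTR", "ADT1R_CTR"),
    treatment = c("ADT1", "ADT2", "CT", "ADT2", "CT",
                  "CT", "ADT1", "ADT2", "ADT2"),
    to = c("ADT1R", "ADT2R", "CTR", "ADT2R", "ADT1R_CTR",
           "ADT2R_CTR", "ADT1R_CTR", "ADT2R_CTR", "ADT2R_CTR"),
    stringsAsFactors = FALSE)
}

#' Is a phenotype sensitive to a treatment?
#'
#' @param phenotype One of [phenotype_levels()].
#' @param treatment One of the interval therapies, `treatment_levels("interval")`.
#' @param susceptibility Susceptibility matrix, see [default_susceptibility()].
#' @return `TRUE` if the therapy affects the phenotype.
#' @export
#' @examples
#' is_sensitive("NAIVE", "ADT1")  # TRUE
#' is_sensitive("ADT2R", "ADT1")  # FALSE: resistant to both ADT generations
is_sensitive <- function(phenotype, treatment,
                         susceptibility = default_susceptibility()) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  treatment <- match.arg(treatment, INTERVAL_TREATMENTS)
  susceptibility[phenotype, treatment]
}

#' Resistant phenotype spawned by treating a sensitive phenotype
#'
#' @inheritParams is_sensitive
#' @param treatment Any treatment kind (therapies without transitions,
#'   e.g. `BISPH` or `NONE`, return `NA`).
#' @param transitions Transition table, see [default_transitions()].
#' @return The target phenotype label, or `NA_character_` if the pair has
#'   no transition.
#' @export
#' @examples
#' resistance_target("NAIVE", "ADT1")   # "ADT1R"
#' resistance_target("ADT1R", "CT")     # "ADT1R_CTR"
#' resistance_target("NAIVE", "BISPH")  # NA: palliation creates no resistance
resistance_target <- function(phenotype, treatment,
                              transitions = default_transitions()) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  hit <- transitions$from == phenotype & transitions$treatment == treatment
  if (any(hit)) transitions$to[which(hit)[1]] else NA_character_
}

#' Validate consistency of a susceptibility matrix and transition graph
#'
#' Checks, exhaustively over the 6 x 4 table, that every transition starts
#' from a phenotype sensitive to the triggering therapy and lands on a
#' phenotype insensitive to it, and that no transitions are declared for
#' palliative or one-time treatments. Called at parameter-construction and
#' configuration-load time.
#'
#' @inheritParams is_sensitive
#' @inheritParams resistance_target
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_resistance_structure <- function(susceptibility = default_susceptibility(),
                                          transitions = default_transitions()) {
  if (!identical(dim(susceptibility), c(6L, 4L)) ||
      !identical(rownames(susceptibility), PHENOTYPES) ||
      !identical(colnames(susceptibility), INTERVAL_TREATMENTS) ||
      !is.logical(susceptibility))
    stop("susceptibility must be a 6 x 4 logical matrix over phenotypes x interval treatments")
  if (!all(c("from", "treatment", "to") %in% names(transitions)))
    stop("transitions must have columns from, treatment, to")
  bad_kind <- setdiff(unique(transitions$treatment), c("ADT1", "ADT2", "CT"))
  if (length(bad_kind))
    stop("transitions declared for treatment(s) that cannot generate resistance: ",
         paste(bad_kind, collapse = ", "))
  for (i in seq_len(nrow(transitions))) {
    fr <- transitions$from[i]; tx <- transitions$treatment[i]; to <- transitions$to[i]
    if (!fr %in% PHENOTYPES || !to %in% PHENOTYPES)
      stop("unknown phenotype in transition row ", i)
    if (!susceptibility[fr, tx])
      stop(sprintf("transition (%s, %s): source is not sensitive to %s", fr, tx, tx))
    if (susceptibility[to, tx])
      stop(sprintf("transition (%s, %s) -> %s: target is still sensitive to %s",
                   fr, tx, to, tx))
  }
  dup <- duplicated(transitions[c("from", "treatment")])
  if (any(dup))
    stop("duplicate transition for (", transitions$from[dup][1], ", ",
         transitions$treatment[dup][1], ")")
  invisible(TRUE)
}
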