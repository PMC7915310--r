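# Treatment regimens: interval therapies, one-time debulk events, and the
# CSV/JSON record schema.

#' Build and validate a treatment regimen
#'
#' A regimen is a set of daily interval therapies over half-open 0-based
#' day ranges `[start_day, end_day)` plus one-time debulking events.
#' Concurrent interval therapies are rejected: at most one daily therapy
#' may be active on any given day.
#'
#' @param intervals data.frame with columns `kind` (one of
#'   `treatment_levels("interval")`), `start_day`, `end_day`; or `NULL`.
#' @param events data.frame with columns `kind` (`RT` or `SURG`), `day`,
#'   and optionally `fraction` (fraction of cells removed; `NA` uses the
#'   model default); or `NULL`.
#' @return Object of class `treatment_regimen`.
#' @export
#' @examples
#' treatment_regimen(
#'   intervals = data.frame(kind = "ADT1", start_day = 0, end_day = 300),
#'   events = data.frame(kind = "SURG", day = 150, fraction = 0.9))
treatment_regimen <- function(intervals = NULL, events = NULL) {
  if (is.null(intervals))
    intervals <- data.frame(kind = character(), start_day = integer(),
                            end_day = integer(), stringsAsFactors = FALSE)
  if (is.null(events))
    events <- data.frame(kind = character(), day = integer(),
                         fraction = numeric(), stringsAsFactors = FALSE)
  if (!all(c("kind", "start_day", "end_day") %in% names(intervals)))
    stop("intervals must have columns kind, start_day, end_day")
  if (!all(c("kind", "day") %in% names(events)))
    stop("events must have columns kind, day")
  if (is.null(events$fraction)) events$fraction <- rep(NA_real_, nrow(events))
  intervals <- data.frame(kind = as.character(intervals$kind),
                          start_day = as.integer(intervals$start_day),
                          end_day = as.integer(intervals$end_day),
                          stringsAsFactors = FALSE)
  events <- data.frame(kind = as.character(events$kind),
                       day = as.integer(events$day),
                       fraction = as.numeric(events$fraction),
                       stringsAsFactors = FALSE)
  bad <- setdiff(intervals$kind, INTERVAL_TREATMENTS)
  if (length(bad))
    stop("unknown interval treatment kind(s): ", paste(unique(bad), collapse = ", "),
         "; permitted: ", paste(INTERVAL_TREATMENTS, collapse = ", "))
  bad <- setdiff(events$kind, EVENT_TREATMENTS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(unique(bad), collapse = ", "),
         "; permitted: ", paste(EVENT_TREATMENTS, collapse = ", "))
  if (any(intervals$start_day < 0) || any(events$day < 0))
    stop("treatment days must be non-negative (0-based days from presentation)")
  if (any(intervals$start_day >= intervals$end_day))
    stop("each interval must satisfy start_day < end_day (half-open [start, end))")
  ok <- is.na(events$fraction) | (events$fraction >= 0 & events$fraction <= 1)
  if (!all(ok)) stop("event fraction must be in [0, 1] (or NA for the default)")
  n <- nrow(intervals)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (intervals$start_day[i] < intervals$end_day[j] &&
        intervals$start_day[j] < intervals$end_day[i])
      stop(sprintf(
        "concurrent therapies are not supported: %s [%d, %d) overlaps %s [%d, %d)",
        intervals$kind[i], intervals$start_day[i], intervals$end_day[i],
        intervals$kind[j], intervals$start_day[j], intervals$end_day[j]))
  }
  structure(list(intervals = intervals, events = events),
            class = "treatment_regimen")
}

#' @export
print.treatment_regimen <- function(x, ...) {
  cat(sprintf("Treatment regimen: %d interval(s), %d event(s)\n",
              nrow(x$intervals), nrow(x$events)))
  if (nrow(x$intervals)) print(x$intervals)
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Interval therapy administered on a given day
#'
#' Returns the unique interval therapy covering `day` (half-open
#' intervals), else `"NONE"`. Debulking events are not reported here.
#'
#' @param regimen A [treatment_regimen()].
#' @param day Integer day(s), 0-based.
#' @return Character vector of treatment kinds, one per `day`.
#' @export
#' @examples
#' reg <- treatment_regimen(data.frame(kind = "ADT1", start_day = 100, end_day = 200))
#' active_treatment_on_day(reg, c(99, 100, 199, 200))
active_treatment_on_day <- function(regimen, day) {
  stopifnot(inherits(regimen, "treatment_regimen"))
  vapply(day, function(d) {
    hit <- regimen$intervals$start_day <= d & d < regimen$intervals$end_day
    if (any(hit)) regimen$intervals$kind[which(hit)[1]] else "NONE"
  }, character(1))
}

#' Write / read a regimen as CSV
#'
#' One row per interval or event, columns `kind`, `start_day`, `end_day`,
#' `day`, `fraction`; interval rows leave `day`/`fraction` empty, event
#' rows leave `start_day`/`end_day` empty. Unknown treatment kinds are a
#' hard parse error naming the permitted kinds.
#'
#' @param regimen A [treatment_regimen()].
#' @param path File path.
#' @return `write_regimen_csv` returns `path` invisibly;
#'   `read_regimen_csv` returns a [treatment_regimen()].
#' @export
write_regimen_csv <- function(regimen, path) {
  stopifnot(inherits(regimen, "treatment_regimen"))
  iv <- regimen$intervals
  ev <- regimen$events
  df <- rbind(
    data.frame(kind = iv$kind, start_day = iv$start_day, end_day = iv$end_day,
               day = NA_integer_, fraction = NA_real_, stringsAsFactors = FALSE),
    data.frame(kind = ev$kind, start_day = NA_integer_, end_day = NA_integer_,
               day = ev$day, fraction = ev$fraction, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_regimen_csv
#' @export
read_regimen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("kind", "start_day", "end_day", "day", "fraction") %in% names(df)))
    stop("regimen CSV must have columns kind, start_day, end_day, day, fraction")
  is_iv <- df$kind %in% INTERVAL_TREATMENTS
  is_ev <- df$kind %in% EVENT_TREATMENTS
  if (!all(is_iv | is_ev))
    stop("unknown treatment kind(s): ",
         paste(unique(df$kind[!(is_iv | is_ev)]), collapse = ", "),
         "; permitted: ",
         paste(c(INTERVAL_TREATMENTS, EVENT_TREATMENTS), collapse = ", "))
  treatment_regimen(intervals = df[is_iv, c("kind", "start_day", "end_day")],
                    events = df[is_ev, c("kind", "day", "fraction")])
}

.regimen_to_list <- function(regimen) {
  list(intervals = regimen$intervals, events = regimen$events)
}

.regimen_from_list <- function(x) {
  iv <- if (length(x$intervals)) as.data.frame(x$intervals) else NULL
  ev <- if (length(x$events)) as.data.frame(x$events) else NULL
  treatment_regimen(intervals = iv, events = ev)
}
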