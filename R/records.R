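## Encounter-history containers: survey schedules, known-fate (radio)
## records and unknown-fate (marked) records.

#' Survey schedule
#'
#' The ordered times (days) at which the study area is surveyed for marked
#' animals (and radio-collared animals checked for mortality), plus the end
#' of the study.
#'
#' @param stimes Strictly increasing, nonempty vector of survey times (days).
#' @param study_end Study end time, at or after the last survey (default the
#'   last survey time).
#' @return An object of class `"survey_schedule"` with elements `stimes` and
#'   `study_end`.
#' @export
survey_schedule <- function(stimes, study_end = max(stimes)) {
  stimes <- as.numeric(stimes)
  if (length(stimes) == 0L) stop("'stimes' must be nonempty")
  if (is.unsorted(stimes, strictly = TRUE))
    stop("'stimes' must be strictly increasing")
  if (study_end < stimes[length(stimes)])
    stop("'study_end' must be at or after the last survey")
  structure(list(stimes = stimes, study_end = as.numeric(study_end)),
            class = "survey_schedule")
}

#' @export
print.survey_schedule <- function(x, ...) {
  cat(sprintf("Survey schedule: %d surveys, days %s..%s, study end %s\n",
              length(x$stimes), format(x$stimes[1]),
              format(x$stimes[length(x$stimes)]), format(x$study_end)))
  invisible(x)
}

#' Weekly survey schedule helper
#'
#' Surveys every `period` days starting at day `period`, up to `study_end`.
#'
#' @param study_end Length of the study in days.
#' @param period Days between surveys (default 7).
#' @return A [survey_schedule()].
#' @export
weekly_schedule <- function(study_end, period = 7) {
  survey_schedule(seq(period, study_end, by = period), study_end = study_end)
}

#' Known-fate (radio-collared) encounter record
#'
#' An individual whose status is ascertained with certainty at every check:
#' entry at time `entry` (staggered entry / left truncation), last known
#' alive at `last_alive`, first known dead at `first_dead` (`Inf` for a
#' right-censored individual).  The death time is known only to the interval
#' `[last_alive, first_dead]`.
#'
#' @param entry,last_alive,first_dead Times in days; `entry <= last_alive <
#'   first_dead`.
#' @param covariates Optional named vector; `NA` marks a missing value.
#' @param detections Optional 0/1 indicators at the surveys after `entry`
#'   (used only when the optional detection term of the known-fate
#'   likelihood is switched on).
#' @param id Optional identifier.
#' @return An object of class `"radio_record"`.
#' @export
radio_record <- function(entry, last_alive, first_dead = Inf,
                         covariates = NULL, detections = NULL, id = NULL) {
  if (entry > last_alive) stop("'entry' must not exceed 'last_alive'")
  if (last_alive >= first_dead)
    stop("'first_dead' must be after 'last_alive'")
  structure(list(entry = as.numeric(entry),
                 last_alive = as.numeric(last_alive),
                 first_dead = as.numeric(first_dead),
                 covariates = covariates, detections = detections, id = id),
            class = "radio_record")
}

#' Unknown-fate (marked) encounter record
#'
#' An individual marked at `entry` and searched for at every subsequent
#' survey, with per-survey detection probability below one.  Death is never
#' observed directly (by default the record is right-censored,
#' `first_dead = Inf`); the information carried is the number of sightings
#' `nn` and the time of the last sighting `last_seen`.
#'
#' @param entry Entry (marking) time in days.
#' @param last_seen Time of the last survey at which the animal was seen, or
#'   `NA` if it was never seen after marking.
#' @param nn Number of sightings (surveys at which it was detected).
#' @param history Optional 0/1 indicator vector over the surveys after
#'   `entry` (through the full schedule); when supplied it must be
#'   consistent with `nn` and `last_seen`.
#' @param first_dead Time the animal was first known dead, if its carcass
#'   was recovered; default `Inf` (right-censored).
#' @param covariates Optional named vector; `NA` marks a missing value.
#' @param id Optional identifier.
#' @return An object of class `"mark_record"`.
#' @export
mark_record <- function(entry, last_seen = NA, nn = 0, history = NULL,
                        first_dead = Inf, covariates = NULL, id = NULL) {
  entry <- as.numeric(entry)
  if (!is.null(history)) {
    history <- as.integer(history)
    if (any(history != 0L & history != 1L)) stop("'history' must be 0/1")
    nn <- sum(history)
  }
  nn <- as.integer(nn)
  if (nn == 0L) last_seen <- NA_real_
  if (nn > 0L && (is.na(last_seen) || !is.finite(last_seen)))
    stop("'last_seen' required when nn > 0")
  if (nn > 0L && last_seen < entry) stop("'last_seen' before 'entry'")
  tstar <- if (nn > 0L) last_seen else entry
  if (is.finite(first_dead) && first_dead <= tstar)
    stop("'first_dead' must be after the last time known alive")
  structure(list(entry = entry, last_seen = as.numeric(last_seen),
                 nn = nn, history = history,
                 first_dead = as.numeric(first_dead),
                 covariates = covariates, id = id),
            class = "mark_record")
}

#' Bundle radio and marked records into one dataset
#'
#' @param radio List of [radio_record()] objects.
#' @param marked List of [mark_record()] objects.
#' @return An object of class `"event_data"`.
#' @export
event_data <- function(radio = list(), marked = list()) {
  if (length(radio) &&
      !all(vapply(radio, inherits, TRUE, "radio_record")))
    stop("'radio' must be a list of radio_record objects")
  if (length(marked) &&
      !all(vapply(marked, inherits, TRUE, "mark_record")))
    stop("'marked' must be a list of mark_record objects")
  structure(list(radio = radio, marked = marked), class = "event_data")
}

#' @export
print.event_data <- function(x, ...) {
  ncen <- sum(vapply(x$radio, function(r) !is.finite(r$first_dead), TRUE))
  cat(sprintf(
    "Event-time dataset: %d known-fate records (%d right-censored), %d marked\n",
    length(x$radio), ncen, length(x$marked)))
  invisible(x)
}

## time the animal was last known alive with certainty (marked records)
tstar_of <- function(rec) if (rec$nn > 0L) rec$last_seen else rec$entry

## number of detection opportunities: surveys in (entry, tstar]
n_avail_of <- function(rec, schedule) {
  tstar <- tstar_of(rec)
  sum(schedule$stimes > rec$entry & schedule$stimes <= tstar)
}
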