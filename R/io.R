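## Plain-text interchange: encounter-history CSV (one row per individual),
## a JSON survey-schedule sidecar, samples as delimited text, and a JSON
## run manifest.  One dialect: comma-separated, UTF-8, '.' decimal, times
## in days, 1-based survey indices.

#' Write / read a survey schedule as JSON
#'
#' @param schedule A [survey_schedule()].
#' @param path File path.
#' @return `read_schedule_json` returns a [survey_schedule()].
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(stimes = schedule$stimes,
                            study_end = schedule$study_end),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  survey_schedule(x$stimes, x$study_end)
}

#' Write an integrated dataset to an encounter-history CSV
#'
#' Columns: `id`, `type` (`radio`/`marked`), `entry`, `last_alive`,
#' `first_dead` (empty = right-censored), `nn`, `last_seen`, `history` (0/1
#' string over the surveys after entry, marked records only), then one
#' column per covariate (empty cells = missing).
#'
#' @param data An [event_data()].
#' @param path File path.
#' @param schedule A [survey_schedule()] (used to reconstruct histories for
#'   marked records stored without one).
#' @return Invisibly, `path`.
#' @export
write_encounter_csv <- function(data, path, schedule) {
  recs <- c(data$radio, data$marked)
  covnames <- unique(unlist(lapply(recs, function(r) names(r$covariates))))
  row_of <- function(r, type, i) {
    hist <- ""
    if (type == "marked") {
      h <- r$history
      if (is.null(h)) {  # reconstruct the minimal consistent history
        st <- schedule$stimes[schedule$stimes > r$entry]
        h <- integer(length(st))
        if (r$nn > 0) {
          seen_at <- which(st <= r$last_seen)
          h[utils::tail(seen_at, r$nn)] <- 1L
        }
      }
      hist <- paste(h, collapse = "")
    }
    cv <- rep(NA_real_, length(covnames))
    names(cv) <- covnames
    if (!is.null(r$covariates)) cv[names(r$covariates)] <- unlist(r$covariates)
    c(list(id = if (is.null(r$id)) i else r$id, type = type,
           entry = r$entry,
           last_alive = if (type == "radio") r$last_alive else NA,
           first_dead = if (is.finite(r$first_dead)) r$first_dead else NA,
           nn = if (type == "marked") r$nn else NA,
           last_seen = if (type == "marked") r$last_seen else NA,
           history = hist),
      as.list(cv))
  }
  rows <- c(lapply(seq_along(data$radio),
                   function(i) row_of(data$radio[[i]], "radio", i)),
            lapply(seq_along(data$marked),
                   function(i) row_of(data$marked[[i]], "marked",
                                      length(data$radio) + i)))
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an encounter-history CSV
#'
#' Parses and validates the format written by [write_encounter_csv()].
#' Empty `first_dead` means right-censored; marked histories are checked
#' against the schedule (length must equal the number of surveys after
#' entry) and against `nn`/`last_seen`; violations raise errors naming the
#' offending row.
#'
#' @param path File path.
#' @param schedule A [survey_schedule()], or the path of a schedule JSON.
#' @return An [event_data()].
#' @export
read_encounter_csv <- function(path, schedule) {
  if (is.character(schedule)) schedule <- read_schedule_json(schedule)
  df <- utils::read.csv(path, colClasses = list(history = "character"),
                        na.strings = "")
  base_cols <- c("id", "type", "entry", "last_alive", "first_dead", "nn",
                 "last_seen", "history")
  covnames <- setdiff(names(df), base_cols)
  radio <- list(); marked <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    cv <- if (length(covnames)) unlist(row[covnames]) else NULL
    rec <- tryCatch({
      if (identical(row$type, "radio")) {
        radio_record(row$entry, row$last_alive,
                     if (is.na(row$first_dead)) Inf else row$first_dead,
                     covariates = cv, id = row$id)
      } else if (identical(row$type, "marked")) {
        hist <- NULL
        if (!is.na(row$history) && nzchar(row$history)) {
          hist <- as.integer(strsplit(row$history, "")[[1]])
          n_after <- sum(schedule$stimes > row$entry)
          if (length(hist) != n_after)
            stop("history length ", length(hist), " but ", n_after,
                 " surveys after entry")
          if (!is.na(row$nn) && sum(hist) != row$nn)
            stop("nn = ", row$nn, " inconsistent with history (",
                 sum(hist), " sightings)")
          st <- schedule$stimes[schedule$stimes > row$entry]
          ls_hist <- if (any(hist == 1L)) st[max(which(hist == 1L))]
                     else NA_real_
          if (!is.na(row$last_seen) &&
              (is.na(ls_hist) || abs(ls_hist - row$last_seen) > 1e-8))
            stop("last_seen inconsistent with history")
        }
        mark_record(row$entry,
                    last_seen = row$last_seen,
                    nn = if (is.na(row$nn)) 0 else row$nn,
                    history = hist,
                    first_dead = if (is.na(row$first_dead)) Inf
                                 else row$first_dead,
                    covariates = cv, id = row$id)
      } else stop("unknown type '", row$type, "'")
    }, error = function(e)
      stop("row ", i, " (id ", row$id, "): ", conditionMessage(e),
           call. = FALSE))
    if (inherits(rec, "radio_record")) radio[[length(radio) + 1L]] <- rec
    else marked[[length(marked) + 1L]] <- rec
  }
  event_data(radio, marked)
}

#' Persist posterior samples as delimited text with a JSON manifest
#'
#' Writes the pooled draws as a CSV (`chain`, `iteration`, one column per
#' parameter) and a sidecar JSON manifest recording the seed,
#' configuration, and acceptance rates, from which a run can be reproduced.
#'
#' @param samples An `ef_samples` object.
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @param extra Named list merged into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_samples_csv <- function(samples, path, extra = list()) {
  d <- dim(samples$draws)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(ch) {
    cbind(chain = ch, iteration = seq_len(d[1]),
          matrix(samples$draws[, , ch], d[1], d[2],
                 dimnames = list(NULL, samples$param_names)))
  }))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  manifest <- c(list(parameters = samples$param_names,
                     n_kept = d[1], n_chains = d[3],
                     acceptance = round(samples$accept, 4),
                     control = samples$control[c("n_iter", "burn_in",
                                                 "n_chains", "seed",
                                                 "algorithm")],
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  mpath <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(mpath)
}
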