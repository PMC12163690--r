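# Reading beep-level CSV, validity filtering, adherence accounting,
# exclusion and series assembly.

KNOWN_STATUSES <- c("completed", "dismissed", "ignored", "discontinued",
                    "missing")

#' Read a beep-level ESM CSV
#'
#' Strict reader for the frozen beep-table dialect: columns `person_id, day,
#' beep, prompt_time, response_time, initiation, status`, one numeric
#' `m_<motive>` item column per catalogue motive and a `mood` column;
#' timestamps ISO-8601; the empty cell is the missing marker. Unknown
#' statuses are rejected.
#'
#' @param path CSV file path.
#' @return data.frame of prompt records with POSIXct times.
#' @export
read_beeps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("person_id", "day", "beep", "prompt_time", "response_time",
            "initiation", "status", "mood")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("beep CSV lacks required column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$status), KNOWN_STATUSES)
  if (length(bad) > 0)
    stopf("unknown status value(s) in beep CSV: %s", paste(bad, collapse = ", "))
  if (!all(df$initiation %in% c("prompted", "manual")))
    stopf("initiation must be 'prompted' or 'manual'")
  df$prompt_time <- as.POSIXct(df$prompt_time, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  df$response_time <- as.POSIXct(df$response_time, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%S")
  df
}

# Beep-table column name of a motive item. Items are prefixed so motive
# names (e.g. "status", "control") can never collide with record fields.
item_col <- function(motive) paste0("m_", motive)

# Motive item columns present in a record table.
motive_columns <- function(records) {
  intersect(item_col(motive_catalogue()), names(records))
}

#' Apply the assessment validity filter
#'
#' Normalises record statuses per the study's validity rules: entries that
#' were dismissed, ignored or discontinued are missing; prompted entries
#' completed more than 30 minutes after the prompt are reclassified as
#' missing; manually initiated entries completed within 30 minutes after the
#' missed prompt remain valid. All item responses (and mood) of missing
#' records are erased. The filter is idempotent.
#'
#' @param records beep-record data.frame (see [read_beeps_csv()]).
#' @param window_s validity window in seconds (default 1800 = 30 minutes;
#'   a latency strictly greater than the window invalidates the record).
#' @return the records with `status` in `{completed, missing}`, erased
#'   responses on missing rows, and a `latency_s` column.
#' @export
apply_validity_filter <- function(records, window_s = 1800) {
  stopifnot(is.data.frame(records))
  status <- records$status
  unknown <- setdiff(unique(status), KNOWN_STATUSES)
  if (length(unknown) > 0)
    stopf("unknown status value(s): %s", paste(unknown, collapse = ", "))

  completed <- status == "completed"
  no_resp <- completed & is.na(records$response_time)
  if (any(no_resp)) {
    r <- records[which(no_resp)[1], ]
    stopf("record %s day %s beep %s is completed but has no response time",
          r$person_id, r$day, r$beep)
  }
  latency <- as.numeric(difftime(records$response_time, records$prompt_time,
                                 units = "secs"))
  late <- completed & latency > window_s
  valid <- completed & !late

  out <- records
  out$status <- ifelse(valid, "completed", "missing")
  out$latency_s <- ifelse(valid, latency, NA_real_)
  erase <- c(motive_columns(records), "mood")
  out[!valid, erase] <- NA
  out$response_time[!valid] <- as.POSIXct(NA)
  out
}

#' Adherence accounting
#'
#' Computes completed/possible counts, the adherence percentage, and the
#' prompted/manual split. Percentages round half-up to integers, the
#' convention used for reporting ESM adherence.
#'
#' @param completed either a filtered record data.frame (counts are taken
#'   from it) or the number of valid completed assessments.
#' @param n_participants number of participants.
#' @param slots_per_person scheduled assessments per participant.
#' @param prompted number of valid completed assessments that were prompted
#'   (taken from the records when a data.frame is given).
#' @return object of class `adherence_summary`: list with `n_completed`,
#'   `n_possible`, `adherence_pct`, `n_prompted`, `n_manual`,
#'   `prompted_pct`, `manual_pct`.
#' @export
#' @examples
#' compute_adherence(1481, n_participants = 51, slots_per_person = 36,
#'                   prompted = 1406)
compute_adherence <- function(completed, n_participants, slots_per_person,
                              prompted = NULL) {
  if (is.data.frame(completed)) {
    recs <- completed
    if (missing(n_participants))
      n_participants <- length(unique(recs$person_id))
    if (missing(slots_per_person))
      slots_per_person <- max(tapply(seq_len(nrow(recs)), recs$person_id,
                                     length))
    done <- recs$status == "completed"
    prompted <- sum(done & recs$initiation == "prompted")
    completed <- sum(done)
  }
  if (!is_count(completed)) stopf("completed must be a nonnegative count")
  possible <- n_participants * slots_per_person
  if (!is_count(possible) || possible == 0)
    stopf("zero possible assessment slots")
  out <- list(n_completed = as.integer(completed),
              n_possible = as.integer(possible),
              adherence_pct = round_half_up(100 * completed / possible))
  if (!is.null(prompted)) {
    if (prompted > completed) stopf("prompted count exceeds completed count")
    out$n_prompted <- as.integer(prompted)
    out$n_manual <- as.integer(completed - prompted)
    out$prompted_pct <- if (completed > 0)
      round_half_up(100 * prompted / completed) else 0
    out$manual_pct <- if (completed > 0)
      round_half_up(100 * (completed - prompted) / completed) else 0
  }
  structure(out, class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("Adherence: %d / %d assessments (%d%%)\n",
              x$n_completed, x$n_possible, x$adherence_pct))
  if (!is.null(x$n_prompted))
    cat(sprintf("  prompted %d (%d%%), manual %d (%d%%)\n",
                x$n_prompted, x$prompted_pct, x$n_manual, x$manual_pct))
  invisible(x)
}

#' Exclude participants with too few valid assessments
#'
#' Drops persons with strictly fewer than `threshold` valid completed
#' assessments (default 12 of 36, i.e. 33%).
#'
#' @param valid_counts named integer vector (person_id -> count of valid
#'   completed assessments) or a data.frame with `person_id` and `n_valid`.
#' @param threshold minimum valid assessments to be retained (default 12).
#' @return list with `retained` (character ids), `excluded` (data.frame of
#'   ids and counts) and `threshold`.
#' @export
exclude_low_adherence <- function(valid_counts, threshold = 12) {
  if (is.data.frame(valid_counts)) {
    counts <- stats::setNames(valid_counts$n_valid,
                              as.character(valid_counts$person_id))
  } else counts <- valid_counts
  if (is.null(names(counts))) stopf("valid_counts must be named by person")
  keep <- counts >= threshold
  if (!any(keep)) warnf("all %d persons fall below the %d-assessment threshold",
                        length(counts), threshold)
  list(retained = names(counts)[keep],
       excluded = data.frame(person_id = names(counts)[!keep],
                             n_valid = as.integer(counts[!keep]),
                             row.names = NULL),
       threshold = threshold)
}

# Count valid completed assessments per person.
valid_counts <- function(records) {
  tab <- tapply(records$status == "completed", records$person_id, sum)
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct a person series object
#'
#' Low-level constructor for the per-person multivariate time series that
#' enters network estimation: a `T x m` integer matrix on the full scheduled
#' slot grid (missing slots as NA rows), the day index of each slot, and
#' optionally the slot-level mood ratings.
#'
#' @param person_id identifier.
#' @param nodes ordered motive names (matrix columns).
#' @param mat `T x m` numeric matrix, NA marking missing responses.
#' @param day length-`T` day index of each slot.
#' @param mood optional length-`T` mood vector (1-7, NA when absent).
#' @return object of class `person_series`.
#' @export
person_series <- function(person_id, nodes, mat, day, mood = NULL) {
  mat <- as.matrix(mat)
  stopifnot(length(day) == nrow(mat), ncol(mat) == length(nodes))
  colnames(mat) <- nodes
  structure(list(person_id = person_id, nodes = nodes, mat = mat,
                 day = as.integer(day), mood = mood,
                 n_valid = sum(rowSums(!is.na(mat)) > 0)),
            class = "person_series")
}

#' @export
print.person_series <- function(x, ...) {
  cat(sprintf("Person series %s: %d slots x %d motives, %d answered\n",
              x$person_id, nrow(x$mat), length(x$nodes), x$n_valid))
  invisible(x)
}

#' Assemble analysis-ready per-person series
#'
#' Restricts each person's records to their selected motives and lays them
#' out on the full scheduled slot grid in chronological `(day, beep)` order.
#' Unanswered slots are present as all-NA rows so the lag structure is
#' preserved. Duplicate slot occupancy is an error.
#'
#' @param records validity-filtered beep records.
#' @param selection named list person_id -> character vector of selected
#'   motives (e.g. from [top_k_motives()]).
#' @return named list of [person_series()] objects, one per person in
#'   `selection` (persons absent from the records are skipped with a
#'   warning).
#' @export
assemble_series <- function(records, selection) {
  stopifnot(is.data.frame(records), is.list(selection))
  if (length(selection) == 0) stopf("empty motive selection")
  cols <- motive_columns(records)
  out <- list()
  for (pid in names(selection)) {
    sel <- selection[[pid]]
    if (length(sel) == 0) stopf("empty motive selection for person %s", pid)
    absent <- setdiff(item_col(sel), cols)
    if (length(absent) > 0)
      stopf("selected motive(s) missing from records for %s: %s", pid,
            paste(absent, collapse = ", "))
    rec <- records[records$person_id == pid, , drop = FALSE]
    if (nrow(rec) == 0) {
      warnf("person %s has no records; skipped", pid)
      next
    }
    if (anyDuplicated(rec[, c("day", "beep")]) > 0)
      stopf("duplicate slot occupancy for person %s", pid)
    rec <- rec[order(rec$day, rec$beep), , drop = FALSE]
    out[[pid]] <- person_series(pid, sel,
                                as.matrix(rec[, item_col(sel), drop = FALSE]),
                                rec$day, mood = rec$mood)
  }
  out
}
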