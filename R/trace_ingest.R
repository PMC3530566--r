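#' Read a raw location-event trace
#'
#' Expects delimited text with columns `user_id`, `timestamp` (ISO-8601,
#' e.g. `2009-01-05T08:00:00Z` or `2009-01-05 08:00:00`), `location_id`.
#'
#' @param path CSV file.
#' @param tz timezone all timestamps are interpreted in (default UTC).
#' @return data.table with `user_id`, `time` (POSIXct), `location_id`,
#'   sorted by user and time.
#' @export
read_traces <- function(path, tz = "UTC") {
  ev <- data.table::fread(path, colClasses = list(character = 1:3))
  .assert(all(c("user_id", "timestamp", "location_id") %in% names(ev)),
          "trace file needs user_id, timestamp, location_id columns")
  ts <- gsub("Z$", "", gsub("T", " ", ev$timestamp))
  ev[, time := as.POSIXct(ts, tz = tz, format = "%Y-%m-%d %H:%M:%S")]
  .assert(!anyNA(ev$time), "unparseable timestamps in trace file")
  data.table::setorder(ev, user_id, time)
  ev[, list(user_id, time, location_id)]
}

#' Majority-rule label for one time slot
#'
#' The slot is assigned the location with the largest total dwell time.
#' Dwell of an event runs from its timestamp to the next event or the slot
#' end, whichever comes first (spans never leak out of the slot). Ties are
#' broken in favour of the location occupied earliest in the slot; an empty
#' slot is [LP_MISSING].
#'
#' @param times event times (POSIXct or numeric seconds), sorted.
#' @param locations location id per event.
#' @param slot_start,slot_minutes slot boundary (same scale as `times`).
#' @return a single location id or [LP_MISSING].
#' @export
slot_majority <- function(times, locations, slot_start, slot_minutes = 60) {
  if (!length(times)) return(LP_MISSING)
  t <- as.numeric(times)
  o <- order(t)
  t <- t[o]; locations <- locations[o]
  slot_end <- as.numeric(slot_start) + slot_minutes * 60
  dwell <- pmin(c(t[-1], Inf), slot_end) - t
  dwell <- pmax(dwell, 0)
  agg <- rowsum(dwell, locations)
  first_seen <- tapply(t, locations, min)[rownames(agg)]
  win <- order(-agg[, 1], first_seen)[1]
  rownames(agg)[win]
}

#' Discretise raw events into per-user day matrices
#'
#' Applies the majority-dwell rule of [slot_majority()] to every
#' (user, day, slot) cell over the half-open slot grid `[t, t + slot)`.
#' Days inside a user's observed date range with no events become all-MISSING
#' rows, so calendar continuity is preserved for padding.
#'
#' @param events data.table from [read_traces()] (or with the same columns).
#' @param slot_minutes slot length (must divide 24 h).
#' @param tz timezone for the day/slot grid.
#' @return named list of [day_matrix()] objects, one per user.
#' @export
discretize_events <- function(events, slot_minutes = 60L, tz = "UTC") {
  n_slots <- n_slots_for(slot_minutes)
  ev <- data.table::as.data.table(events)
  if (!"time" %in% names(ev)) {
    .assert("timestamp" %in% names(ev), "events need a time/timestamp column")
    ts <- gsub("Z$", "", gsub("T", " ", ev$timestamp))
    ev[, time := as.POSIXct(ts, tz = tz, format = "%Y-%m-%d %H:%M:%S")]
    .assert(!anyNA(ev$time), "unparseable timestamps")
  }
  data.table::setorder(ev, user_id, time)
  ev[, secs := as.numeric(time)]
  ev[, date := format(time, "%Y-%m-%d", tz = tz)]
  hrs <- as.integer(format(ev$time, "%H", tz = tz))
  mns <- as.integer(format(ev$time, "%M", tz = tz))
  scs <- as.integer(format(ev$time, "%S", tz = tz))
  ev[, slot := pmin(((hrs * 3600L + mns * 60L + scs) %/%
                       (slot_minutes * 60L)) + 1L, n_slots)]
  ev[, sec_in_slot := (hrs * 3600 + mns * 60 + scs) %% (slot_minutes * 60)]
  ev[, nxt := data.table::shift(secs, -1L, fill = Inf), by = user_id]
  ev[, dwell := pmax(pmin(nxt - secs, slot_minutes * 60 - sec_in_slot), 0)]
  agg <- ev[, list(dwell = sum(dwell), first = min(secs)),
            by = list(user_id, date, slot, location_id)]
  data.table::setorder(agg, user_id, date, slot, -dwell, first)
  win <- agg[, utils::head(.SD, 1L), by = list(user_id, date, slot)]
  out <- list()
  for (uid in unique(win$user_id)) {
    wu <- win[win$user_id == uid]
    dates <- format(seq(as.Date(min(wu$date)), as.Date(max(wu$date)), by = 1))
    m <- matrix(LP_MISSING, length(dates), n_slots, dimnames = list(dates))
    m[cbind(match(wu$date, dates), wu$slot)] <- wu$location_id
    out[[uid]] <- day_matrix(m, uid, dates, slot_minutes)
  }
  out
}

#' Pad short same-location gaps in a slot sequence
#'
#' A maximal run of MISSING slots of length `<= max_gap_slots` whose two
#' flanking non-missing slots carry the same location is filled with that
#' location (the phone-off-at-home case). All other runs, including runs at
#' either end of the sequence, are left untouched. Works on the concatenated
#' multi-day sequence, so padding may cross midnight.
#'
#' @param x character vector of slot labels.
#' @param max_gap_slots maximum fillable run length (default 6).
#' @return padded copy of `x`.
#' @export
pad_gaps <- function(x, max_gap_slots = 6L) {
  r <- rle(x == LP_MISSING)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] > max_gap_slots) next
    if (i == 1L || i == length(r$values)) next
    left <- x[starts[i] - 1L]
    right <- x[ends[i] + 1L]
    if (left == right && left != LP_MISSING)
      x[starts[i]:ends[i]] <- left
  }
  x
}

#' Pad a day matrix along its chronological slot sequence
#'
#' @param mat a [day_matrix()].
#' @inheritParams pad_gaps
#' @return the padded day matrix (attributes preserved).
#' @export
pad_day_matrix <- function(mat, max_gap_slots = 6L) {
  a <- attributes(mat)
  seqv <- as.vector(t(.as_mat(mat)))           # row-major: calendar order
  padded <- pad_gaps(seqv, max_gap_slots)
  out <- matrix(padded, nrow(mat), ncol(mat), byrow = TRUE)
  attributes(out) <- a
  out
}

#' Exclude days with too much missing data
#'
#' @param mat a day matrix (padding already applied).
#' @param max_missing_fraction a day is kept iff its MISSING fraction is
#'   `<=` this bound (default 0.30).
#' @return list with `days` (kept day matrix) and `excluded`
#'   (data.frame: date, missing_fraction).
#' @export
filter_days <- function(mat, max_missing_fraction = 0.30) {
  frac <- rowMeans(.as_mat(mat) == LP_MISSING)
  keep <- frac <= max_missing_fraction
  a <- attributes(mat)
  kept <- .as_mat(mat)[keep, , drop = FALSE]
  kept <- day_matrix(kept, a$user_id %||% "user",
                     rownames(mat)[keep], a$slot_minutes %||% 60L)
  list(days = kept,
       excluded = data.frame(date = rownames(mat)[!keep] %||% character(),
                             missing_fraction = frac[!keep],
                             row.names = NULL))
}

#' Keep users with enough accepted days
#'
#' @param panel named list of day matrices (after [filter_days()]).
#' @param min_days minimum accepted-day count (default 30).
#' @return list with `panel` (kept users) and `rejected`
#'   (data.frame: user_id, n_days).
#' @export
accept_users <- function(panel, min_days = 30L) {
  n <- vapply(panel, nrow, integer(1))
  keep <- n >= min_days
  list(panel = panel[keep],
       rejected = data.frame(user_id = names(panel)[!keep],
                             n_days = unname(n[!keep]), row.names = NULL))
}

#' Full ingestion chain: events to accepted day matrices
#'
#' read/parse -> majority-rule discretisation -> gap padding -> 30% day
#' exclusion -> minimum-days user acceptance.
#'
#' @param events a data.table of events, or a path to a trace CSV.
#' @param slot_minutes slot length (30, 60 or 120 are the supported grids).
#' @param max_gap_slots padding bound (default 6 slots).
#' @param max_missing_fraction day-exclusion bound (default 0.30).
#' @param min_days user-acceptance bound (default 30).
#' @param tz timezone of the slot grid.
#' @return list with `panel` (named list of accepted day matrices) and
#'   `exclusions` (per-user excluded days, rejected users).
#' @export
ingest_traces <- function(events, slot_minutes = 60L, max_gap_slots = 6L,
                          max_missing_fraction = 0.30, min_days = 30L,
                          tz = "UTC") {
  if (is.character(events)) events <- read_traces(events, tz = tz)
  mats <- discretize_events(events, slot_minutes, tz = tz)
  excluded <- list()
  for (uid in names(mats)) {
    padded <- pad_day_matrix(mats[[uid]], max_gap_slots)
    fl <- filter_days(padded, max_missing_fraction)
    mats[[uid]] <- fl$days
    excluded[[uid]] <- fl$excluded
  }
  acc <- accept_users(mats, min_days)
  list(panel = acc$panel,
       exclusions = list(days = excluded, users = acc$rejected))
}

#' Write / read a day matrix as CSV
#'
#' One row per day: `date`, then one column per slot.
#' @param mat a day matrix.
#' @param path CSV file.
#' @export
write_day_matrix <- function(mat, path) {
  df <- data.frame(date = rownames(mat) %||% seq_len(nrow(mat)),
                   .as_mat(mat), check.names = FALSE)
  names(df) <- c("date", paste0("slot", seq_len(ncol(mat))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_day_matrix
#' @param user_id,slot_minutes metadata for the reconstructed object.
#' @export
read_day_matrix <- function(path, user_id = "user", slot_minutes = 60L) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$date, NULL)
  day_matrix(m, user_id, df$date, slot_minutes)
}
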