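`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Construct a day matrix
#'
#' A day matrix is the package's unit container: a character matrix with one
#' row per calendar day and one column per time slot. Entries are location
#' ids, [LP_OTHER] (lumped rare locations) or [LP_MISSING] (no data).
#'
#' @param x character matrix (days x slots).
#' @param user_id user identifier.
#' @param dates optional character vector of ISO dates (row names).
#' @param slot_minutes slot length in minutes.
#' @return the matrix with class `day_matrix` and metadata attributes.
#' @export
day_matrix <- function(x, user_id = "user", dates = NULL, slot_minutes = 60L) {
  .assert(is.matrix(x) && is.character(x), "day matrix must be a character matrix")
  if (!is.null(dates)) rownames(x) <- as.character(dates)
  attr(x, "user_id") <- user_id
  attr(x, "slot_minutes") <- as.integer(slot_minutes)
  class(x) <- c("day_matrix", class(x))
  x
}

#' @export
print.day_matrix <- function(x, ...) {
  cat(sprintf("<day_matrix> user=%s  %d days x %d slots (%d min), %.1f%% missing\n",
              attr(x, "user_id") %||% "?", nrow(x), ncol(x),
              attr(x, "slot_minutes") %||% 60L,
              100 * mean(unclass(x) == LP_MISSING)))
  invisible(x)
}

# Strip day_matrix class so plain matrix indexing applies.
.as_mat <- function(x) {
  class(x) <- "matrix"
  x
}

# Deterministic modal label: highest count, ties broken by first occurrence
# in scan order. MISSING entries are ignored; returns NA if all missing.
modal_label <- function(x) {
  x <- x[x != LP_MISSING & !is.na(x)]
  if (!length(x)) return(NA_character_)
  lev <- unique(x)                      # first-occurrence order
  cnt <- tabulate(match(x, lev))
  lev[which.max(cnt)]
}

# Shannon entropy (bits) of a count or probability vector.
shannon <- function(p, base = 2) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

# Slot index helpers: slots are 1-based, slot s covers
# [(s-1)*slot_minutes, s*slot_minutes) minutes after local midnight.
n_slots_for <- function(slot_minutes) {
  .assert(24 * 60 %% slot_minutes == 0, "slot length must divide 24 h")
  as.integer(24 * 60 / slot_minutes)
}

hours_to_slots <- function(from_hour, to_hour, slot_minutes = 60L) {
  # half-open hour window [from_hour, to_hour) -> slot indices
  per_hour <- 60 / slot_minutes
  seq.int(floor(from_hour * per_hour) + 1L, ceiling(to_hour * per_hour))
}
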