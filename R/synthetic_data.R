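#' Generator configuration for synthetic location-trace panels
#'
#' Bundles and validates the parameters of the synthetic panel generator.
#' Defaults describe a small smartphone-style panel: heavy-tailed location
#' frequencies, a few day-pattern templates per user dominated by a working
#' day, per-slot noise drawn preferentially from rare locations, night-time
#' phone-off gaps at home, and working-day lengths drawn from a two-sided
#' exponential-hazard departure model.
#'
#' @param n_users number of users.
#' @param n_days days per user.
#' @param n_locations locations per user.
#' @param alpha power-law exponent of the rank-frequency law (frequency of
#'   rank r proportional to r^-alpha); must exceed 1.
#' @param templates_per_user number of planted day templates K (>= 1).
#' @param noise_rate per-slot probability epsilon in `[0,1]` that a slot
#'   deviates from its template.
#' @param gap_spec list with `night_start`, `night_end` (hours, half-open
#'   window), `night_prob` (per-day probability the night window is a
#'   phone-off gap) and `random_gap_rate` (independent per-slot drop rate).
#' @param departure_params list with `T0` (typical work length, slots),
#'   `a_early`, `a_late` (per-slot hazard growth rates) and `h0` (baseline
#'   hazard); `NULL` disables departure jitter so the work template is fixed.
#' @param slot_minutes slot length in minutes (must divide 24 h).
#' @param noise_bias `"rank"` (noise location weight proportional to rank,
#'   i.e. rarer locations over-represented) or `"uniform"`.
#' @param event_minutes within-slot event emission resolution (minutes).
#' @param seed master RNG seed; per-user streams use `seed + user index`.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_users = 10L, n_days = 60L, n_locations = 50L,
                             alpha = 1.7, templates_per_user = 3L,
                             noise_rate = 0.05,
                             gap_spec = list(night_start = 1, night_end = 5,
                                             night_prob = 0.5,
                                             random_gap_rate = 0.02),
                             departure_params = list(T0 = 9, a_early = 0.7,
                                                     a_late = 0.5, h0 = 0.15),
                             slot_minutes = 60L,
                             noise_bias = c("rank", "uniform"),
                             event_minutes = 5L,
                             seed = 1L) {
  noise_bias <- match.arg(noise_bias)
  .assert(n_users >= 1 && n_days >= 1 && n_locations >= 1,
          "counts must be positive")
  .assert(templates_per_user >= 1, "templates_per_user must be >= 1")
  .assert(noise_rate >= 0 && noise_rate <= 1, "noise_rate must be in [0,1]")
  if (n_locations > 1) .assert(alpha > 1, "alpha must be > 1")
  if (!is.null(departure_params)) {
    .assert(all(c("T0", "a_early", "a_late") %in% names(departure_params)),
            "departure_params needs T0, a_early, a_late")
    .assert(departure_params$a_early > 0 && departure_params$a_late > 0,
            "hazard rates must be positive")
    departure_params$h0 <- departure_params$h0 %||% 0.05
  }
  gap_spec <- utils::modifyList(
    list(night_start = 1, night_end = 5, night_prob = 0.5,
         random_gap_rate = 0.02), gap_spec %||% list())
  cfg <- list(n_users = as.integer(n_users), n_days = as.integer(n_days),
              n_locations = as.integer(n_locations), alpha = alpha,
              templates_per_user = as.integer(templates_per_user),
              noise_rate = noise_rate, gap_spec = gap_spec,
              departure_params = departure_params,
              slot_minutes = as.integer(slot_minutes),
              noise_bias = noise_bias,
              event_minutes = as.integer(event_minutes),
              seed = as.integer(seed))
  n_slots_for(cfg$slot_minutes)  # validates divisibility
  class(cfg) <- "generator_config"
  cfg
}

#' Ranked power-law location alphabet
#'
#' Relative visit frequencies over `n_locations` ranks, with the frequency of
#' rank r proportional to r^-alpha (normalised to sum to 1).
#'
#' @param n_locations number of locations (>= 1).
#' @param alpha power-law exponent (> 1 unless `n_locations == 1`, where the
#'   alphabet is the degenerate single location with frequency 1).
#' @return data.frame with `rank`, `location_id`, `freq` (non-increasing).
#' @export
sample_location_alphabet <- function(n_locations, alpha = 1.7) {
  .assert(length(n_locations) == 1 && n_locations >= 1,
          "n_locations must be a positive count")
  n_locations <- as.integer(n_locations)
  if (n_locations == 1L)
    return(data.frame(rank = 1L, location_id = "L1", freq = 1))
  .assert(alpha > 1, "alpha must be > 1")
  w <- (1:n_locations)^(-alpha)
  data.frame(rank = 1:n_locations,
             location_id = paste0("L", 1:n_locations),
             freq = w / sum(w))
}

# Noise-location sampling weights over the alphabet: linear-in-rank tail
# bias (rarer locations proportionally more likely) or uniform.
noise_weights <- function(n_locations, noise_bias = "rank") {
  w <- if (noise_bias == "rank") as.numeric(1:n_locations)
       else rep(1, n_locations)
  w / sum(w)
}

#' Superimpose slot noise on a template day
#'
#' Each slot independently keeps its template location with probability
#' `1 - noise_rate`; otherwise it is replaced by a location drawn from the
#' alphabet under the noise law (which may, by chance, equal the template).
#'
#' @param template character vector of location ids (no MISSING slots).
#' @param noise_rate epsilon in `[0,1]`.
#' @param alphabet data.frame from [sample_location_alphabet()].
#' @param noise_bias `"rank"` or `"uniform"`.
#' @return character vector of the same length.
#' @export
generate_day <- function(template, noise_rate, alphabet,
                         noise_bias = "rank") {
  .assert(!any(template == LP_MISSING), "template must have no MISSING slots")
  .assert(noise_rate >= 0 && noise_rate <= 1, "noise_rate must be in [0,1]")
  n <- length(template)
  if (noise_rate == 0) return(template)
  hit <- runif(n) < noise_rate
  if (any(hit)) {
    q <- noise_weights(nrow(alphabet), noise_bias)
    template[hit] <- sample(alphabet$location_id, sum(hit),
                            replace = TRUE, prob = q)
  }
  template
}

#' Sample working-day lengths from the two-sided hazard model
#'
#' Discrete-time survival draw: at each slot t the probability of leaving is
#' `h(t) = min(1, h0 * exp(a_early * (t - T0)))` for `t <= T0` and
#' `h(t) = min(1, h0 * exp(a_late * (t - T0)))` afterwards; the day length is
#' the first t at which the leave event fires. The late hazard reaches 1 in
#' finite time, so lengths are almost surely finite.
#'
#' @param n number of draws.
#' @param T0 typical-length anchor (slots).
#' @param a_early,a_late per-slot hazard growth rates (positive).
#' @param h0 baseline hazard at `t = T0` (in (0,1]).
#' @return integer vector of day lengths (slots, >= 1).
#' @seealso [departure_pdf()] for the matching analytic distribution.
#' @export
sample_departure_time <- function(n = 1L, T0, a_early, a_late, h0 = 0.05) {
  .assert(a_early > 0 && a_late > 0, "hazard rates must be positive")
  .assert(h0 > 0 && h0 <= 1, "h0 must be in (0,1]")
  t_max <- ceiling(T0 + log(1 / h0) / a_late) + 1L  # h = 1 from here on
  t <- 1:t_max
  h <- departure_hazard(t, T0, a_early, a_late, h0)
  # survival sampling: length = first slot whose hazard fires
  out <- integer(n)
  u <- matrix(runif(n * t_max), nrow = t_max)
  fired <- u < h
  out <- apply(fired, 2, function(z) which(z)[1])
  out[is.na(out)] <- t_max  # unreachable (h(t_max) = 1) but be safe
  as.integer(out)
}

departure_hazard <- function(t, T0, a_early, a_late, h0) {
  a <- ifelse(t <= T0, a_early, a_late)
  pmin(1, h0 * exp(a * (t - T0)))
}

# Planted day templates for one user. Template 1 is the working day (home
# nights flanking a contiguous work block); template 2 a home day with a
# short errand; template 3 a leisure day; further templates place a random
# mid-frequency location over the daytime hours.
.user_templates <- function(K, n_slots, alphabet, slot_minutes, T0 = 9) {
  ids <- alphabet$location_id
  n_loc <- length(ids)
  home <- ids[1]
  work <- if (n_loc >= 2) ids[2] else ids[1]
  per_hour <- 60 / slot_minutes
  hrs <- function(a, b) hours_to_slots(a, b, slot_minutes)
  base <- rep(home, n_slots)
  tpl <- vector("list", K)
  arrival_hour <- 8
  work_slots <- (arrival_hour * per_hour + 1):
    min(n_slots, arrival_hour * per_hour + T0)
  t1 <- base; t1[work_slots] <- work
  tpl[[1]] <- t1
  if (K >= 2) {
    t2 <- base
    if (n_loc >= 5) t2[hrs(14, 16)] <- ids[5]
    tpl[[2]] <- t2
  }
  if (K >= 3) {
    t3 <- base
    if (n_loc >= 4) t3[hrs(10, 20)] <- ids[4]
    tpl[[3]] <- t3
  }
  if (K >= 4) {
    for (k in 4:K) {
      tk <- base
      body <- sample(ids[seq_len(min(n_loc, 8))[-1]], 2)
      tk[hrs(9, 15)] <- body[1]
      tk[hrs(15, 21)] <- body[2]
      tpl[[k]] <- tk
    }
  }
  list(templates = tpl, home = home, work = work,
       arrival_slot = work_slots[1], work_template = 1L)
}

# Emit 5-minute events for one day. labels has NA for gap slots. At a label
# change the first `carry` events of the new slot keep the previous label so
# majority-rule ingestion is exercised non-trivially (carry is small enough
# never to flip the majority).
.emit_day_events <- function(labels, date, slot_minutes, event_minutes) {
  n_slots <- length(labels)
  per_slot <- slot_minutes %/% event_minutes
  keep <- which(!is.na(labels))
  if (!length(keep)) return(NULL)
  mins <- locs <- vector("list", length(keep))
  max_carry <- min(2L, per_slot %/% 3L)
  for (k in seq_along(keep)) {
    s <- keep[k]
    m <- (s - 1L) * slot_minutes + seq(0L, slot_minutes - event_minutes,
                                       by = event_minutes)
    l <- rep(labels[s], per_slot)
    if (s > 1L && !is.na(labels[s - 1L]) && labels[s - 1L] != labels[s] &&
        max_carry > 0L) {
      carry <- sample.int(max_carry + 1L, 1L) - 1L
      if (carry > 0L) l[seq_len(carry)] <- labels[s - 1L]
    }
    mins[[k]] <- m
    locs[[k]] <- l
  }
  data.table::data.table(minute = unlist(mins), location_id = unlist(locs),
                         date = date)
}

#' Generate a synthetic event panel with ground truth
#'
#' Draws a full panel of raw timestamped location events: per user, `K`
#' planted day templates, a per-day template assignment (working day with
#' probability 5/7 when `K >= 2`), working-day departure jitter via
#' [sample_departure_time()], per-slot noise via [generate_day()], night-time
#' phone-off gaps (the night window is home-flanked by construction) and
#' random per-slot gaps. Events are emitted at `event_minutes` resolution so
#' the majority-rule ingester is exercised end to end.
#'
#' @param config a [generator_config()].
#' @return list with `events` (data.table: user_id, timestamp (ISO-8601 UTC),
#'   location_id) and `truth` (per-user list: templates, assignment,
#'   clean_days, noisy_days day matrices, alphabet, home/work, config echo).
#' @export
generate_panel <- function(config) {
  .assert(inherits(config, "generator_config"), "config must be a generator_config")
  n_slots <- n_slots_for(config$slot_minutes)
  dates <- format(as.Date("2009-01-05") + seq_len(config$n_days) - 1L)
  gap <- config$gap_spec
  night_slots <- hours_to_slots(gap$night_start, gap$night_end,
                                config$slot_minutes)
  events <- vector("list", config$n_users)
  truth <- vector("list", config$n_users)
  alphabet <- sample_location_alphabet(config$n_locations, config$alpha)
  T0 <- if (is.null(config$departure_params)) 9 else config$departure_params$T0
  for (u in seq_len(config$n_users)) {
    set.seed(config$seed + u)            # deterministic per-user stream
    uid <- sprintf("u%03d", u)
    tp <- .user_templates(config$templates_per_user, n_slots, alphabet,
                          config$slot_minutes, T0 = T0)
    K <- config$templates_per_user
    wts <- if (K >= 2) c(5 / 7, rep((2 / 7) / (K - 1), K - 1)) else 1
    assignment <- sample.int(K, config$n_days, replace = TRUE, prob = wts)
    clean <- matrix(LP_MISSING, config$n_days, n_slots)
    noisy <- clean
    day_events <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      day <- tp$templates[[assignment[d]]]
      if (assignment[d] == tp$work_template &&
          !is.null(config$departure_params)) {
        dp <- config$departure_params
        len <- sample_departure_time(1L, dp$T0, dp$a_early, dp$a_late, dp$h0)
        len <- min(len, n_slots - tp$arrival_slot)  # leave room to get home
        day <- tp$templates[[assignment[d]]]
        work_span <- tp$arrival_slot:(tp$arrival_slot + len - 1L)
        day[day == tp$work] <- tp$home
        day[work_span] <- tp$work
      }
      clean[d, ] <- day
      nd <- generate_day(day, config$noise_rate, alphabet, config$noise_bias)
      noisy[d, ] <- nd
      lab <- nd
      if (gap$night_prob > 0 && runif(1) < gap$night_prob)
        lab[night_slots] <- NA
      if (gap$random_gap_rate > 0)
        lab[runif(n_slots) < gap$random_gap_rate] <- NA
      day_events[[d]] <- .emit_day_events(lab, dates[d], config$slot_minutes,
                                          config$event_minutes)
    }
    ev <- data.table::rbindlist(day_events)
    ev[, timestamp := paste0(date, "T",
                             sprintf("%02d:%02d:00", minute %/% 60L,
                                     minute %% 60L), "Z")]
    events[[u]] <- ev[, list(user_id = uid, timestamp, location_id)]
    truth[[u]] <- list(
      user_id = uid,
      templates = tp$templates,
      assignment = assignment,
      clean_days = day_matrix(clean, uid, dates, config$slot_minutes),
      noisy_days = day_matrix(noisy, uid, dates, config$slot_minutes),
      alphabet = alphabet,
      home = tp$home, work = tp$work,
      work_template = tp$work_template,
      arrival_slot = tp$arrival_slot,
      departure_params = config$departure_params)
    names(truth)[u] <- uid
  }
  list(events = data.table::rbindlist(events), truth = truth, config = config)
}

#' Analytic entropies implied by a user's planted ground truth
#'
#' Population values of the bare and clustered life entropy for the mixture
#' the generator planted: within cluster c, slot j carries the template
#' location with probability `1 - eps` plus `eps` times the noise law;
#' across clusters slots mix with the realised assignment weights. Exact
#' when departure jitter and gaps are disabled.
#'
#' Alongside the population entropies, the exact finite-sample expectations
#' of the plug-in estimators are returned (`*_plugin` fields): the plug-in
#' entropy is a sum of per-location terms depending only on the binomial
#' marginal counts, so `E[H_hat] = -sum_i sum_k P(c_i = k) (k/N) log2(k/N)`
#' in closed form. With few days and a wide noise tail the plug-in values
#' sit well below the population ones, and a measured entropy drop must be
#' compared against the plug-in expectation, not the population value.
#'
#' @param user_truth one element of `generate_panel()$truth`.
#' @param noise_rate,noise_bias the generator settings used.
#' @return list with `S_bare`, `S_clustered`, `delta`, `relative_pct` and
#'   the matching `S_bare_plugin`, `S_clustered_plugin`, `delta_plugin`,
#'   `relative_pct_plugin`.
#' @export
analytic_entropy <- function(user_truth, noise_rate, noise_bias = "rank") {
  ids <- user_truth$alphabet$location_id
  q <- noise_weights(length(ids), noise_bias)
  tpl <- user_truth$templates
  n_slots <- length(tpl[[1]])
  n_c <- tabulate(user_truth$assignment, nbins = length(tpl))
  N <- sum(n_c)
  w <- n_c / N
  # exact expectation of the plug-in entropy of a multinomial(N, p) sample
  e_plugin <- function(p, N) {
    k <- seq_len(N)
    f <- (k / N) * log2(k / N)            # term value at count k
    -sum(vapply(p[p > 0], function(pi)
      sum(stats::dbinom(k, N, pi) * f), numeric(1)))
  }
  Hc <- Hc_plug <- numeric(length(tpl))
  p_bare <- matrix(0, length(ids), n_slots)
  for (c in seq_along(tpl)) {
    hj <- hj_plug <- numeric(n_slots)
    for (j in seq_len(n_slots)) {
      p <- noise_rate * q
      i <- match(tpl[[c]][j], ids)
      p[i] <- p[i] + (1 - noise_rate)
      hj[j] <- shannon(p)
      hj_plug[j] <- e_plugin(p, n_c[c])
      p_bare[, j] <- p_bare[, j] + w[c] * p
    }
    Hc[c] <- mean(hj)
    Hc_plug[c] <- mean(hj_plug)
  }
  S_clustered <- sum(w * Hc)
  S_bare <- mean(apply(p_bare, 2, shannon))
  S_cl_plug <- sum(w * Hc_plug)
  S_bare_plug <- mean(apply(p_bare, 2, e_plugin, N = N))
  delta <- S_bare - S_clustered
  delta_plug <- S_bare_plug - S_cl_plug
  list(S_bare = S_bare, S_clustered = S_clustered, delta = delta,
       relative_pct = if (S_bare > 0) 100 * delta / S_bare else 0,
       S_bare_plugin = S_bare_plug, S_clustered_plugin = S_cl_plug,
       delta_plugin = delta_plug,
       relative_pct_plugin =
         if (S_bare_plug > 0) 100 * delta_plug / S_bare_plug else 0)
}

#' Write a raw event trace as CSV
#' @param events data.table/data.frame with user_id, timestamp, location_id.
#' @param path output file.
#' @export
write_traces <- function(events, path) {
  data.table::fwrite(events[, c("user_id", "timestamp", "location_id")], path)
  invisible(path)
}

#' Serialise panel ground truth as JSON
#' @param truth the `truth` element of [generate_panel()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  slim <- lapply(truth, function(tu) list(
    user_id = tu$user_id,
    templates = tu$templates,
    assignment = tu$assignment,
    alphabet = tu$alphabet,
    home = tu$home, work = tu$work,
    departure_params = tu$departure_params))
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
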