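#' Identify a user's work location and regular-worker status
#'
#' Home is taken as the modal night-time location; the work candidate is the
#' non-home location with the largest occupancy in the daytime window. The
#' user qualifies as a regular worker when that location appears on at least
#' `min_workdays` days with a run of `min_consecutive` or more consecutive
#' slots.
#'
#' @param mat a (thresholded) day matrix.
#' @param daytime_hours half-open hour window scanned for work (default
#'   `c(9, 17)`).
#' @param night_hours half-open hour window defining home (default `c(0, 6)`).
#' @param min_workdays minimum qualifying working days (default 20).
#' @param min_consecutive minimum consecutive work slots in a qualifying day.
#' @return list with `work` (location id or `NULL`), `home`, `n_workdays`,
#'   `qualified`.
#' @export
find_work_location <- function(mat, daytime_hours = c(9, 17),
                               night_hours = c(0, 6),
                               min_workdays = 20L, min_consecutive = 4L) {
  m <- .as_mat(mat)
  slot_minutes <- attr(mat, "slot_minutes") %||% (24 * 60 / ncol(m))
  day_slots <- hours_to_slots(daytime_hours[1], daytime_hours[2], slot_minutes)
  night_slots <- hours_to_slots(night_hours[1], night_hours[2], slot_minutes)
  home <- modal_label(m[, night_slots, drop = FALSE])
  if (is.na(home)) home <- modal_label(m)
  day_obs <- m[, day_slots, drop = FALSE]
  day_obs <- day_obs[day_obs != LP_MISSING & day_obs != home]
  if (!length(day_obs))
    return(list(work = NULL, home = home, n_workdays = 0L, qualified = FALSE))
  lev <- unique(day_obs)
  work <- lev[which.max(tabulate(match(day_obs, lev)))]
  runs_ok <- apply(m, 1, function(d) {
    r <- rle(d == work)
    any(r$values & r$lengths >= min_consecutive)
  })
  n_workdays <- sum(runs_ok)
  list(work = work, home = home, n_workdays = n_workdays,
       qualified = n_workdays >= min_workdays)
}

#' Working-day length table
#'
#' For every day containing the work location, the length is
#' `last work slot - first work slot + 1` (first-to-last convention: a lunch
#' break elsewhere does not shorten the day). Lengths are z-scored with the
#' user's own mean and standard deviation for cross-user pooling.
#'
#' @param mat a day matrix.
#' @param work_location the work location id.
#' @param min_run only count days where the work location occurs in a run of
#'   at least this many consecutive slots (default 1 = every appearance; the
#'   pipeline uses its `min_consecutive` so that an isolated noise slot at
#'   the work location does not masquerade as a working day).
#' @return data.frame of class `workday_table`: `date`, `arrival`,
#'   `departure` (slot indices), `length` (slots), `z`.
#' @export
day_lengths <- function(mat, work_location, min_run = 1L) {
  m <- .as_mat(mat)
  rows <- lapply(seq_len(nrow(m)), function(d) {
    at <- which(m[d, ] == work_location)
    if (!length(at)) return(NULL)
    r <- rle(m[d, ] == work_location)
    if (max(r$lengths[r$values]) < min_run) return(NULL)
    data.frame(date = rownames(m)[d] %||% as.character(d),
               arrival = min(at), departure = max(at),
               length = max(at) - min(at) + 1L)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(date = character(), arrival = integer(),
                      departure = integer(), length = integer())
  out$z <- if (nrow(out) >= 2 && stats::sd(out$length) > 0)
    (out$length - mean(out$length)) / stats::sd(out$length)
  else rep(NA_real_, nrow(out))
  class(out) <- c("workday_table", class(out))
  out
}

#' Pool scaled working-day lengths across users
#'
#' @param tables list of [day_lengths()] tables.
#' @param min_workdays users with fewer working days are excluded.
#' @return data.frame with `user_id` (list index or name), `length`, `z`.
#' @export
pool_day_lengths <- function(tables, min_workdays = 20L) {
  nm <- names(tables) %||% as.character(seq_along(tables))
  keep <- vapply(tables, nrow, integer(1)) >= min_workdays
  rows <- lapply(which(keep), function(i)
    data.frame(user_id = nm[i], length = tables[[i]]$length,
               z = tables[[i]]$z))
  out <- do.call(rbind, rows)
  out %||% data.frame(user_id = character(), length = integer(),
                      z = numeric())
}

#' Analytic departure-time distribution
#'
#' Discrete-time survival construction over a grid of day lengths: the
#' per-slot hazard grows exponentially at rate `a_early` below the typical
#' length `T0` and at rate `a_late` above it, sharing the baseline `h0` at
#' `T0` (so the hazard is continuous there):
#' `h(t) = min(1, h0 exp(a * (t - T0)))`, `pdf(t) = h(t) prod_{s<t}(1-h(s))`,
#' normalised over the grid.
#'
#' @param model list with `T0`, `a_early`, `a_late`, `h0` (a
#'   `departure_model` fit works too).
#' @param grid ordered vector of lengths; the default covers slot 1 up to
#'   the point where the late hazard saturates at 1 (all mass enclosed).
#' @return data.frame with `t`, `hazard`, `pdf` (summing to 1).
#' @export
departure_pdf <- function(model, grid = NULL) {
  .assert(model$a_early > 0 && model$a_late > 0, "rates must be positive")
  h0 <- model$h0 %||% 0.05
  grid <- grid %||%
    seq_len(ceiling(model$T0 + log(1 / h0) / model$a_late) + 1)
  h_raw <- h0 * exp(ifelse(grid <= model$T0, model$a_early, model$a_late) *
                      (grid - model$T0))
  if (h_raw[1] > 1)
    warning("hazard exceeds 1 at the grid start; clipping")
  h <- pmin(1, h_raw)
  surv <- cumprod(1 - h)
  pdf <- h * c(1, utils::head(surv, -1))
  s <- sum(pdf)
  .assert(s > 0, "degenerate hazard: zero mass on grid")
  data.frame(t = grid, hazard = h, pdf = pdf / s)
}

.departure_nll <- function(par, t_obs, grid) {
  # par: (logit h0, T0, log a_early, log a_late)
  h0 <- stats::plogis(par[1])
  T0 <- par[2]
  ae <- exp(par[3]); al <- exp(par[4])
  if (!is.finite(ae) || !is.finite(al) || ae <= 0 || al <= 0) return(1e10)
  pdf <- tryCatch(
    suppressWarnings(departure_pdf(list(T0 = T0, a_early = ae, a_late = al,
                                        h0 = h0), grid)$pdf),
    error = function(e) NULL)
  if (is.null(pdf)) return(1e10)
  p <- pdf[match(t_obs, grid)]
  if (anyNA(p)) return(1e10)
  # floor keeps the surface finite where the fitted support misses data,
  # so the optimiser can climb out instead of hitting a flat penalty
  -sum(log(pmax(p, 1e-12)))
}

#' Maximum-likelihood fit of the two-hazard departure model
#'
#' Fits `(h0, T0, a_early, a_late)` to pooled day lengths under the
#' [departure_pdf()] construction by numerical MLE (Nelder-Mead on
#' transformed parameters), with standard errors from the observed
#' information (numerical Hessian) and a Kolmogorov-Smirnov goodness-of-fit
#' statistic. Lengths may be raw slots (integers) or scaled units; in the
#' latter case supply `step`, the grid spacing corresponding to one slot, so
#' rates are reported in both per-grid-step and per-slot units.
#'
#' @param lengths numeric vector of pooled day lengths (>= 100 by default).
#' @param step grid spacing (default 1 = raw slots).
#' @param min_n minimum sample size (default 100).
#' @param start optional named list of starting values.
#' @return object of class `departure_model`: `T0`, `a_early`, `a_late`,
#'   `h0`, `se` (named, for T0 and the log-rates mapped back), `rates_per_slot`,
#'   `ks`, `logLik`, `n`, `convergence`, `grid`.
#' @export
fit_departure_model <- function(lengths, step = 1, min_n = 100L,
                                start = NULL) {
  lengths <- lengths[is.finite(lengths)]
  .assert(length(lengths) >= min_n,
          sprintf("need at least %d pooled lengths", min_n))
  .assert(stats::sd(lengths) > 0, "degenerate sample: constant lengths")
  # snap observations onto a uniform grid and optimise on the dimensionless
  # index scale, so the fit is exactly invariant under affine rescaling of
  # the lengths (with `step` rescaled along) and numerically stable for
  # z-scored inputs
  lo <- floor(min(lengths) / step) * step
  idx <- pmax(1L, as.integer(round((lengths - lo) / step)) + 1L)
  grid_i <- seq_len(max(idx) + 10L)
  st <- if (is.null(start))
    list(h0 = 0.05, T0 = stats::median(idx), a_early = 0.02, a_late = 0.02)
  else list(h0 = start$h0 %||% 0.05,
            T0 = (start$T0 - lo) / step + 1,
            a_early = start$a_early * step, a_late = start$a_late * step)
  par0 <- c(stats::qlogis(st$h0), st$T0, log(st$a_early), log(st$a_late))
  opt <- stats::optim(par0, .departure_nll, t_obs = idx, grid = grid_i,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-10))
  # restart from the found optimum: Nelder-Mead on 4 parameters benefits
  # from a fresh simplex before the Hessian is taken
  opt <- stats::optim(opt$par, .departure_nll, t_obs = idx, grid = grid_i,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-10),
                      hessian = TRUE)
  if (opt$convergence != 0)
    stop("departure-model fit did not converge (code ", opt$convergence,
         "); value trace: ", paste(signif(opt$par, 4), collapse = ", "))
  h0 <- stats::plogis(opt$par[1])
  T0_i <- opt$par[2]
  ae_i <- exp(opt$par[3]); al_i <- exp(opt$par[4])
  se_t <- tryCatch({
    v <- diag(solve(opt$hessian))
    v[v < 0] <- NA_real_    # boundary-flat directions: no Wald SE
    sqrt(v)
  }, error = function(e) rep(NA_real_, 4))
  # delta method back to natural scale, then to caller units
  se <- c(h0 = se_t[1] * h0 * (1 - h0), T0 = se_t[2] * step,
          a_early = se_t[3] * ae_i / step, a_late = se_t[4] * al_i / step)
  pdf <- departure_pdf(list(T0 = T0_i, a_early = ae_i, a_late = al_i,
                            h0 = h0), grid_i)
  cdf_fit <- cumsum(pdf$pdf)
  cdf_emp <- stats::ecdf(idx)(grid_i)
  out <- list(T0 = lo + (T0_i - 1) * step,
              a_early = ae_i / step, a_late = al_i / step, h0 = h0, se = se,
              rates_per_slot = c(a_early = ae_i, a_late = al_i),
              ks = max(abs(cdf_emp - cdf_fit)), logLik = -opt$value,
              n = length(idx), convergence = opt$convergence,
              grid = lo + (grid_i - 1) * step, step = step)
  class(out) <- "departure_model"
  out
}

#' @export
print.departure_model <- function(x, ...) {
  cat(sprintf(paste0("<departure_model> T0=%.3f h0=%.4f a_early=%.4f ",
                     "a_late=%.4f (per slot: %.4f/%.4f) KS=%.4f n=%d\n"),
              x$T0, x$h0, x$a_early, x$a_late,
              x$rates_per_slot[1], x$rates_per_slot[2], x$ks, x$n))
  invisible(x)
}
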