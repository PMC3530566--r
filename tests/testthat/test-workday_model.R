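# a textbook 9-to-5 user: home nights, work hours 9-17
nine_to_five <- function(n_work = 25, n_home = 10) {
  work <- paste0(strrep("H", 9), strrep("W", 8), strrep("H", 7))
  home <- strrep("H", 24)
  toy_days(c(rep(work, n_work), rep(home, n_home)))
}

test_that("work location identification applies the qualification rules", {
  m <- nine_to_five()
  wl <- find_work_location(m)
  expect_identical(wl$work, "W")
  expect_identical(wl$home, "H")
  expect_true(wl$qualified)
  expect_equal(wl$n_workdays, 25)

  const <- toy_days(rep(strrep("H", 24), 40))
  wl2 <- find_work_location(const)
  expect_null(wl2$work)
  expect_false(wl2$qualified)

  few <- nine_to_five(n_work = 10, n_home = 30)
  wl3 <- find_work_location(few)
  expect_identical(wl3$work, "W")
  expect_false(wl3$qualified)              # 10 < 20 working days
})

test_that("day lengths use the first-to-last convention and z-score", {
  work <- paste0(strrep("H", 9), strrep("W", 8), strrep("H", 7))
  lunch <- paste0(strrep("H", 9), "WWW", "H", "WWWW", strrep("H", 7))
  short <- paste0(strrep("H", 9), "WWWWW", strrep("H", 10))
  m <- toy_days(c(work, lunch, short, strrep("H", 24)))
  dl <- day_lengths(m, "W")
  expect_equal(nrow(dl), 3)                # home day skipped
  expect_equal(dl$length, c(8, 8, 5))      # lunch break does not shorten
  expect_equal(dl$arrival, c(10, 10, 10))
  expect_equal(mean(dl$z), 0, tolerance = 1e-12)
  expect_equal(sd(dl$z), 1, tolerance = 1e-12)
  # min_run filters isolated noise appearances
  noisy <- paste0(strrep("H", 5), "W", strrep("H", 18))
  m2 <- toy_days(c(work, noisy))
  expect_equal(nrow(day_lengths(m2, "W", min_run = 4)), 1)
})

test_that("departure pdf normalises, is symmetric in hazard, peaks at T0", {
  pdf <- departure_pdf(list(T0 = 9, a_early = 0.045, a_late = 0.046,
                            h0 = 0.05))
  expect_equal(sum(pdf$pdf), 1, tolerance = 1e-9)
  expect_true(all(pdf$hazard <= 1))

  # equal rates: the hazard's log-deviation from baseline is symmetric in
  # t - T0 (the hazard itself is monotone: it grows towards T0 from below
  # and keeps growing past it)
  sym <- departure_pdf(list(T0 = 10, a_early = 0.3, a_late = 0.3, h0 = 0.1),
                       grid = 1:19)
  expect_equal(abs(log(sym$hazard[10 - 1:5] / 0.1)),
               abs(log(sym$hazard[10 + 1:5] / 0.1)))

  # with baseline h0 = 1 - exp(-a_early) the pdf turns over exactly at T0
  tuned <- departure_pdf(list(T0 = 12, a_early = 0.045, a_late = 0.046,
                              h0 = 1 - exp(-0.045)))
  expect_lte(abs(tuned$t[which.max(tuned$pdf)] - 12), 1)

  expect_warning(departure_pdf(list(T0 = 2, a_early = 1, a_late = 1,
                                    h0 = 0.9), grid = 5:20), "clipping")
})

test_that("degenerate departure samples are rejected", {
  expect_error(fit_departure_model(rep(8, 200)), "degenerate")
  expect_error(fit_departure_model(c(7, 8, 9)), "at least")
})

test_that("fit is invariant to affine rescaling with matching step", {
  set.seed(71)
  x <- sample_departure_time(3000, T0 = 9, a_early = 0.7, a_late = 0.5,
                             h0 = 0.15)
  f1 <- fit_departure_model(x, step = 1)
  f2 <- fit_departure_model(x * 2.5, step = 2.5)
  expect_equal(unname(f1$rates_per_slot), unname(f2$rates_per_slot),
               tolerance = 1e-3)
  expect_equal(f2$T0 / 2.5, f1$T0, tolerance = 1e-3)
  expect_equal(f1$ks, f2$ks, tolerance = 1e-6)
})

test_that("likelihood is maximal near the truth on a large sample", {
  set.seed(72)
  x <- sample_departure_time(2e4, T0 = 9, a_early = 0.7, a_late = 0.5,
                             h0 = 0.15)
  grid <- seq_len(max(x) + 10)
  nll <- function(T0, ae, al, h0) {
    p <- departure_pdf(list(T0 = T0, a_early = ae, a_late = al, h0 = h0),
                       grid)$pdf
    -sum(log(pmax(p[match(x, grid)], 1e-300)))
  }
  base <- nll(9, 0.7, 0.5, 0.15)
  expect_lt(base, nll(9, 0.35, 0.5, 0.15))   # -50% on a_early
  expect_lt(base, nll(9, 1.05, 0.5, 0.15))   # +50%
  expect_lt(base, nll(9, 0.7, 0.25, 0.15))
  expect_lt(base, nll(9, 0.7, 0.75, 0.15))
})

test_that("pooled z-lengths expose the qualification filter", {
  tabs <- list(a = day_lengths(nine_to_five(25, 5), "W"),
               b = day_lengths(nine_to_five(10, 5), "W"))
  pooled <- pool_day_lengths(tabs, min_workdays = 20)
  expect_identical(unique(pooled$user_id), "a")
  expect_equal(nrow(pooled), 25)
})
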