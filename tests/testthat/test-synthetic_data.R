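test_that("location alphabet follows the rank power law", {
  expect_equal(sample_location_alphabet(1, 1.7)$freq, 1.0)
  expect_error(sample_location_alphabet(3, 1), "alpha")
  expect_error(sample_location_alphabet(0, 1.7), "positive")
  ab <- sample_location_alphabet(100, 1.7)
  expect_equal(sum(ab$freq), 1)
  expect_true(all(diff(ab$freq) < 0))
  # freq(r) proportional to r^-alpha: ratios match exactly
  expect_equal(ab$freq[10] / ab$freq[1], 10^(-1.7))
  expect_equal(ab$freq[50] / ab$freq[5], 10^(-1.7))
})

test_that("power-law MLE recovers the alphabet exponent from visit draws", {
  set.seed(101)
  ab <- sample_location_alphabet(1000, 1.7)
  draws <- sample.int(1000, 1e5, replace = TRUE, prob = ab$freq)
  fit <- fit_power_law(tabulate(draws, nbins = 1000))
  expect_gt(1.7, fit$ci[1])
  expect_lt(1.7, fit$ci[2])
})

test_that("generate_day noise matches its binomial oracle", {
  ab <- sample_location_alphabet(50, 1.7)
  tpl <- rep(c("L1", "L2"), each = 12)
  expect_identical(generate_day(tpl, 0, ab), tpl)
  expect_error(generate_day(c("L1", LP_MISSING), 0.1, ab), "MISSING")

  # eps = 1: mismatch fraction = 1 - P(noise draw hits the template slot)
  set.seed(7)
  q <- (1:50) / sum(1:50)                      # rank-biased noise law
  tpl_big <- rep(c("L1", "L2"), each = 5000)
  out <- generate_day(tpl_big, 1, ab)
  p_hit <- mean(q[c(1, 2)])                    # template is L1 half, L2 half
  expected <- 1 - p_hit
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(out != tpl_big) - expected), 3 * se)

  # eps = 0.1, 24 slots, many replicates: mean mismatch count ~ binomial mean
  set.seed(8)
  tpl24 <- rep("L1", 24)
  mism <- replicate(5000, sum(generate_day(tpl24, 0.1, ab) != tpl24))
  mu <- 24 * 0.1 * (1 - q[1])
  sigma <- sqrt(24 * 0.1 * (1 - 0.1 * q[1])) # per-day sd upper bound
  expect_lt(abs(mean(mism) - mu), 3 * sigma / sqrt(5000))
})

test_that("departure sampler is consistent with the analytic pdf", {
  expect_error(sample_departure_time(5, 9, -1, 0.5), "positive")
  set.seed(12)
  x <- sample_departure_time(2e4, T0 = 9, a_early = 0.045, a_late = 0.046,
                             h0 = 0.05)
  pdf <- departure_pdf(list(T0 = 9, a_early = 0.045, a_late = 0.046,
                            h0 = 0.05))
  emp <- tabulate(x, nbins = nrow(pdf)) / length(x)
  ks <- max(abs(cumsum(emp) - cumsum(pdf$pdf)))
  expect_lt(ks, 1.63 / sqrt(2e4))              # alpha = 0.01 critical value

  # equal rates: MC skewness matches the analytic pdf's skewness
  set.seed(13)
  y <- sample_departure_time(2e4, T0 = 12, a_early = 0.3, a_late = 0.3,
                             h0 = 0.1)
  pdf2 <- departure_pdf(list(T0 = 12, a_early = 0.3, a_late = 0.3, h0 = 0.1))
  mu <- sum(pdf2$t * pdf2$pdf)
  s2 <- sum((pdf2$t - mu)^2 * pdf2$pdf)
  skew_true <- sum((pdf2$t - mu)^3 * pdf2$pdf) / s2^1.5
  skew_mc <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(skew_mc - skew_true), 3 * sqrt(6 / 2e4))

  # large a_early: leaving earlier than T0 becomes impossible
  set.seed(14)
  z <- sample_departure_time(2000, T0 = 8, a_early = 50, a_late = 0.5,
                             h0 = 0.5)
  expect_true(all(z >= 8))
})

test_that("generate_panel is deterministic and honours its ground truth", {
  cfg <- generator_config(n_users = 2, n_days = 10, seed = 5)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$events, p2$events)
  for (tu in p1$truth) {
    expect_length(tu$assignment, 10)
    expect_true(all(tu$assignment %in% seq_along(tu$templates)))
  }
})

test_that("noiseless gap-free panels round-trip through ingestion", {
  cfg <- generator_config(n_users = 1, n_days = 32, noise_rate = 0,
                          gap_spec = list(night_prob = 0, random_gap_rate = 0),
                          departure_params = NULL, seed = 9)
  p <- generate_panel(cfg)
  ing <- ingest_traces(p$events, min_days = 30)
  m <- ing$panel[[1]]
  clean <- p$truth[[1]]$clean_days
  expect_equal(unclass(m)[, ], unclass(clean)[, ], ignore_attr = TRUE)
  # and the planted templates are exactly the distinct rows
  expect_identical(
    sort(unique(apply(unclass(m), 1, paste, collapse = ","))),
    sort(unique(vapply(p$truth[[1]]$templates, paste, "", collapse = ","))))
})

test_that("noise slots carry stochastically rarer locations", {
  pl <- planted_user(n_days = 80, noise_rate = 0.15, seed = 31)
  m <- unclass(pl$mat)
  clean <- unclass(pl$truth$clean_days)
  rank_of <- match(m, pl$truth$alphabet$location_id)
  noise <- m != clean
  w <- wilcox.test(rank_of[noise], rank_of[!noise],
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 1e-6)
})

test_that("trace and ground-truth serialisation round-trips", {
  cfg <- generator_config(n_users = 1, n_days = 5, seed = 2)
  p <- generate_panel(cfg)
  tf <- tempfile(fileext = ".csv")
  write_traces(p$events, tf)
  back <- read_traces(tf)
  expect_equal(nrow(back), nrow(p$events))
  expect_identical(back$location_id, p$events$location_id)
  gj <- tempfile(fileext = ".json")
  write_ground_truth(p$truth, gj)
  parsed <- jsonlite::read_json(gj, simplifyVector = TRUE)
  expect_identical(parsed[[1]]$assignment, p$truth[[1]]$assignment)
})
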