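test_that("weighted Hamming distance follows the formula", {
  d1 <- rep("A", 24); d2 <- rep("B", 24)
  expect_equal(day_distance(d1, d1), 0)
  expect_equal(day_distance(d1, d2), 24)
  d3 <- d1; d3[5] <- "B"
  expect_equal(day_distance(d1, d3), 1)
  u <- rep(1, 24); u[5] <- 0.5
  expect_equal(day_distance(d1, d3, u), 0.5)
  expect_error(day_distance(d1, d2[1:10]), "length")
  # MISSING slots excluded, renormalised to the full-day scale
  d4 <- d1; d4[1:12] <- LP_MISSING; d4[13] <- "B"
  expect_equal(day_distance(d1, d4), (1 / 12) * 24)
})

test_that("day graph weights decay as exp(-D/delta)", {
  m <- toy_days(c(strrep("A", 24), strrep("A", 24), strrep("B", 24)))
  g <- build_day_graph(m, delta = 24)
  expect_equal(g$weights[1, 2], 1)              # D = 0
  expect_equal(g$weights[1, 3], exp(-1))        # D = delta
  expect_equal(diag(g$weights), rep(0, 3))
  expect_error(build_day_graph(m, delta = 0), "delta")
  # monotone: larger D, smaller w
  m2 <- toy_days(c(strrep("A", 24), paste0(strrep("B", 6), strrep("A", 18)),
                   strrep("B", 24)))
  g2 <- build_day_graph(m2)
  expect_gt(g2$weights[1, 2], g2$weights[1, 3])
})

test_that("EO finds planted structure and leaves uniform graphs whole", {
  # uniform complete graph: any split has non-positive modularity
  W <- matrix(1, 8, 8); diag(W) <- 0
  eo <- eo_modularity(W, seed = 1)
  expect_equal(eo$k, 1L)
  expect_equal(eo$modularity, modularity_value(W, rep(1L, 8)))

  # two 5-cliques with one weak bridge: matches the exhaustive optimum
  W2 <- matrix(0, 10, 10)
  W2[1:5, 1:5] <- 1; W2[6:10, 6:10] <- 1; diag(W2) <- 0
  W2[5, 6] <- W2[6, 5] <- 0.1
  bf <- brute_max_modularity(W2)
  eo2 <- eo_modularity(W2, seed = 2)
  expect_equal(eo2$modularity, bf$q, tolerance = 1e-12)
  expect_equal(label_agreement(eo2$labels, rep(1:2, each = 5)), 1)

  # single vertex
  expect_equal(eo_modularity(matrix(0, 1, 1))$k, 1L)
})

test_that("EO modularity never loses to the one-cluster partition", {
  for (s in 1:3) {
    pl <- planted_user(n_days = 30, noise_rate = 0.1, seed = 40 + s)
    g <- build_day_graph(pl$mat)
    eo <- eo_modularity(g, seed = s)
    expect_gte(eo$modularity, modularity_value(g, rep(1L, g$n)) - 1e-12)
  }
})

test_that("k-means separates exact groups and honours best-of-n selection", {
  m <- toy_days(c(rep(strrep("A", 24), 5), rep(strrep("B", 24), 4)))
  km <- kmeans_days(m, 2, n_runs = 10, seed = 1)
  expect_equal(km$objective, 0)
  expect_equal(label_agreement(km$labels, rep(1:2, c(5, 4))), 1)

  pl <- planted_user(n_days = 40, noise_rate = 0.2, seed = 50)
  km1 <- kmeans_days(pl$mat, 1, n_runs = 5, seed = 2)
  X <- onehot_days(pl$mat)
  expect_equal(km1$objective, sum(scale(X, scale = FALSE)^2))
  km3 <- kmeans_days(pl$mat, 3, n_runs = 25, seed = 3)
  expect_true(all(km3$objectives >= km3$objective - 1e-9))
  expect_error(kmeans_days(pl$mat, 41), "k")
})

test_that("noiseless planted panels are recovered exactly by both methods", {
  pl <- planted_user(n_days = 36, noise_rate = 0, seed = 60)
  truth <- pl$truth$assignment
  g <- build_day_graph(pl$mat)
  eo <- eo_modularity(g, seed = 4)
  km <- kmeans_days(pl$mat, 3, n_runs = 20, seed = 5)
  expect_equal(label_agreement(eo$labels, truth), 1)
  expect_equal(label_agreement(km$labels, truth), 1)
})

test_that("clustering results are invariant under day reordering", {
  pl <- planted_user(n_days = 30, noise_rate = 0.1, seed = 70)
  set.seed(9)
  perm <- sample(30)
  mperm <- day_matrix(unclass(pl$mat)[perm, ], "perm", slot_minutes = 60L)
  eo_a <- eo_modularity(build_day_graph(pl$mat), seed = 11)
  eo_b <- eo_modularity(build_day_graph(mperm), seed = 11)
  expect_equal(eo_a$modularity, eo_b$modularity, tolerance = 1e-9)
  km_a <- kmeans_days(pl$mat, 3, n_runs = 25, seed = 12)
  km_b <- kmeans_days(mperm, 3, n_runs = 25, seed = 12)
  expect_equal(km_a$objective, km_b$objective, tolerance = 1e-9)
  expect_equal(label_agreement(km_a$labels[perm], km_b$labels), 1)
})

test_that("cluster profiles flag deviations and rare-location enrichment", {
  rows <- c(rep(strrep("A", 24), 4))
  m <- toy_days(rows)
  asg <- structure(list(labels = rep(1L, 4), k = 1L, sizes = 4L,
                        method = "manual"), class = "cluster_assignment")
  pr <- cluster_profile(asg, m)
  expect_identical(pr$average_days[1, ], rep("A", 24))
  expect_false(any(pr$deviation_mask))

  m2 <- unclass(m); m2[2, 7] <- "B"
  m2 <- day_matrix(m2, "t", slot_minutes = 60L)
  pr2 <- cluster_profile(asg, m2)
  expect_identical(which(pr2$deviation_mask), which(unclass(m2) == "B"))

  pl <- planted_user(n_days = 100, noise_rate = 0.15, seed = 80)
  g <- build_day_graph(pl$mat)
  eo <- eo_modularity(g, seed = 6)
  pr3 <- cluster_profile(eo, pl$mat)
  expect_gt(pr3$rank_enrichment, 0)
})
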