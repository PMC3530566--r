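#' Weighted Hamming distance between two day vectors
#'
#' `D = sum_j u_j * [d1_j != d2_j]` over slots observed in both days; when
#' some slots are MISSING in either day the sum is renormalised by the
#' compared weight so that distances remain on the full-day scale. With unit
#' weights and complete days this is the plain Hamming distance.
#'
#' @param d1,d2 character slot vectors of equal length.
#' @param slot_weights optional positive weights `u_j` (default 1).
#' @return non-negative distance; `NA` if no slot is observed in both days.
#' @export
day_distance <- function(d1, d2, slot_weights = NULL) {
  .assert(length(d1) == length(d2), "day vectors must have equal length")
  u <- slot_weights %||% rep(1, length(d1))
  .assert(length(u) == length(d1) && all(u >= 0), "bad slot weights")
  ok <- d1 != LP_MISSING & d2 != LP_MISSING
  if (!any(ok)) return(NA_real_)
  sum(u[ok] * (d1[ok] != d2[ok])) * sum(u) / sum(u[ok])
}

#' Build the weighted day-similarity graph
#'
#' Complete graph on a user's days with edge weight
#' `w(d1, d2) = exp(-D(d1, d2) / delta)` where `D` is [day_distance()];
#' identical days get weight 1 and weights decay smoothly with distance.
#'
#' The scale `delta` decides when two days still count as the same routine:
#' days sharing a pattern with per-slot noise rate eps differ in about
#' `2 * eps * n_slots` slots (~2-3 at eps = 0.05 on 24 slots), while days of
#' different patterns differ by multi-hour blocks (>= 6 slots). The default
#' `n_slots / 12` (2 slots at 1-h resolution) sits between the two, keeping
#' same-pattern days strongly connected while inter-pattern weights are
#' near zero; much larger scales make the graph so uniformly dense that the
#' modularity resolution limit merges small minority patterns.
#'
#' @param mat a day matrix with at least two days.
#' @param delta distance scale (> 0); default `n_slots / 12`.
#' @param slot_weights optional per-slot weights for `D`.
#' @return object of class `day_graph`: list with `weights` (symmetric
#'   matrix, zero diagonal), `delta`, `n`.
#' @export
build_day_graph <- function(mat, delta = NULL, slot_weights = NULL) {
  m <- .as_mat(mat)
  .assert(nrow(m) >= 2, "need at least two days")
  delta <- delta %||% (ncol(m) / 12)
  .assert(delta > 0, "delta must be positive")
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- day_distance(m[i, ], m[j, ], slot_weights)
  if (anyNA(D)) stop("days with no co-observed slots: cannot build graph")
  W <- exp(-D / delta)
  diag(W) <- 0
  structure(list(weights = W, delta = delta, n = n,
                 dates = rownames(m)), class = "day_graph")
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) [c_i == c_j]` with strengths
#' `k_i` and total weight `2m` (self-loops excluded).
#'
#' @param W symmetric weight matrix (zero diagonal) or a `day_graph`.
#' @param labels integer community label per vertex.
#' @return modularity value.
#' @export
modularity_value <- function(W, labels) {
  if (inherits(W, "day_graph")) W <- W$weights
  k <- rowSums(W)
  two_m <- sum(k)
  if (two_m == 0) return(0)
  q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    q <- q + sum(W[idx, idx, drop = FALSE]) / two_m -
      (sum(k[idx]) / two_m)^2
  }
  q
}

# One tau-EO bisection attempt of community `members` of the full graph,
# optimising GLOBAL modularity (full-graph strengths k and total weight 2m;
# only within-community adjacency matters for the split's Q contribution).
# Fitness of vertex i in part p: lambda_i = kappa_i(p)/k_i - a_p, so that
# sum_i k_i lambda_i = 2m * Q restricted to this community.
.eo_bisect <- function(W, k, two_m, members, tau, sweeps) {
  n <- length(members)
  if (n < 2) return(NULL)
  Wm <- W[members, members, drop = FALSE]
  km <- k[members]
  side <- sample(rep(c(TRUE, FALSE), length.out = n))  # TRUE = part 1
  kappa1 <- as.vector(Wm %*% side)          # strength towards part 1
  row_tot <- rowSums(Wm)
  K1 <- sum(km[side]); K_all <- sum(km)
  part_q <- function() {
    sum_in <- sum(kappa1[side]) + sum((row_tot - kappa1)[!side])
    sum_in / two_m - (K1 / two_m)^2 - ((K_all - K1) / two_m)^2
  }
  best_side <- NULL
  best_q <- -Inf
  rank_prob <- (1:n)^(-tau)
  steps <- max(30L, sweeps * n)
  stale <- 0L
  for (it in seq_len(steps)) {
    kappa_own <- ifelse(side, kappa1, row_tot - kappa1)
    a_own <- ifelse(side, K1, K_all - K1) / two_m
    lambda <- ifelse(km > 0, kappa_own / km, 0) - a_own
    o <- order(lambda)                       # worst fitness first
    pick <- o[sample.int(n, 1L, prob = rank_prob)]
    if (side[pick]) {                        # leaves part 1
      side[pick] <- FALSE
      kappa1 <- kappa1 - Wm[, pick]
      K1 <- K1 - km[pick]
    } else {
      side[pick] <- TRUE
      kappa1 <- kappa1 + Wm[, pick]
      K1 <- K1 + km[pick]
    }
    q <- part_q()
    if (any(side) && !all(side) && q > best_q + 1e-12) {
      best_q <- q
      best_side <- side
      stale <- 0L
    } else stale <- stale + 1L
    if (stale > steps %/% 3L) break
  }
  if (is.null(best_side)) return(NULL)
  list(q = best_q, side = best_side)
}

#' Extremal-optimization modularity clustering of days
#'
#' Duch-Arenas tau-EO: recursive bisection of the weighted day graph, where
#' each bisection repeatedly ranks vertices by fitness (within-community
#' strength fraction minus expected) and flips a vertex chosen with
#' probability proportional to rank^-tau. A split is kept only if it
#' increases global modularity, so the number of clusters is an emergent
#' outcome, not an input. A single-vertex-move polish pass runs at the end.
#'
#' @param graph a [build_day_graph()] result (or a symmetric weight matrix).
#' @param tau rank-selection exponent (default 1.4).
#' @param sweeps EO move budget per bisection, in units of community size.
#' @param restarts independent restarts; the best-modularity run is kept.
#' @param seed optional RNG seed for a fixed-seed determinism contract.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (integers 1..k), `k`, `sizes`, `modularity`, `method = "eo"`.
#' @export
eo_modularity <- function(graph, tau = 1.4, sweeps = 40L, restarts = 3L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- if (inherits(graph, "day_graph")) graph$weights else graph
  n <- nrow(W)
  if (n == 1L)
    return(.assignment(1L, "eo", modularity = 0))
  k <- rowSums(W)
  two_m <- sum(k)
  best_labels <- rep(1L, n)
  best_q <- modularity_value(W, best_labels)
  for (r in seq_len(restarts)) {
    labels <- rep(1L, n)
    queue <- list(seq_len(n))
    next_label <- 2L
    while (length(queue)) {
      members <- queue[[1]]
      queue <- queue[-1]
      base_q <- modularity_value(W, labels)
      bs <- .eo_bisect(W, k, two_m, members, tau, sweeps)
      if (is.null(bs)) next
      cand <- labels
      cand[members[bs$side]] <- next_label
      if (modularity_value(W, cand) > base_q + 1e-12) {
        labels <- cand
        queue <- c(queue, list(members[bs$side], members[!bs$side]))
        next_label <- next_label + 1L
      }
    }
    labels <- .polish_moves(W, labels)
    q <- modularity_value(W, labels)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_labels <- labels
    }
  }
  .assignment(match(best_labels, unique(best_labels)), "eo",
              modularity = best_q)
}

# Greedy single-vertex moves between existing communities (plus the empty
# community) until no move improves modularity.
.polish_moves <- function(W, labels) {
  n <- nrow(W)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      cur <- labels[i]
      cands <- setdiff(unique(labels), cur)
      if (sum(labels == cur) > 1L) cands <- c(cands, max(labels) + 1L)
      best_q <- modularity_value(W, labels)
      for (cc in cands) {
        trial <- labels
        trial[i] <- cc
        q <- modularity_value(W, trial)
        if (q > best_q + 1e-12) {
          labels <- trial
          best_q <- q
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  labels
}

.assignment <- function(labels, method, modularity = NULL, objective = NULL,
                        objectives = NULL) {
  structure(list(labels = as.integer(labels), k = length(unique(labels)),
                 sizes = as.integer(table(labels)), method = method,
                 modularity = modularity, objective = objective,
                 objectives = objectives),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> method=%s k=%d sizes=[%s]%s\n",
              x$method, x$k, paste(x$sizes, collapse = ","),
              if (!is.null(x$modularity))
                sprintf(" Q=%.4f", x$modularity)
              else sprintf(" WSS=%.4f", x$objective)))
  invisible(x)
}

#' One-hot ("binary expansion") encoding of a day matrix
#'
#' Each slot becomes `|alphabet|` binary columns; MISSING slots encode as an
#' all-zero block.
#'
#' @param mat a day matrix.
#' @param alphabet optional fixed symbol order.
#' @return numeric matrix, days x (n_slots * |alphabet|).
#' @export
onehot_days <- function(mat, alphabet = NULL) {
  m <- .as_mat(mat)
  syms <- alphabet %||% sort(unique(m[m != LP_MISSING]))
  n <- nrow(m); s <- ncol(m); L <- length(syms)
  X <- matrix(0, n, s * L)
  idx <- match(m, syms)                     # column-major over slots
  for (j in seq_len(s)) {
    hit <- which(!is.na(idx[(j - 1) * n + seq_len(n)]))
    X[cbind(hit, (j - 1) * L + idx[(j - 1) * n + hit])] <- 1
  }
  X
}

#' Best-of-n-runs k-means clustering of day vectors
#'
#' Days are one-hot encoded and clustered by Euclidean k-means; `n_runs`
#' random initialisations are run and the partition with the smallest
#' within-cluster sum of squares is returned. When the number of distinct
#' day vectors does not exceed `k` the exact zero-loss partition (one
#' cluster per distinct vector) is returned directly.
#'
#' @param mat a day matrix.
#' @param k number of clusters (1 <= k <= number of days).
#' @param n_runs number of random restarts (default 200).
#' @param seed optional RNG seed.
#' @return a `cluster_assignment` with `objective` (best WSS) and
#'   `objectives` (per-run WSS vector).
#' @export
kmeans_days <- function(mat, k, n_runs = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- .as_mat(mat)
  .assert(k >= 1 && k <= nrow(m), "need 1 <= k <= number of days")
  X <- onehot_days(mat)
  du <- unique(X)
  if (nrow(du) <= k) {
    labels <- apply(X, 1, function(r)
      which(apply(du, 1, function(c) all(c == r)))[1])
    return(.assignment(labels, "kmeans", objective = 0,
                       objectives = rep(0, n_runs)))
  }
  if (k == 1L) {
    wss <- sum(scale(X, scale = FALSE)^2)
    return(.assignment(rep(1L, nrow(X)), "kmeans", objective = wss,
                       objectives = rep(wss, n_runs)))
  }
  best <- NULL
  objectives <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    km <- tryCatch(stats::kmeans(X, centers = k, iter.max = 100L, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km)) {
      objectives[r] <- Inf
      next
    }
    objectives[r] <- km$tot.withinss
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  .assert(!is.null(best), "k-means failed in every run")
  .assignment(best$cluster, "kmeans", objective = best$tot.withinss,
              objectives = objectives)
}

#' Cluster profiles: average days, deviation masks, rarity enrichment
#'
#' The average day of a cluster is the per-slot modal location among its
#' days (ties broken by first occurrence). The deviation mask flags slots
#' where a day differs from its cluster's average day (MISSING slots are
#' never flagged). Enrichment is the difference in mean location rank
#' between deviation slots and agreement slots: positive values mean the
#' noise is made of rarer locations than the patterns.
#'
#' @param assignment a `cluster_assignment` over the days of `mat`.
#' @param mat the day matrix.
#' @param alphabet optional [location_frequencies()] table supplying ranks.
#' @return list with `average_days` (k x n_slots character matrix),
#'   `deviation_mask` (logical matrix, days x slots), `rank_enrichment`.
#' @export
cluster_profile <- function(assignment, mat, alphabet = NULL) {
  m <- .as_mat(mat)
  labels <- assignment$labels
  .assert(length(labels) == nrow(m), "assignment/day mismatch")
  ks <- sort(unique(labels))
  avg <- matrix(NA_character_, length(ks), ncol(m))
  for (ci in seq_along(ks)) {
    rows <- m[labels == ks[ci], , drop = FALSE]
    .assert(nrow(rows) > 0, "empty cluster")
    avg[ci, ] <- apply(rows, 2, modal_label)
  }
  expanded <- avg[match(labels, ks), , drop = FALSE]
  mask <- m != expanded & m != LP_MISSING
  if (is.null(alphabet)) alphabet <- location_frequencies(mat)
  ranks <- alphabet$rank[match(m, alphabet$location_id)]
  obs <- m != LP_MISSING & !is.na(ranks)
  dev_ranks <- ranks[mask & obs]
  agree_ranks <- ranks[!mask & obs]
  enrich <- if (length(dev_ranks) && length(agree_ranks))
    mean(dev_ranks) - mean(agree_ranks) else NA_real_
  list(average_days = avg, deviation_mask = mask, rank_enrichment = enrich)
}

#' Agreement of two partitions up to label permutation
#'
#' Fraction of items whose labels match under the best one-to-one relabelling
#' (exact Hungarian-style search over permutations for small k, greedy
#' otherwise). Used for planted-template recovery checks.
#'
#' @param a,b integer label vectors of equal length.
#' @return agreement fraction in `[0,1]`.
#' @export
label_agreement <- function(a, b) {
  .assert(length(a) == length(b), "length mismatch")
  la <- unique(a); lb <- unique(b)
  if (length(la) <= 8 && length(lb) <= 8) {
    ka <- length(la); kb <- length(lb)
    # pad the smaller side so permutations are over the larger
    if (ka <= kb) {
      perms <- .permutations(kb)
      best <- 0
      for (p in seq_len(nrow(perms))) {
        mapping <- lb[perms[p, ]]
        hit <- mean(mapping[match(a, la)] == b, na.rm = TRUE)
        best <- max(best, hit)
      }
      return(best)
    } else return(label_agreement(b, a))
  }
  tab <- table(a, b)   # greedy fallback
  total <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  total / length(a)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
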