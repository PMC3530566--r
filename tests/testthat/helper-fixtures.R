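# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-writable day matrix: `rows` is a character vector of
# slot-strings like "AABB" (one letter per slot); "." means MISSING.
toy_days <- function(rows, user_id = "toy") {
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(s) {
    s[s == "."] <- LP_MISSING
    s
  }))
  day_matrix(m, user_id,
             dates = format(as.Date("2009-01-05") + seq_along(rows) - 1),
             slot_minutes = as.integer(24 * 60 / nchar(rows[1])))
}

# Independent per-slot histogram entropy oracle (brute force, base 2).
oracle_bare_entropy <- function(mat) {
  m <- unclass(mat)
  hs <- c()
  for (j in seq_len(ncol(m))) {
    col <- m[, j][m[, j] != LP_MISSING]
    if (!length(col)) next
    p <- as.numeric(table(col)) / length(col)
    hs <- c(hs, -sum(p * log2(p)))
  }
  if (!length(hs)) 0 else mean(hs)
}

# Enumerate all set partitions of n items as label vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (v in 1:(mx + 1)) {
      a[i] <<- v
      rec(i + 1, max(mx, v))
    }
  }
  rec(1, 0)
  out
}

# Exhaustive maximum-modularity oracle over all partitions.
brute_max_modularity <- function(W) {
  best <- -Inf
  bl <- NULL
  for (p in all_partitions(nrow(W))) {
    q <- modularity_value(W, p)
    if (q > best + 1e-12) {
      best <- q
      bl <- p
    }
  }
  list(q = best, labels = bl)
}

# Planted-template panel used across tests: K templates, no gaps, optional
# departure jitter, returning the user's noisy day matrix plus truth.
planted_user <- function(n_days = 120, K = 3, noise_rate = 0.05, seed = 11,
                         departure_params = NULL, n_locations = 50) {
  cfg <- generator_config(n_users = 1, n_days = n_days, templates_per_user = K,
                          noise_rate = noise_rate, n_locations = n_locations,
                          gap_spec = list(night_prob = 0, random_gap_rate = 0),
                          departure_params = departure_params, seed = seed)
  p <- generate_panel(cfg)
  list(mat = p$truth[[1]]$noisy_days, truth = p$truth[[1]], cfg = cfg,
       events = p$events)
}

# i.i.d. panel: every slot of every day drawn independently from `probs`
# over locations A, B, C, ... — no temporal structure at all.
iid_days <- function(n_days, n_slots, probs, seed = 1) {
  set.seed(seed)
  syms <- LETTERS[seq_along(probs)]
  m <- matrix(sample(syms, n_days * n_slots, replace = TRUE, prob = probs),
              n_days, n_slots)
  day_matrix(m, "iid", slot_minutes = as.integer(24 * 60 / n_slots))
}
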