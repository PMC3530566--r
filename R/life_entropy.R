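#' Bare life entropy of a day matrix
#'
#' Per-slot Shannon entropy of the slot-location distribution, averaged over
#' slots: `S = (1/n_slots) * sum_j H_j` with
#' `H_j = -sum_i (n_ij / N_j) log2(n_ij / N_j)`, where `n_ij` counts the days
#' in which location i dominates slot j and `N_j` is the number of days with
#' an observed (non-MISSING) slot j. Slots with no observations are skipped
#' with a warning and the average is taken over the remaining slots.
#'
#' @param mat a day matrix (accepted, usually thresholded days).
#' @param base logarithm base (default 2: bits).
#' @return bare entropy in bits.
#' @export
bare_entropy <- function(mat, base = 2) {
  m <- .as_mat(mat)
  hj <- apply(m, 2, function(col) {
    col <- col[col != LP_MISSING]
    if (!length(col)) return(NA_real_)
    shannon(table(col), base = base)
  })
  if (anyNA(hj)) {
    warning(sum(is.na(hj)), " slot(s) with no observations skipped")
    hj <- hj[!is.na(hj)]
  }
  if (!length(hj)) return(0)
  mean(hj)
}

#' Clustered life entropy under a day partition
#'
#' Size-weighted average of the within-cluster bare entropies:
#' `S_clustered = sum_c (n_c / N) * S_c`, where `S_c` is [bare_entropy()]
#' computed on the days of cluster c alone. Perfectly pattern-split days
#' give zero; the identity partition gives the bare entropy back.
#'
#' @param mat a day matrix.
#' @param assignment a `cluster_assignment` or an integer label vector over
#'   the same days.
#' @param base logarithm base.
#' @return clustered entropy in bits.
#' @export
clustered_entropy <- function(mat, assignment, base = 2) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  m <- .as_mat(mat)
  .assert(length(labels) == nrow(m), "assignment/day mismatch")
  N <- nrow(m)
  s <- 0
  for (c in unique(labels)) {
    rows <- m[labels == c, , drop = FALSE]
    s <- s + (nrow(rows) / N) *
      suppressWarnings(bare_entropy(rows, base = base))
  }
  s
}

#' Entropy drop due to clustering
#'
#' `delta_S = S_bare - S_clustered`; the relative drop is
#' `100 * delta_S / S_bare` percent (defined as 0 when `S_bare = 0`).
#' On complete data the drop is non-negative for any partition; a negative
#' value beyond numerical tolerance triggers a warning (it can only arise
#' from missing-data renormalisation).
#'
#' @param S_bare,S_clustered entropies computed on the same days.
#' @return list with `delta` (bits) and `relative_pct`.
#' @export
entropy_drop <- function(S_bare, S_clustered) {
  delta <- S_bare - S_clustered
  if (delta < -1e-9)
    warning("negative entropy drop: check for missing-data artefacts")
  list(delta = delta,
       relative_pct = if (S_bare > 0) 100 * delta / S_bare else 0)
}

#' Null-model (reference) entropy
#'
#' Maximum entropy compatible with a concentrated modal probability `p0` on
#' the pattern location and the residual mass spread uniformly over the
#' remaining `n_locations - 1` locations:
#' `S_null = -p0 log2 p0 - (1 - p0) log2((1 - p0) / (n - 1))`.
#'
#' @param p0 modal probability, in `[1/n_locations, 1]`.
#' @param n_locations number of (significant) locations (>= 1).
#' @return null entropy in bits (0 when `n_locations = 1` or `p0 = 1`).
#' @export
null_entropy <- function(p0, n_locations) {
  .assert(n_locations >= 1, "n_locations must be >= 1")
  if (n_locations == 1) {
    .assert(abs(p0 - 1) < 1e-12, "p0 must be 1 when only one location")
    return(0)
  }
  .assert(p0 >= 1 / n_locations - 1e-12 && p0 <= 1,
          "p0 must be a modal mass in [1/n, 1]")
  if (p0 >= 1) return(0)
  -p0 * log2(p0) - (1 - p0) * log2((1 - p0) / (n_locations - 1))
}

#' Mean per-slot modal probability
#'
#' `p0` for the null model: the empirical probability of the most common
#' location per slot, averaged over slots (slots without data skipped).
#'
#' @param mat a day matrix.
#' @return scalar in `(0, 1]`.
#' @export
modal_probability <- function(mat) {
  m <- .as_mat(mat)
  pj <- apply(m, 2, function(col) {
    col <- col[col != LP_MISSING]
    if (!length(col)) return(NA_real_)
    max(table(col)) / length(col)
  })
  mean(pj, na.rm = TRUE)
}

#' Per-user entropy report
#'
#' Convenience wrapper computing the full entropy account for one user under
#' one (or more) clusterings.
#'
#' @param mat thresholded day matrix.
#' @param assignments named list of `cluster_assignment`s (e.g.
#'   `list(eo = ..., kmeans = ...)`).
#' @param alphabet optional [location_frequencies()] table (for the
#'   significant-location count).
#' @return data.frame, one row per clustering method, with `user_id`,
#'   `method`, `S_bare`, `S_clustered`, `delta_S`, `relative_pct`, `S_null`,
#'   `n_patterns`, `n_significant_locations`, `p0`.
#' @export
entropy_report <- function(mat, assignments, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- location_frequencies(mat)
  n_sig <- sum(alphabet$significant)
  S_bare <- bare_entropy(mat)
  p0 <- modal_probability(mat)
  S_null <- null_entropy(max(p0, 1 / max(n_sig, 1)), max(n_sig, 1))
  rows <- lapply(names(assignments), function(nm) {
    a <- assignments[[nm]]
    S_cl <- clustered_entropy(mat, a)
    dr <- entropy_drop(S_bare, S_cl)
    data.frame(user_id = attr(mat, "user_id") %||% "user", method = nm,
               S_bare = S_bare, S_clustered = S_cl, delta_S = dr$delta,
               relative_pct = dr$relative_pct, S_null = S_null,
               n_patterns = a$k, n_significant_locations = n_sig, p0 = p0)
  })
  do.call(rbind, rows)
}

#' Panel-level cumulative entropy distributions
#'
#' Empirical CDFs and medians of the bare, clustered and null entropies
#' across users.
#'
#' @param reports data.frame of stacked [entropy_report()] rows (>= 2 users).
#' @param method which clustering method's rows to use (default the first).
#' @return list with `cdf` (named list of ecdf functions) and `medians`.
#' @export
entropy_distributions <- function(reports, method = NULL) {
  method <- method %||% reports$method[1]
  r <- reports[reports$method == method, , drop = FALSE]
  .assert(length(unique(r$user_id)) >= 2, "need at least 2 users")
  list(cdf = list(S_bare = stats::ecdf(r$S_bare),
                  S_clustered = stats::ecdf(r$S_clustered),
                  S_null = stats::ecdf(r$S_null)),
       medians = c(S_bare = stats::median(r$S_bare),
                   S_clustered = stats::median(r$S_clustered),
                   S_null = stats::median(r$S_null)))
}
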