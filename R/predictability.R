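#' Per-slot occupancy probabilities
#'
#' Empirical probability `p_ij` of being at location i in slot j (MISSING
#' slots excluded per slot), optionally split by cluster (`p_icj`).
#'
#' @param mat a (thresholded) day matrix.
#' @param assignment optional `cluster_assignment` (or label vector).
#' @return list with `alphabet`, `p` (|L| x n_slots, columns summing to 1
#'   where defined), and if clustered: `clusters` (list of such matrices)
#'   and `weights` (n_c / N).
#' @export
occupancy_model <- function(mat, assignment = NULL) {
  m <- .as_mat(mat)
  L <- sort(unique(m[m != LP_MISSING]))
  pmat <- function(rows) {
    apply(rows, 2, function(col) {
      col <- col[col != LP_MISSING]
      if (!length(col)) return(rep(NA_real_, length(L)))
      tabulate(match(col, L), nbins = length(L)) / length(col)
    })
  }
  out <- list(alphabet = L, p = pmat(m))
  if (!is.null(assignment)) {
    labels <- if (inherits(assignment, "cluster_assignment"))
      assignment$labels else as.integer(assignment)
    .assert(length(labels) == nrow(m), "assignment/day mismatch")
    cl <- sort(unique(labels))
    out$clusters <- lapply(cl, function(c)
      pmat(m[labels == c, , drop = FALSE]))
    names(out$clusters) <- cl
    out$weights <- as.vector(table(factor(labels, levels = cl))) / nrow(m)
  }
  out
}

.rule_quality <- function(p, rule) {
  # p: probability vector (may be NA if slot unobserved)
  if (anyNA(p)) return(NA_real_)
  if (rule == "matching") sum(p^2) else max(p)
}

#' Static (occupancy-based) prediction quality
#'
#' Guess the slot-j location from the occupancy distribution alone. Under
#' the probability-matching rule the success probability is
#' `Q_j = sum_i p_ij^2`; under the mode rule it is `max_i p_ij`. With
#' patterns, per-cluster qualities are averaged with weights `n_c / N`
#' (renormalised over clusters observed at slot j), which can only improve
#' the matching-rule quality (Jensen).
#'
#' @param mat a day matrix.
#' @param assignment optional clustering (`NULL` = no patterns).
#' @param rule `"matching"` (default) or `"mode"`.
#' @return list with `overall` (day-averaged Q), `per_slot`, `rule`,
#'   `with_patterns`.
#' @export
static_quality <- function(mat, assignment = NULL,
                           rule = c("matching", "mode")) {
  rule <- match.arg(rule)
  om <- occupancy_model(mat, assignment)
  n_slots <- ncol(om$p)
  if (is.null(assignment)) {
    qj <- vapply(seq_len(n_slots),
                 function(j) .rule_quality(om$p[, j], rule), numeric(1))
  } else {
    qj <- vapply(seq_len(n_slots), function(j) {
      qc <- vapply(om$clusters, function(pc) .rule_quality(pc[, j], rule),
                   numeric(1))
      ok <- !is.na(qc)
      if (!any(ok)) return(NA_real_)
      sum(om$weights[ok] * qc[ok]) / sum(om$weights[ok])
    }, numeric(1))
  }
  list(overall = mean(qj, na.rm = TRUE), per_slot = qj, rule = rule,
       with_patterns = !is.null(assignment))
}

# Pair extraction over the concatenated calendar sequence. Returns origin
# index info for all pairs with both members observed.
.pairs_of <- function(m, dt) {
  n_slots <- ncol(m)
  x <- as.vector(t(m))
  n <- length(x)
  i <- seq_len(n - dt)
  ok <- x[i] != LP_MISSING & x[i + dt] != LP_MISSING
  i <- i[ok]
  list(from = x[i], to = x[i + dt],
       slot = ((i - 1L) %% n_slots) + 1L,
       day = ((i - 1L) %/% n_slots) + 1L)
}

#' Fit empirical transition (transfer) matrices
#'
#' Counts pairs `(location a at slot j, location b at slot j + dt)` over the
#' concatenated calendar sequence of a user's days (pairs cross midnight;
#' pairs with a MISSING member are skipped) and row-normalises. By default
#' matrices are slot-dependent (one |L| x |L| matrix per origin slot); with
#' `pooled = TRUE` a single matrix is fitted. With an assignment, counts are
#' additionally split by the origin day's cluster.
#'
#' @param mat a day matrix with days in calendar order.
#' @param dt lag in slots (>= 1).
#' @param assignment optional clustering.
#' @param pooled pool over origin slots (default FALSE).
#' @return object of class `transition_model`: `alphabet`, `dt`, `pooled`,
#'   `counts` / `probs` (arrays: |L| x |L| x n_slots, or |L| x |L|),
#'   optionally `clusters` (per-cluster prob arrays), `weights`,
#'   `day_cluster`, and `n_pairs`.
#' @export
fit_transition_model <- function(mat, dt = 1L, assignment = NULL,
                                 pooled = FALSE) {
  .assert(dt >= 1, "dt must be >= 1")
  m <- .as_mat(mat)
  L <- sort(unique(m[m != LP_MISSING]))
  nL <- length(L)
  n_slots <- ncol(m)
  pr <- .pairs_of(m, dt)
  count_array <- function(sel) {
    if (pooled) {
      cnt <- matrix(0, nL, nL, dimnames = list(L, L))
      if (any(sel)) {
        t3 <- table(factor(pr$from[sel], L), factor(pr$to[sel], L))
        cnt <- cnt + unclass(t3)
      }
      cnt
    } else {
      cnt <- array(0, c(nL, nL, n_slots), dimnames = list(L, L, NULL))
      if (any(sel)) {
        t3 <- table(factor(pr$from[sel], L), factor(pr$to[sel], L),
                    factor(pr$slot[sel], seq_len(n_slots)))
        cnt <- cnt + unclass(t3)
      }
      cnt
    }
  }
  normalise <- function(cnt) {
    if (pooled) {
      rs <- rowSums(cnt)
      sweep(cnt, 1, pmax(rs, 1), "/") * ifelse(rs > 0, 1, NA)
    } else {
      out <- cnt
      for (j in seq_len(dim(cnt)[3])) {
        rs <- rowSums(cnt[, , j])
        out[, , j] <- sweep(cnt[, , j], 1, pmax(rs, 1), "/") *
          ifelse(rs > 0, 1, NA)
      }
      out
    }
  }
  model <- list(alphabet = L, dt = as.integer(dt), pooled = pooled,
                n_pairs = length(pr$from))
  all_cnt <- count_array(rep(TRUE, length(pr$from)))
  model$counts <- all_cnt
  model$probs <- normalise(all_cnt)
  if (!is.null(assignment)) {
    labels <- if (inherits(assignment, "cluster_assignment"))
      assignment$labels else as.integer(assignment)
    .assert(length(labels) == nrow(m), "assignment/day mismatch")
    cl <- sort(unique(labels))
    day_cluster <- labels
    model$clusters <- lapply(cl, function(c)
      normalise(count_array(day_cluster[pr$day] == c)))
    names(model$clusters) <- cl
    model$weights <- as.vector(table(factor(labels, levels = cl))) / nrow(m)
    model$day_cluster <- day_cluster
  }
  class(model) <- "transition_model"
  model
}

.row_of <- function(model, probs, from, slot) {
  i <- match(from, model$alphabet)
  if (is.na(i)) return(NULL)
  row <- if (model$pooled) probs[i, ] else probs[i, , slot]
  if (anyNA(row)) return(NULL)
  row
}

#' Transition-matrix prediction quality
#'
#' Evaluates the transition model on the observed pairs of the same user:
#' for each pair `(a at slot j -> b)`, the mode rule scores 1 when b is the
#' most probable target of a's row, while the matching rule scores the row
#' probability of b (so that in-sample the total equals
#' `sum_a p_a sum_b T(a,b)^2`). Pairs whose row is undefined (unseen origin
#' in the relevant cluster) are skipped and counted.
#'
#' @param model a [fit_transition_model()] result.
#' @param mat the day matrix the model was fitted on.
#' @param rule `"matching"` or `"mode"`.
#' @return list with `overall`, `per_slot`, `n_pairs`, `n_skipped`, `rule`.
#' @export
transition_quality <- function(model, mat, rule = c("matching", "mode")) {
  rule <- match.arg(rule)
  m <- .as_mat(mat)
  pr <- .pairs_of(m, model$dt)
  n_slots <- ncol(m)
  score <- numeric(length(pr$from))
  used <- logical(length(pr$from))
  for (p in seq_along(pr$from)) {
    probs <- if (!is.null(model$clusters))
      model$clusters[[as.character(model$day_cluster[pr$day[p]])]]
    else model$probs
    row <- .row_of(model, probs, pr$from[p], pr$slot[p])
    if (is.null(row)) next
    used[p] <- TRUE
    j <- match(pr$to[p], model$alphabet)
    score[p] <- if (rule == "matching") row[j]
                else as.numeric(j == which.max(row))
  }
  per_slot <- vapply(seq_len(n_slots), function(j) {
    sel <- used & pr$slot == j
    if (!any(sel)) NA_real_ else mean(score[sel])
  }, numeric(1))
  list(overall = if (any(used)) mean(score[used]) else NA_real_,
       per_slot = per_slot, n_pairs = sum(used),
       n_skipped = sum(!used), rule = rule)
}

#' Long-range prediction-quality curve
#'
#' Transition quality as a function of lag `dt = 1..dt_max` slots, with a
#' least-squares logarithmic fit `Q = a - b log(dt)` and a comparison
#' against the static-method day average.
#'
#' @param mat a day matrix.
#' @param dt_max maximum lag in slots (default 12, i.e. 12 h at 1-h slots).
#' @param assignment optional clustering used for both methods.
#' @param rule guess rule for both methods.
#' @param pooled pool transition matrices over slots.
#' @return list with `curve` (data.frame: dt, Q, n_pairs), `fit`
#'   (intercept a, slope b of `Q ~ -log dt`), `static_overall` and
#'   `above_static` (fraction of lags beating the static average).
#' @export
long_range_curve <- function(mat, dt_max = 12L, assignment = NULL,
                             rule = c("matching", "mode"), pooled = FALSE) {
  rule <- match.arg(rule)
  qs <- numeric(dt_max)
  np <- integer(dt_max)
  for (dt in seq_len(dt_max)) {
    tm <- fit_transition_model(mat, dt, assignment, pooled)
    tq <- transition_quality(tm, mat, rule)
    qs[dt] <- tq$overall
    np[dt] <- tq$n_pairs
  }
  curve <- data.frame(dt = seq_len(dt_max), Q = qs, n_pairs = np)
  ok <- !is.na(qs)
  fit <- if (sum(ok) >= 2) {
    co <- stats::coef(stats::lm(Q ~ I(-log(dt)), data = curve[ok, ]))
    c(a = unname(co[1]), b = unname(co[2]))
  } else c(a = NA_real_, b = NA_real_)
  st <- static_quality(mat, assignment, rule)$overall
  list(curve = curve, fit = fit, static_overall = st,
       above_static = mean(qs[ok] > st))
}

#' Correlation of personal entropy with predictability
#'
#' Rank correlation (Spearman by default) of per-user prediction quality
#' against per-user entropy — bare entropy for pattern-free methods,
#' clustered entropy when patterns aid the prediction.
#'
#' @param entropy numeric vector, one value per user.
#' @param quality numeric vector, same length.
#' @param method correlation method (default `"spearman"`).
#' @return list with `rho`, `method`, `defined` (FALSE when a variance is
#'   degenerate, in which case `rho` is NA and a warning is issued).
#' @export
entropy_predictability_correlation <- function(entropy, quality,
                                               method = "spearman") {
  .assert(length(entropy) == length(quality), "length mismatch")
  .assert(length(entropy) >= 3, "need at least 3 users")
  if (stats::sd(entropy) == 0 || stats::sd(quality) == 0) {
    warning("degenerate variance: correlation undefined")
    return(list(rho = NA_real_, method = method, defined = FALSE))
  }
  list(rho = stats::cor(entropy, quality, method = method),
       method = method, defined = TRUE)
}
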