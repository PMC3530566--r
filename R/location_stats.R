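#' Per-user location frequency table
#'
#' Counts the number of slots each location dominates (MISSING slots are
#' excluded) and ranks locations by count. A location is *significant* when
#' its count is at least 1% of the most common location's count; rarer ones
#' are candidates for lumping into [LP_OTHER].
#'
#' @param mat a day matrix of accepted days.
#' @param significance_fraction the lumping threshold (default 0.01).
#' @return object of class `location_alphabet`: data.frame with
#'   `location_id`, `count`, `freq`, `rank`, `significant`.
#' @export
location_frequencies <- function(mat, significance_fraction = 0.01) {
  x <- .as_mat(mat)
  x <- x[x != LP_MISSING]
  .assert(length(x) > 0, "no observed slots: all data missing")
  lev <- unique(x)
  cnt <- tabulate(match(x, lev))
  o <- order(-cnt, lev)
  out <- data.frame(location_id = lev[o], count = cnt[o],
                    freq = cnt[o] / sum(cnt), rank = seq_along(o))
  out$significant <- out$count >= significance_fraction * out$count[1]
  attr(out, "significance_fraction") <- significance_fraction
  class(out) <- c("location_alphabet", class(out))
  out
}

#' Lump rare locations into OTHER
#'
#' Relabels every slot whose location falls below the significance threshold
#' as [LP_OTHER]; OTHER is then an ordinary symbol for all downstream
#' computation. MISSING slots are untouched.
#'
#' @param mat a day matrix.
#' @param alphabet a [location_frequencies()] table (computed from `mat` if
#'   omitted).
#' @return list with `days` (relabelled day matrix) and `alphabet` (reduced
#'   table in which lumped mass is collected under OTHER).
#' @export
threshold_locations <- function(mat, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- location_frequencies(mat)
  rare <- alphabet$location_id[!alphabet$significant]
  a <- attributes(mat)
  m <- .as_mat(mat)
  if (length(rare)) m[m %in% rare] <- LP_OTHER
  attributes(m) <- a
  kept <- alphabet[alphabet$significant, , drop = FALSE]
  if (length(rare)) {
    lump <- data.frame(location_id = LP_OTHER,
                       count = sum(alphabet$count[!alphabet$significant]),
                       freq = sum(alphabet$freq[!alphabet$significant]),
                       rank = nrow(kept) + 1L, significant = FALSE)
    kept <- rbind(kept, lump)
  }
  rownames(kept) <- NULL
  list(days = m, alphabet = kept)
}

#' Number of distinct locations per slot
#'
#' @param mat a (thresholded) day matrix.
#' @return integer vector, one count per slot (MISSING excluded).
#' @export
slot_location_counts <- function(mat) {
  apply(.as_mat(mat), 2, function(col) length(unique(col[col != LP_MISSING])))
}

#' Pooled rank-frequency curve across users
#'
#' Averages the per-user normalised rank-frequency curves (each user's
#' frequencies are indexed by rank, padded with zeros to the longest
#' alphabet, then averaged with equal user weights).
#'
#' @param panel named list of day matrices.
#' @return data.frame with `rank` and `freq` (mean relative frequency).
#' @export
pooled_rank_frequency <- function(panel) {
  curves <- lapply(panel, function(m) location_frequencies(m)$freq)
  rmax <- max(vapply(curves, length, integer(1)))
  m <- vapply(curves, function(f) c(f, rep(0, rmax - length(f))),
              numeric(rmax))
  data.frame(rank = seq_len(rmax), freq = rowMeans(as.matrix(m)))
}

# Truncated discrete power-law machinery: observations are ranks r in
# {xmin..rmax} with P(r) proportional to r^-alpha. Normalisation is the
# finite sum, so no zeta-function approximation is needed.
.pl_negll <- function(alpha, r_vals, n_r, rmax) {
  z <- sum((min(r_vals):rmax)^(-alpha))
  alpha * sum(n_r * log(r_vals)) + sum(n_r) * log(z)
}

.pl_mle <- function(r_vals, n_r, rmax) {
  opt <- stats::optimize(.pl_negll, c(1.0001, 8), r_vals = r_vals,
                         n_r = n_r, rmax = rmax, tol = 1e-7)
  alpha <- opt$minimum
  supp <- min(r_vals):rmax
  p <- supp^(-alpha); p <- p / sum(p)
  vlog <- sum(p * log(supp)^2) - sum(p * log(supp))^2  # Var[log r] under fit
  se <- 1 / sqrt(sum(n_r) * vlog)
  list(alpha = alpha, se = se)
}

.pl_ks <- function(alpha, r_vals, n_r, rmax) {
  supp <- min(r_vals):rmax
  p <- supp^(-alpha); p <- p / sum(p)
  cdf_fit <- cumsum(p)
  emp <- numeric(length(supp))
  emp[match(r_vals, supp)] <- n_r
  cdf_emp <- cumsum(emp) / sum(n_r)
  max(abs(cdf_emp - cdf_fit))
}

#' Discrete maximum-likelihood power-law fit
#'
#' Fits `P(r) ~ r^-alpha` on `r in {xmin..rmax}` (truncated at the largest
#' observed rank) by discrete MLE, with the lower cutoff `xmin` chosen to
#' minimise the Kolmogorov-Smirnov distance between the fitted and empirical
#' tail distributions. Least-squares fitting on log-log axes is deliberately
#' not offered (it is biased for heavy tails).
#'
#' @param counts integer vector of observation counts per rank; `counts[r]`
#'   is the number of observations with rank value `r`. (For slot data this
#'   is the pooled slot-dominance count of the rank-r location.)
#' @param xmin fixed lower cutoff, or `NULL` to scan candidates by KS.
#' @param conf confidence level for the Wald interval (default 0.95).
#' @return list with `alpha`, `se`, `ci` (length 2), `xmin`, `ks`, `n_tail`.
#' @export
fit_power_law <- function(counts, xmin = NULL, conf = 0.95) {
  counts <- as.numeric(counts)
  .assert(all(counts >= 0) && sum(counts) > 0, "counts must be non-negative")
  r_all <- which(counts > 0)
  .assert(length(unique(counts[r_all])) >= 10 || length(r_all) >= 10,
          "too few distinct frequency values for a power-law fit")
  rmax <- max(r_all)
  fit_at <- function(xm) {
    keep <- r_all >= xm
    r_vals <- r_all[keep]; n_r <- counts[r_vals]
    if (length(r_vals) < 5 || sum(n_r) < 20) return(NULL)
    m <- .pl_mle(r_vals, n_r, rmax)
    m$ks <- .pl_ks(m$alpha, r_vals, n_r, rmax)
    m$xmin <- xm; m$n_tail <- sum(n_r)
    m
  }
  if (!is.null(xmin)) {
    best <- fit_at(xmin)
    .assert(!is.null(best), "tail above xmin too small to fit")
  } else {
    cands <- r_all[r_all <= stats::quantile(rep(r_all, counts[r_all]), 0.5)]
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    .assert(length(fits) > 0, "no viable cutoff: sample too small")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  }
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(alpha = best$alpha, se = best$se,
       ci = best$alpha + c(-1, 1) * zq * best$se,
       xmin = best$xmin, ks = best$ks, n_tail = best$n_tail)
}

#' Draw rank observations from a truncated discrete power law
#'
#' Convenience sampler for fitter-recovery tests: `n` draws from
#' `P(r) ~ r^-alpha` on `1..n_ranks`, returned as counts per rank.
#'
#' @param n number of draws.
#' @param n_ranks support size.
#' @param alpha exponent (> 1).
#' @return integer vector of length `n_ranks` (counts).
#' @export
sample_power_law_counts <- function(n, n_ranks, alpha) {
  w <- (1:n_ranks)^(-alpha)
  tabulate(sample.int(n_ranks, n, replace = TRUE, prob = w / sum(w)),
           nbins = n_ranks)
}
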