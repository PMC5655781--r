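# Paired-comparison machinery: Wilcoxon signed-rank with averaged tie ranks,
# split zero-difference rank-sums and a ceiled test statistic, plus
# Benjamini-Hochberg FDR control.

#' Wilcoxon signed-rank test with averaged ties and split zeros
#'
#' Two-sided signed-rank test on paired differences with the following
#' conventions: all data points (including zero differences) receive the
#' average rank of their absolute value among all pairs; the rank-sum of the
#' zero differences is split half and half between the positive and
#' negative rank-sums; a non-integer test statistic (caused by ties or
#' zeros) is rounded up to the next larger integer (conservative). The
#' statistic is the smaller of the two rank-sums. For n <= `exact_limit`
#' pairs the p value is exact, from full enumeration of the 2^m sign
#' assignments of the m nonzero differences (zeros always contribute their
#' split rank-sum); above that a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x first sample (e.g. per-subject accuracies of method A), or the
#'   paired differences if `y` is NULL.
#' @param y second sample (same length as `x`).
#' @param exact_limit maximum n for exact enumeration (default 25).
#' @return list with `statistic` (ceiled min rank-sum), `rank_sum_pos`,
#'   `rank_sum_neg`, `p_value`, `n`, and `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  stopifnot(all(is.finite(d)))
  n <- length(d)
  if (n < 1) stop("need at least one pair")
  r <- rank(abs(d))  # average ranks, zeros included
  zero_half <- sum(r[d == 0]) / 2
  w_pos <- sum(r[d > 0]) + zero_half
  w_neg <- sum(r[d < 0]) + zero_half
  w <- min(w_pos, w_neg)
  statistic <- ceiling(w)
  nz <- which(d != 0)
  m <- length(nz)
  if (m == 0) {
    return(list(statistic = statistic, rank_sum_pos = w_pos,
                rank_sum_neg = w_neg, p_value = 1, n = n, method = "exact"))
  }
  if (m <= exact_limit) {
    # distribution of W+ under random signs of the nonzero differences
    rz <- r[nz]
    sums <- numeric(1)  # rank-sums reachable with subsets (start: empty set)
    for (ri in rz) sums <- c(sums, sums + ri)
    w_plus_all <- sums + zero_half
    lower <- mean(w_plus_all <= statistic)
    upper <- mean(w_plus_all >= 2 * zero_half + sum(rz) - statistic)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r[nz]^2) / 4  # only nonzero differences flip sign
    z <- (w + 0.5 - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(statistic = statistic, rank_sum_pos = w_pos, rank_sum_neg = w_neg,
       p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `alpha`: with ordered p values p_(1) <= ... <=
#' p_(m), all hypotheses up to the largest i with p_(i) <= i * alpha / m are
#' rejected.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `rejected` (logical mask in input order), `threshold`
#'   (largest rejected p value, or 0 if none) and `adjusted` (BH-adjusted p
#'   values).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  rejected <- adjusted <= alpha
  threshold <- if (any(rejected)) max(p_values[rejected]) else 0
  list(rejected = rejected, threshold = threshold, adjusted = adjusted)
}

#' Compare two per-subject accuracy tables
#'
#' Convenience wrapper pairing two (subject, accuracy) tables, running the
#' signed-rank test and reporting the mean difference.
#'
#' @param a,b data.frames with columns `subject` and `accuracy`.
#' @return data.frame with the mean difference, statistic and p value.
#' @export
compare_accuracies <- function(a, b) {
  m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no common subjects between the two tables")
  res <- wilcoxon_signed_rank(m$accuracy_a, m$accuracy_b)
  data.frame(n = res$n, mean_diff = mean(m$accuracy_a - m$accuracy_b),
             statistic = res$statistic, p_value = res$p_value,
             method = res$method)
}
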