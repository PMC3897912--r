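#' Statistic thresholds matching a p-value cutoff
#'
#' For an upper-tail chi-squared test, the statistic threshold equivalent
#' to a p-value cutoff `p_cutoff` at `d` degrees of freedom is the upper
#' `p_cutoff` quantile of \eqn{\chi^2_d}.  Comparing every pair's
#' statistic against its df-matched threshold selects exactly the pairs
#' with `p <= p_cutoff` without evaluating the chi-squared tail for the
#' (vast) non-significant majority.
#'
#' @param p_cutoff P-value cutoff in (0, 1].
#' @param max_df Largest degrees of freedom needed.
#' @return Named numeric vector of thresholds for df `1..max_df`.
#' @examples
#' stat_thresholds(0.05, 2)
#' @export
stat_thresholds <- function(p_cutoff, max_df) {
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1L ||
      p_cutoff <= 0 || p_cutoff > 1)
    stop("p_cutoff must be a single probability in (0, 1]")
  d <- seq_len(max_df)
  stats::setNames(stats::qchisq(p_cutoff, df = d, lower.tail = FALSE), d)
}

# statistics above their df-matched threshold -> long-format table with
# chi-squared upper-tail p-values; sorted by p, ties broken by
# (marker, trait) for deterministic output
association_table <- function(stats, p_cutoff) {
  stopifnot(inherits(stats, "kw_stats"))
  thr <- stat_thresholds(p_cutoff, max(stats$max_allele, 1L))
  hit <- stats$testable & !is.na(stats$statistic) &
    stats$statistic >= thr[pmax(stats$df, 1L)]
  hit[is.na(hit)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  h <- stats$statistic[hit]
  d <- stats$df[hit]
  tab <- data.frame(
    marker = stats$marker_ids[idx[, 2]],
    trait = stats$trait_ids[idx[, 1]],
    statistic = h,
    df = d,
    pvalue = stats::pchisq(h, df = d, lower.tail = FALSE),
    fdr = rep(NA_real_, length(h)),
    stringsAsFactors = FALSE)
  tab <- tab[tab$pvalue <= p_cutoff, , drop = FALSE]
  tab[order(tab$pvalue, tab$marker, tab$trait), , drop = FALSE]
}

#' Permutation-based empirical false discovery rates
#'
#' The empirical FDR of an association observed at p-value `p` is the
#' average number of associations at least as significant in
#' column-permuted data, divided by the number at least as significant in
#' the real data:
#' \deqn{FDR(p) = \frac{\mathrm{mean}_r\, \#\{p'_r \le p\}}{\#\{p_{real} \le p\}}.}
#' Counting uses `<=`, so tied p-values pool and share one FDR value.
#' Raw ratios can exceed 1 or decrease as `p` grows; they are capped at 1
#' and, by default, made monotone non-decreasing in `p` by a running
#' maximum from the smallest p-value upward.
#'
#' @param real_p Numeric vector of p-values from the real scan (all below
#'   the scan cutoff).
#' @param perm_p List with one numeric vector of permuted-scan p-values
#'   per permutation round (same cutoff).
#' @param monotone Enforce monotone non-decreasing FDR in p (default
#'   `TRUE`).
#' @return Numeric vector of FDR values aligned with `real_p`; length 0
#'   input yields length 0 output.
#' @examples
#' empirical_fdr(c(0.01, 0.02), list(numeric(0), 0.015, c(0.005, 0.02)))
#' @export
empirical_fdr <- function(real_p, perm_p, monotone = TRUE) {
  if (length(real_p) == 0L) return(numeric(0))
  if (!is.list(perm_p) || length(perm_p) < 1L)
    stop("perm_p must be a non-empty list (one vector per permutation round)")
  ord <- order(real_p)
  sorted <- real_p[ord]
  n_le_real <- findInterval(sorted, sorted)    # counts with <=, pools ties
  counts <- vapply(
    perm_p, function(pp) as.numeric(findInterval(sorted, sort(pp))),
    numeric(length(sorted)))
  mean_perm <- rowMeans(matrix(counts, nrow = length(sorted)))
  fdr_sorted <- pmin(1, mean_perm / n_le_real)
  if (monotone) fdr_sorted <- cummax(fdr_sorted)
  fdr <- numeric(length(real_p))
  fdr[ord] <- fdr_sorted
  fdr
}
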