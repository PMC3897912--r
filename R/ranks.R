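#' Row-wise mid-ranks of an expression matrix
#'
#' Ranks every trait (row) of an expression matrix independently using
#' mid-ranks (tied values share the average of the ranks they span),
#' ignoring missing values.  Missing positions receive rank 0 so that
#' subsequent matrix products against genotype indicator matrices still
#' produce correct group rank sums, and a 0/1 presence matrix records
#' where data were observed.  The tie bookkeeping needed for the
#' Kruskal-Wallis tie correction -- the sum over tie groups of
#' \eqn{T = t^3 - t}, with \eqn{t} the size of each tie group -- is
#' accumulated per row.
#'
#' @param x Numeric matrix, traits in rows, samples in columns.  `NA` /
#'   `NaN` mark missing values.
#' @return An object of class `"rank_data"`: a list with elements
#'   \describe{
#'     \item{ranks}{numeric matrix of mid-ranks, 0 at missing positions.}
#'     \item{presence}{0/1 matrix, 0 exactly where `x` is missing.}
#'     \item{tie_sum}{per-row sum of \eqn{t^3 - t} over tie groups.}
#'     \item{eff_n}{per-row count of non-missing values.}
#'     \item{untestable}{logical; `TRUE` for rows with fewer than 2
#'       observed values.}
#'     \item{constant}{logical; `TRUE` for rows whose observed values are
#'       all equal (one single tie group), for which the tie-correction
#'       denominator vanishes and the test statistic is undefined.}
#'   }
#' @examples
#' rd <- rank_traits(rbind(a = c(5, 1, 3), b = c(2, 2, 4), c = c(3, NA, 1)))
#' rd$ranks
#' rd$tie_sum
#' @export
rank_traits <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("expression matrix needs at least 1 row and 2 columns")
  n_row <- nrow(x)
  miss <- is.na(x)
  ranks <- matrix(0, n_row, ncol(x), dimnames = dimnames(x))
  tie_sum <- numeric(n_row)
  for (i in seq_len(n_row)) {
    r <- rank(x[i, ], ties.method = "average", na.last = "keep")
    r[is.na(r)] <- 0
    ranks[i, ] <- r
    # tie groups among observed values only
    t_sizes <- tabulate(match(x[i, !miss[i, ]], unique(x[i, !miss[i, ]])))
    tie_sum[i] <- sum(t_sizes^3 - t_sizes)
  }
  eff_n <- as.numeric(ncol(x) - rowSums(miss))
  untestable <- eff_n < 2
  constant <- !untestable & tie_sum >= eff_n^3 - eff_n & eff_n >= 2
  if (any(untestable))
    warning(sum(untestable), " trait(s) with fewer than 2 observed values ",
            "are untestable and excluded from scans")
  structure(
    list(ranks = ranks, presence = 1 - miss, tie_sum = tie_sum,
         eff_n = eff_n, untestable = untestable, constant = constant),
    class = "rank_data")
}

#' @export
print.rank_data <- function(x, ...) {
  cat("Row-ranked trait matrix:", nrow(x$ranks), "traits x",
      ncol(x$ranks), "samples\n")
  cat("  traits with ties:    ", sum(x$tie_sum > 0), "\n")
  cat("  traits with missing: ", sum(x$eff_n < ncol(x$ranks)), "\n")
  if (any(x$untestable))
    cat("  untestable traits:   ", sum(x$untestable), "\n")
  invisible(x)
}
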