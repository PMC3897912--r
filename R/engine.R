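#' Sparse per-allele indicator matrices of a genotype matrix
#'
#' Expands an integer-coded genotype matrix `G` (markers in rows, samples
#' in columns, codes `0..max_allele`, `NA` allowed) into sparse 0/1
#' matrices `I_0, ..., I_l` with `I_i[m, k] = 1` iff `G[m, k] == i`.
#' Missing genotype cells are 0 in every indicator, so each sample
#' contributes to at most one genotype group.
#'
#' @param codes Integer matrix of genotype codes (markers x samples).
#' @param max_allele Highest genotype code `l` to expand; defaults to the
#'   observed maximum.  Codes above `max_allele` are an error.
#' @return List of `max_allele + 1` sparse `dgCMatrix` objects, named
#'   `"0" ... "l"`.
#' @examples
#' indicator_matrices(rbind(m1 = c(0, 1, 1, 2)))
#' @export
indicator_matrices <- function(codes, max_allele = NULL) {
  codes <- validate_genotypes(codes, max_allele)
  l <- attr(codes, "max_allele")
  lapply(stats::setNames(0:l, 0:l), function(i) {
    methods::as(Matrix::Matrix((!is.na(codes)) & codes == i, sparse = TRUE),
                "dMatrix") * 1
  })
}

# shared genotype validation: integer codes in [0, max_allele], NA allowed
validate_genotypes <- function(codes, max_allele = NULL) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  vals <- codes[!is.na(codes)]
  if (length(vals) == 0L) stop("genotype matrix is entirely missing")
  if (any(vals != round(vals)) || any(vals < 0)) {
    bad <- which(!is.na(codes) & (codes != round(codes) | codes < 0),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code at marker '%s', sample '%s'",
                 rownames(codes)[bad[1]] %||% bad[1],
                 colnames(codes)[bad[2]] %||% bad[2]))
  }
  if (is.null(max_allele)) max_allele <- max(vals)
  if (any(vals > max_allele)) {
    bad <- which(!is.na(codes) & codes > max_allele, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype code exceeds max_allele=%d at marker '%s', sample '%s'",
                 max_allele,
                 rownames(codes)[bad[1]] %||% bad[1],
                 colnames(codes)[bad[2]] %||% bad[2]))
  }
  storage.mode(codes) <- "double"
  attr(codes, "max_allele") <- as.integer(max_allele)
  codes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-group rank sums and sample counts
#'
#' Given row-ranked traits and the indicator matrices of a genotype block,
#' forms the group rank-sum matrices `S_i = R I_i'` (traits x markers) and
#' the group sizes: a per-marker vector `N_i = rowSums(I_i)` when no
#' expression value is missing, or the per-pair matrix `Z I_i'` (where `Z`
#' is the 0/1 presence matrix) when it is.  Because missing expression
#' positions carry rank 0, the rank sums are correct without adjustment.
#'
#' @param rank_data A [rank_traits()] result.
#' @param indicators A list of indicator matrices from
#'   [indicator_matrices()] with the same number of samples.
#' @return List with elements `rank_sums` (list of traits x markers
#'   matrices, one per genotype code) and `counts` (list of either
#'   per-marker vectors or traits x markers matrices).
#' @export
group_rank_sums <- function(rank_data, indicators) {
  stopifnot(inherits(rank_data, "rank_data"))
  K <- ncol(rank_data$ranks)
  if (ncol(indicators[[1]]) != K)
    stop("rank data and indicators disagree on sample count")
  expr_missing <- any(rank_data$presence == 0)
  rank_sums <- lapply(indicators, function(I)
    as.matrix(rank_data$ranks %*% Matrix::t(I)))
  counts <- if (expr_missing)
    lapply(indicators, function(I) as.matrix(rank_data$presence %*% Matrix::t(I)))
  else
    lapply(indicators, Matrix::rowSums)
  list(rank_sums = rank_sums, counts = counts)
}

#' Group markers by their missing-sample pattern
#'
#' Missing genotype calls usually stem from sample quality, so the same
#' missing-sample pattern recurs across many markers.  Markers sharing a
#' pattern can be scanned together after dropping exactly those samples,
#' which is how the engine keeps the matrix formulation exact under
#' genotype missingness.
#'
#' @param codes Genotype matrix (markers x samples), `NA` for missing.
#' @return List of partitions, each a list with `markers` (row indices)
#'   and `samples` (retained column indices).  Markers missing every
#'   sample form a partition with an empty sample set (untestable).
#'   Partitions are disjoint and cover all markers; the all-present
#'   pattern retains every sample.
#' @export
partition_missing_genotypes <- function(codes) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  miss <- is.na(codes)
  key <- apply(miss, 1, function(z) paste(which(z), collapse = ","))
  groups <- split(seq_len(nrow(codes)), key)
  # stable order: partition containing the lowest marker index first
  groups <- groups[order(vapply(groups, min, 1L))]
  unname(lapply(groups, function(idx) {
    list(markers = idx, samples = which(!miss[idx[1], ]))
  }))
}

#' Kruskal-Wallis statistics for all marker-trait pairs
#'
#' Computes the tie-corrected Kruskal-Wallis statistic of every pair by
#' indicator-matrix multiplication.  For a pair with `n` jointly observed
#' samples, group rank sums `S_i` and group sizes `N_i`,
#' \deqn{H = \left[\frac{12}{n(n+1)} \sum_i \frac{S_i^2}{N_i} - 3(n+1)\right]
#'       \Big/ \left[1 - \frac{\sum T}{n^3 - n}\right],}
#' where the tie sum runs over tie groups of the trait (\eqn{T = t^3 - t}).
#' Empty genotype groups contribute 0 to the sum, which yields the correct
#' statistic on the reduced number of groups; the pair's degrees of freedom
#' are (non-empty groups - 1).  Genotype missingness is handled by
#' partitioning markers by missing-sample pattern and re-ranking traits on
#' each partition's retained samples; expression missingness via the
#' presence-matrix group counts of [group_rank_sums()].
#'
#' Markers are processed in contiguous slices of `slice_size` to bound the
#' size of intermediate matrices; results are independent of the slicing.
#' Supplying `start_marker` processes the single slice starting there
#' (a hook for trivially parallel runs over marker blocks).
#'
#' @param genotypes Genotype matrix (markers x samples, codes
#'   `0..max_allele`, `NA` allowed).
#' @param expression Expression matrix (traits x samples, `NA` allowed).
#'   Columns must already be aligned with `genotypes` (see
#'   [align_samples()]).
#' @param max_allele Highest genotype code in the dataset; default: the
#'   observed maximum.
#' @param slice_size Markers per slice (default 2000).
#' @param start_marker If given, only the slice
#'   `start_marker : min(start_marker + slice_size - 1, M)` is computed
#'   and returned.
#' @return An object of class `"kw_stats"`: list with traits x markers
#'   matrices `statistic`, `df` and logical `testable`, plus `marker_ids`,
#'   `trait_ids` and `n_samples`.  Untestable pairs (fewer than 2
#'   non-empty groups, fewer than 3 jointly observed samples, or a trait
#'   constant on the retained samples) have `NA` statistics.
#' @examples
#' g <- rbind(m1 = c(0, 0, 0, 1, 1, 1))
#' e <- rbind(t1 = c(2.1, 3.5, 0.3, 8.8, 7.1, 9.4))
#' kw_stat_matrix(g, e)$statistic
#' @export
kw_stat_matrix <- function(genotypes, expression, max_allele = NULL,
                           slice_size = 2000L, start_marker = NULL) {
  genotypes <- validate_genotypes(genotypes, max_allele)
  l <- attr(genotypes, "max_allele")
  if (!is.matrix(expression)) expression <- as.matrix(expression)
  if (ncol(expression) != ncol(genotypes))
    stop("genotype and expression matrices disagree on sample count; ",
         "align them first (see align_samples)")
  M <- nrow(genotypes); N <- nrow(expression)
  slice_size <- as.integer(slice_size)
  if (slice_size < 1L) stop("slice_size must be at least 1")
  slice_size <- min(slice_size, M)
  if (!is.null(start_marker)) {
    start_marker <- as.integer(start_marker)
    if (start_marker < 1L || start_marker > M)
      stop("start_marker out of range")
    starts <- start_marker
  } else {
    starts <- seq.int(1L, M, by = slice_size)
  }
  stat <- matrix(NA_real_, N, M)
  df <- matrix(NA_integer_, N, M)
  testable <- matrix(FALSE, N, M)
  for (s in starts) {
    cols <- s:min(s + slice_size - 1L, M)
    blk <- scan_marker_block(genotypes[cols, , drop = FALSE], expression, l)
    stat[, cols] <- blk$statistic
    df[, cols] <- blk$df
    testable[, cols] <- blk$testable
  }
  if (!is.null(start_marker)) {
    keep <- start_marker:min(start_marker + slice_size - 1L, M)
    stat <- stat[, keep, drop = FALSE]
    df <- df[, keep, drop = FALSE]
    testable <- testable[, keep, drop = FALSE]
    marker_ids <- (rownames(genotypes) %||% paste0("marker", seq_len(M)))[keep]
  } else {
    marker_ids <- rownames(genotypes) %||% paste0("marker", seq_len(M))
  }
  trait_ids <- rownames(expression) %||% paste0("trait", seq_len(N))
  dimnames(stat) <- dimnames(df) <- dimnames(testable) <-
    list(trait_ids, marker_ids)
  dead_traits <- sum(rowSums(testable) == 0)
  if (dead_traits > 0)
    message(dead_traits, " trait(s) untestable against every marker ",
            "(all-missing or constant); excluded from results")
  structure(list(statistic = stat, df = df, testable = testable,
                 marker_ids = marker_ids, trait_ids = trait_ids,
                 n_samples = ncol(genotypes), max_allele = l),
            class = "kw_stats")
}

# one marker slice: partition by missing-genotype pattern, re-rank the
# retained samples of each partition, run the matrix formula
scan_marker_block <- function(codes, expression, l) {
  N <- nrow(expression); m_blk <- nrow(codes)
  stat <- matrix(NA_real_, N, m_blk)
  df <- matrix(NA_integer_, N, m_blk)
  testable <- matrix(FALSE, N, m_blk)
  for (part in partition_missing_genotypes(codes)) {
    mk <- part$markers; sm <- part$samples
    if (length(sm) < 3L) next  # too few retained samples: untestable
    sub <- codes[mk, sm, drop = FALSE]
    rd <- suppressWarnings(
      rank_traits(expression[, sm, drop = FALSE]))
    res <- kw_block_statistic(sub, rd, l)
    stat[, mk] <- res$statistic
    df[, mk] <- res$df
    testable[, mk] <- res$testable
  }
  list(statistic = stat, df = df, testable = testable)
}

# core matrix formula on a complete (no missing genotype) block
kw_block_statistic <- function(codes, rd, l) {
  K <- ncol(codes); N <- nrow(rd$ranks); m <- nrow(codes)
  ind <- indicator_matrices(codes, l)
  gs <- group_rank_sums(rd, ind)
  expr_missing <- any(rd$presence == 0)
  A <- matrix(0, N, m)
  if (expr_missing) {
    nonempty <- matrix(0L, N, m)
    for (i in seq_along(ind)) {
      Ni <- gs$counts[[i]]                 # N x m per-pair counts
      contrib <- gs$rank_sums[[i]]^2 / Ni  # 0/0 -> NaN for empty groups
      contrib[Ni == 0] <- 0                # empty groups contribute 0
      A <- A + contrib
      nonempty <- nonempty + (Ni > 0L)
    }
  } else {
    nonempty_m <- integer(m)
    for (i in seq_along(ind)) {
      Ni <- gs$counts[[i]]                 # per-marker counts
      contrib <- sweep(gs$rank_sums[[i]]^2, 2, Ni, "/")
      contrib[, Ni == 0] <- 0
      A <- A + contrib
      nonempty_m <- nonempty_m + (Ni > 0)
    }
    nonempty <- matrix(nonempty_m, N, m, byrow = TRUE)
  }
  # pair sample count n: the trait's observed count on the retained samples
  # (markers are complete within the block, so n varies by trait only)
  n <- rd$eff_n
  h_raw <- 12 / (n * (n + 1)) * A - 3 * (n + 1)
  tie_den <- 1 - rd$tie_sum / (n^3 - n)
  tie_den[n < 2] <- 0
  H <- h_raw / tie_den
  H[H < 0 & H > -1e-8] <- 0  # clamp roundoff below the true minimum 0
  df <- nonempty - 1L
  ok_trait <- !rd$untestable & !rd$constant & n >= 3 & tie_den > 0
  testable <- (df >= 1L) & matrix(ok_trait, N, m)
  H[!testable] <- NA_real_
  storage.mode(df) <- "integer"
  df[!testable] <- NA_integer_
  list(statistic = H, df = df, testable = testable)
}

#' @export
print.kw_stats <- function(x, ...) {
  cat("Kruskal-Wallis statistic matrix:",
      length(x$trait_ids), "traits x", length(x$marker_ids), "markers,",
      x$n_samples, "samples\n")
  cat("  testable pairs:", sum(x$testable), "of", length(x$testable), "\n")
  invisible(x)
}
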