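#' Genome-wide Kruskal-Wallis eQTL scan
#'
#' Runs the full scan pipeline: align samples between genotype and
#' expression matrices, compute the tie-corrected Kruskal-Wallis statistic
#' of every marker-trait pair by sliced indicator-matrix multiplication
#' ([kw_stat_matrix()]), keep pairs with chi-squared p-value at or below
#' `p_cutoff`, optionally restrict to cis pairs (marker within
#' `cis_window` base pairs of the gene start on the same chromosome), and
#' optionally attach permutation-based empirical FDR values
#' ([empirical_fdr()]).  Each permutation round applies one random
#' permutation to the sample columns of the expression data -- shared
#' across all traits, so trait-trait correlation is preserved -- and
#' re-runs the identical pipeline at the same cutoff.
#'
#' @param genotypes Genotype matrix, markers x samples, integer codes
#'   `0..max_allele`, `NA` for missing calls.
#' @param expression Expression matrix, traits x samples, `NA` for missing
#'   values.  If both matrices carry sample (column) names the columns are
#'   joined on the intersection of names; otherwise equal column counts
#'   are required and positions are trusted.
#' @param p_cutoff P-value cutoff in (0, 1]; only pairs at or below it are
#'   reported (default 0.05).
#' @param n_permutations Permutation rounds for the empirical FDR
#'   (default 0: no FDR column).
#' @param seed Integer seed controlling the permutations (and nothing
#'   else); required when `n_permutations > 0` for reproducibility.
#' @param slice_size Markers per processing slice (default 2000).
#' @param start_marker Restrict the scan to the single slice starting at
#'   this marker index (parallelisation hook).
#' @param marker_pos,gene_pos Optional position tables (data frames with
#'   columns `id`, `chrom`, `pos`; see [read_positions()]).  When both are
#'   given, associations are cis-filtered *before* FDR counting, in both
#'   the real and the permuted scans.
#' @param cis_window Cis window in base pairs (default 1e6), inclusive.
#' @param monotone_fdr Enforce monotone non-decreasing FDR in p
#'   (default `TRUE`).
#' @param max_allele Dataset-wide maximum genotype code; default: observed
#'   maximum.
#' @return Object of class `"kwscan"`: list with `associations` (a data
#'   frame with columns `marker`, `trait`, `statistic`, `df`, `pvalue`,
#'   `fdr`, sorted by ascending p-value, ties broken by marker then
#'   trait), `n_tests` (testable pairs), `dims`, and the scan settings.
#' @examples
#' panel <- simulate_eqtl_panel(simulation_spec(
#'   n_markers = 50, n_traits = 10, n_samples = 60,
#'   effects = data.frame(marker = 1, trait = 1,
#'                        type = "additive", size = 2),
#'   seed = 1))
#' fit <- kw_scan(panel$genotypes, panel$expression,
#'                p_cutoff = 1e-4, n_permutations = 2, seed = 1)
#' fit
#' head(fit$associations)
#' @export
kw_scan <- function(genotypes, expression, p_cutoff = 0.05,
                    n_permutations = 0L, seed = NULL,
                    slice_size = 2000L, start_marker = NULL,
                    marker_pos = NULL, gene_pos = NULL, cis_window = 1e6,
                    monotone_fdr = TRUE, max_allele = NULL) {
  cl <- match.call()
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 0L) stop("n_permutations must be >= 0")
  if (n_permutations > 0L && is.null(seed))
    stop("a seed is required when permutations are requested")
  aligned <- align_samples(genotypes, expression)
  genotypes <- aligned$genotypes
  expression <- aligned$expression
  use_cis <- !is.null(marker_pos) && !is.null(gene_pos)

  run_once <- function(expr) {
    st <- kw_stat_matrix(genotypes, expr, max_allele = max_allele,
                         slice_size = slice_size,
                         start_marker = start_marker)
    tab <- association_table(st, p_cutoff)
    if (use_cis)
      tab <- cis_filter(tab, marker_pos, gene_pos, window = cis_window)
    list(stats = st, table = tab)
  }

  real <- run_once(expression)
  tab <- real$table

  if (n_permutations > 0L && nrow(tab) > 0L) {
    set.seed(as.integer(seed))
    round_seeds <- sample.int(.Machine$integer.max, n_permutations)
    K <- ncol(expression)
    perm_p <- lapply(round_seeds, function(s) {
      set.seed(s)
      perm <- sample.int(K)
      permuted <- expression[, perm, drop = FALSE]
      colnames(permuted) <- colnames(expression)  # break the sample link only
      suppressMessages(run_once(permuted))$table$pvalue
    })
    tab$fdr <- empirical_fdr(tab$pvalue, perm_p, monotone = monotone_fdr)
  }
  rownames(tab) <- NULL

  structure(list(
    associations = tab,
    n_tests = sum(real$stats$testable),
    dims = c(markers = length(real$stats$marker_ids),
             traits = length(real$stats$trait_ids),
             samples = ncol(expression)),
    p_cutoff = p_cutoff,
    n_permutations = n_permutations,
    seed = seed,
    slice_size = slice_size,
    cis_window = if (use_cis) cis_window else NA_real_,
    call = cl), class = "kwscan")
}

#' @export
print.kwscan <- function(x, ...) {
  cat("Kruskal-Wallis eQTL scan\n")
  cat(sprintf("  %d markers x %d traits x %d samples (%d testable pairs)\n",
              x$dims[["markers"]], x$dims[["traits"]], x$dims[["samples"]],
              x$n_tests))
  cat(sprintf("  %d associations at p <= %g", nrow(x$associations),
              x$p_cutoff))
  if (!is.na(x$cis_window))
    cat(sprintf(" (cis only, window %g bp)", x$cis_window))
  cat("\n")
  if (x$n_permutations > 0)
    cat(sprintf("  empirical FDR from %d permutation round(s)\n",
                x$n_permutations))
  invisible(x)
}

#' @export
summary.kwscan <- function(object, fdr_levels = c(0.01, 0.05, 0.1, 0.3),
                           ...) {
  tab <- object$associations
  cat("Kruskal-Wallis eQTL scan: ")
  cat(nrow(tab), "associations at p <=", object$p_cutoff, "\n")
  if (nrow(tab) > 0) {
    cat("\nSmallest p-values:\n")
    print(utils::head(tab, 5), row.names = FALSE)
    if (object$n_permutations > 0) {
      cat("\nAssociations by empirical FDR level:\n")
      counts <- vapply(fdr_levels, function(f) sum(tab$fdr <= f), 0)
      print(stats::setNames(counts, paste0("FDR<=", fdr_levels)))
    }
  }
  invisible(object)
}

#' @export
as.data.frame.kwscan <- function(x, ...) x$associations
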