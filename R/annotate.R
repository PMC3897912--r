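#' Restrict an association table to cis pairs
#'
#' Keeps marker-trait pairs lying on the same chromosome with
#' `|marker position - gene start| <= window`.  The gene start is used as
#' a transcription start site proxy; coordinates are 1-based and the
#' window is inclusive at the boundary.  Pairs referencing a feature with
#' no known position are dropped with a warning.
#'
#' @param associations Association data frame with `marker` and `trait`
#'   columns (e.g. the `associations` element of a [kw_scan()] result).
#' @param marker_pos,gene_pos Position tables: data frames with columns
#'   `id`, `chrom`, `pos` (see [read_positions()]).
#' @param window Cis window in base pairs, default 1e6.
#' @return The filtered association data frame.
#' @export
cis_filter <- function(associations, marker_pos, gene_pos, window = 1e6) {
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  marker_pos <- check_positions(marker_pos, "marker_pos")
  gene_pos <- check_positions(gene_pos, "gene_pos")
  mi <- match(associations$marker, marker_pos$id)
  gi <- match(associations$trait, gene_pos$id)
  unknown <- is.na(mi) | is.na(gi)
  if (any(unknown))
    warning(sum(unknown), " association(s) dropped: no position available ",
            "for their marker or trait")
  keep <- !unknown &
    marker_pos$chrom[mi] == gene_pos$chrom[gi] &
    abs(marker_pos$pos[mi] - gene_pos$pos[gi]) <= window
  keep[is.na(keep)] <- FALSE
  associations[keep, , drop = FALSE]
}

check_positions <- function(pos, what) {
  pos <- as.data.frame(pos)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(pos)))
    stop(what, " must have columns id, chrom, pos")
  if (any(duplicated(pos$id))) stop("duplicate ids in ", what)
  pos
}

#' Classify a biallelic eQTL association
#'
#' Associations at biallelic markers (codes 0/1/2 with 1 = heterozygous)
#' fall into three types: *skewed* when the smallest non-empty genotype
#' group holds fewer than 5 samples -- the regime in which parametric
#' methods chase outliers; otherwise *non-linear* when the heterozygous
#' samples differ significantly from the pooled homozygous samples
#' (two-sided Wilcoxon rank-sum test, p < 0.05) -- the dominant or
#' heterozygote-outside patterns a purely additive model misses; and
#' *other* otherwise.  Markers with codes above 2 are reported as
#' *unclassified*, as are degenerate pairs with fewer than 2 non-empty
#' groups.
#'
#' @param genotype Integer vector of genotype codes for one marker
#'   (`NA` allowed).
#' @param trait Numeric vector of expression values for one trait, same
#'   samples.
#' @return List with `label` (one of `"skewed"`, `"non-linear"`,
#'   `"other"`, `"unclassified"`), `min_group` (smallest non-empty group
#'   size) and `p_het_vs_hom` (rank-sum p-value, `NA` when not computed).
#' @examples
#' g <- rep(c(0, 1, 2), c(30, 40, 30))
#' y <- ifelse(g == 1, rnorm(100, 3), rnorm(100))
#' classify_eqtl(g, y)$label
#' @export
classify_eqtl <- function(genotype, trait) {
  stopifnot(length(genotype) == length(trait))
  ok <- !is.na(genotype) & !is.na(trait)
  g <- genotype[ok]; y <- trait[ok]
  out <- list(label = "unclassified", min_group = NA_integer_,
              p_het_vs_hom = NA_real_)
  if (length(g) == 0 || any(g > 2) || any(g < 0) || any(g != round(g)))
    return(out)
  sizes <- table(g)
  out$min_group <- as.integer(min(sizes))
  if (length(sizes) < 2L) return(out)
  if (out$min_group < 5L) {
    out$label <- "skewed"
    return(out)
  }
  het <- y[g == 1]; hom <- y[g != 1]
  if (length(het) == 0L || length(hom) == 0L) {
    out$label <- "other"  # no heterozygotes: the non-linear test is void
    return(out)
  }
  out$p_het_vs_hom <- suppressWarnings(
    stats::wilcox.test(het, hom, alternative = "two.sided")$p.value)
  out$label <- if (out$p_het_vs_hom < 0.05) "non-linear" else "other"
  out
}

#' Classify every association in a table
#'
#' Applies [classify_eqtl()] to each (marker, trait) row of an
#' association table against the original data matrices.
#'
#' @param associations Association data frame with `marker` and `trait`
#'   columns.
#' @param genotypes,expression The matrices the scan was run on (sample
#'   columns aligned).
#' @return The table with `class`, `min_group` and `p_het_vs_hom` columns
#'   appended.
#' @export
classify_associations <- function(associations, genotypes, expression) {
  aligned <- align_samples(genotypes, expression)
  g <- aligned$genotypes; e <- aligned$expression
  res <- lapply(seq_len(nrow(associations)), function(i) {
    classify_eqtl(g[associations$marker[i], ], e[associations$trait[i], ])
  })
  associations$class <- vapply(res, `[[`, "", "label")
  associations$min_group <- vapply(res, `[[`, 1L, "min_group")
  associations$p_het_vs_hom <- vapply(res, `[[`, 1, "p_het_vs_hom")
  associations
}
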