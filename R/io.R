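#' Read a genotype matrix from tab-separated text
#'
#' Expects a header row of sample IDs, a first column of marker IDs, and
#' integer genotype codes in the cells.  `NA`, `NaN` and empty fields are
#' treated as missing calls.  The dataset-wide maximum code is the
#' inferred `max_allele`.
#'
#' @param path Path to the file.
#' @return Integer matrix, markers in rows (rownames = marker IDs),
#'   samples in columns (colnames = sample IDs).
#' @export
read_genotype_matrix <- function(path) {
  m <- read_feature_matrix(path, "marker")
  m2 <- validate_genotypes(m)         # integer codes, names the offender
  attr(m2, "max_allele") <- NULL
  storage.mode(m2) <- "integer"
  m2
}

#' Read an expression matrix from tab-separated text
#'
#' Same dialect as [read_genotype_matrix()]: header of sample IDs, first
#' column of trait IDs, numeric cells, `NA`/`NaN`/empty missing.
#'
#' @param path Path to the file.
#' @return Numeric matrix, traits in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  read_feature_matrix(path, "trait")
}

read_feature_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("NA", "NaN", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a feature-ID column plus data columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ", what, " ID: ", ids[duplicated(ids)][1])
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample ID in header: ",
         names(df)[-1][duplicated(names(df)[-1])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell at %s '%s', sample '%s'", what,
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
  }
  rownames(m) <- ids
  m
}

#' Write a genotype or expression matrix as tab-separated text
#'
#' Inverse of [read_genotype_matrix()] / [read_expression_matrix()]:
#' header of sample IDs, first column (named `id`) of feature IDs.
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature position table
#'
#' Three tab-separated columns with header: feature `id`, `chrom` label
#' and 1-based base-pair `pos`.
#'
#' @param path Path to the file.
#' @return Data frame with columns `id`, `chrom`, `pos`.
#' @export
read_positions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("id", "chrom", "pos")
  check_positions(df, path)
}

#' Write a feature position table
#' @param pos Data frame with columns `id`, `chrom`, `pos`.
#' @param path Output path.
#' @export
write_positions <- function(pos, path) {
  utils::write.table(check_positions(pos, "pos"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotype and expression matrices on shared samples
#'
#' When both matrices carry column (sample) names, both are reordered to
#' the intersection of the two sets, in the genotype matrix's column
#' order; samples present in only one input are dropped with a warning,
#' and an empty intersection is an error.  Unnamed matrices are trusted
#' positionally (equal column counts required).
#'
#' @param genotypes Markers x samples matrix.
#' @param expression Traits x samples matrix.
#' @return List with aligned `genotypes` and `expression`.
#' @export
align_samples <- function(genotypes, expression) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(expression)) expression <- as.matrix(expression)
  gs <- colnames(genotypes); es <- colnames(expression)
  if (is.null(gs) || is.null(es)) {
    if (ncol(genotypes) != ncol(expression))
      stop("unnamed samples and unequal column counts: cannot align")
    return(list(genotypes = genotypes, expression = expression))
  }
  shared <- intersect(gs, es)
  if (length(shared) == 0L) stop("no shared sample IDs between inputs")
  dropped <- (length(gs) - length(shared)) + (length(es) - length(shared))
  if (dropped > 0)
    warning(dropped, " sample column(s) without a partner dropped; ",
            length(shared), " shared samples retained")
  else
    message(length(shared), " samples aligned")
  list(genotypes = genotypes[, shared, drop = FALSE],
       expression = expression[, shared, drop = FALSE])
}

#' Write an association table as tab-separated text
#'
#' Columns `marker`, `trait`, `statistic`, `df`, `pvalue`, `fdr`, sorted
#' by ascending p-value with ties broken by (marker, trait); numbers at
#' full double precision so that re-reading reproduces the table.
#'
#' @param associations Association data frame (or a `"kwscan"` object).
#' @param path Output path.
#' @export
write_associations <- function(associations, path) {
  if (inherits(associations, "kwscan"))
    associations <- associations$associations
  cols <- c("marker", "trait", "statistic", "df", "pvalue", "fdr")
  tab <- associations[order(associations$pvalue, associations$marker,
                            associations$trait), cols, drop = FALSE]
  for (cc in c("statistic", "pvalue", "fdr"))
    tab[[cc]] <- sprintf("%.15g", tab[[cc]])
  tab$fdr[tab$fdr == "NA"] <- "NA"
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_associations()]
#' @param path Path to the file.
#' @return Association data frame.
#' @export
read_associations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(marker = "character",
                                   trait = "character"))
}
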