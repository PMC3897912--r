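#' Specification of a synthetic eQTL panel
#'
#' Collects and validates the parameters of [simulate_eqtl_panel()]:
#' panel dimensions, the minor allele frequency range from which each
#' marker's MAF is drawn, the per-marker allele count (2 for biallelic
#' SNPs coded 0/1/2, 3 for multiallelic markers coded 0..3), the planted
#' effects, and the rates at which missing values and rounding-induced
#' ties are injected.
#'
#' Planted effect types (`effects` data frame columns `marker`, `trait`,
#' `type`, `size`; `size` in units of the unit-variance expression noise):
#' \describe{
#'   \item{additive}{per-allele dosage shift `size * g`.}
#'   \item{dominant}{shift `size` for every carrier (`g >= 1`).}
#'   \item{het-outside}{shift `size` for heterozygotes only (`g == 1`),
#'     placing them outside the homozygote range.}
#' }
#'
#' @param n_markers,n_traits,n_samples Panel dimensions (default
#'   1000 x 100 x 100).
#' @param maf_range Interval in (0, 0.5] from which marker MAFs are drawn
#'   uniformly; default `c(0.05, 0.5)`, mirroring the common >5% MAF
#'   filter applied to real SNP panels.
#' @param allele_count 2 or 3, scalar or per-marker vector (default 2).
#' @param effects `NULL` or a data frame of planted effects (see above);
#'   (marker, trait) pairs must be unique and in range.
#' @param missing_rate_geno,missing_rate_expr Independent per-cell
#'   missingness probabilities in `[0, 1)` (default 0).
#' @param tie_rate Probability in `[0, 1)` that an expression value is
#'   rounded to one decimal, inducing ties (default 0).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return Validated list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_markers = 1000L, n_traits = 100L,
                            n_samples = 100L, maf_range = c(0.05, 0.5),
                            allele_count = 2L, effects = NULL,
                            missing_rate_geno = 0, missing_rate_expr = 0,
                            tie_rate = 0, seed = 1L) {
  stopifnot(n_markers >= 1, n_traits >= 1, n_samples >= 2)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  allele_count <- as.integer(allele_count)
  if (!all(allele_count %in% c(2L, 3L)))
    stop("allele_count must be 2 or 3")
  if (length(allele_count) == 1L)
    allele_count <- rep(allele_count, n_markers)
  if (length(allele_count) != n_markers)
    stop("allele_count must be scalar or one value per marker")
  for (r in c(missing_rate_geno, missing_rate_expr, tie_rate))
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    need <- c("marker", "trait", "type", "size")
    if (!all(need %in% names(effects)))
      stop("effects needs columns marker, trait, type, size")
    if (!all(effects$type %in% c("additive", "dominant", "het-outside")))
      stop("effect type must be additive, dominant or het-outside")
    if (any(effects$marker < 1 | effects$marker > n_markers |
            effects$trait < 1 | effects$trait > n_traits))
      stop("planted effect references an out-of-range marker or trait")
    if (anyDuplicated(effects[, c("marker", "trait")]))
      stop("planted (marker, trait) pairs must be unique")
  }
  structure(list(n_markers = as.integer(n_markers),
                 n_traits = as.integer(n_traits),
                 n_samples = as.integer(n_samples),
                 maf_range = maf_range, allele_count = allele_count,
                 effects = effects,
                 missing_rate_geno = missing_rate_geno,
                 missing_rate_expr = missing_rate_expr,
                 tie_rate = tie_rate, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a genotype/expression panel with planted eQTLs
#'
#' Genotypes are drawn per marker at a MAF sampled uniformly from
#' `maf_range`: biallelic markers take Hardy-Weinberg genotype
#' frequencies \eqn{((1-q)^2, 2q(1-q), q^2)} over codes 0/1/2;
#' three-allele markers collapse the six Hardy-Weinberg genotype classes
#' of allele frequencies \eqn{(p_1, p_2, q)} into four ordered codes
#' \eqn{(p_1^2,\; 2p_1p_2,\; p_2^2 + 2p_1q,\; 2p_2q + q^2)}.  Expression
#' is unit-variance Gaussian noise plus the planted effect terms.
#' Missing values and rounding ties are then injected independently per
#' cell at the spec rates.
#'
#' Features are placed on 5 synthetic chromosomes of 200 Mbp: markers
#' uniformly at random; each planted trait within 0.5 Mbp of its marker
#' (guaranteed cis under a 1 Mbp window), all other traits uniformly at
#' random (almost always trans to any given marker).
#'
#' @param spec A [simulation_spec()].
#' @return List of class `"eqtl_panel"`: `genotypes` (markers x samples,
#'   `NA` for missing), `expression` (traits x samples), `marker_pos` and
#'   `gene_pos` (data frames `id`, `chrom`, `pos`), `truth` (the planted
#'   effects with ids), `maf` (per-marker), and `spec`.
#' @examples
#' panel <- simulate_eqtl_panel(simulation_spec(
#'   n_markers = 20, n_traits = 5, n_samples = 50, seed = 7))
#' panel$genotypes[1:3, 1:6]
#' @export
simulate_eqtl_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  M <- spec$n_markers; N <- spec$n_traits; K <- spec$n_samples
  marker_ids <- sprintf("snp_%04d", seq_len(M))
  trait_ids <- sprintf("gene_%04d", seq_len(N))
  sample_ids <- sprintf("sample_%03d", seq_len(K))

  maf <- stats::runif(M, spec$maf_range[1], spec$maf_range[2])
  geno <- matrix(NA_integer_, M, K, dimnames = list(marker_ids, sample_ids))
  for (m in seq_len(M)) {
    q <- maf[m]
    if (spec$allele_count[m] == 2L) {
      probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    } else {
      u <- stats::runif(1, 0.3, 0.7)   # split the major mass over 2 alleles
      p1 <- (1 - q) * u; p2 <- (1 - q) * (1 - u)
      probs <- c(p1^2, 2 * p1 * p2, p2^2 + 2 * p1 * q, 2 * p2 * q + q^2)
    }
    geno[m, ] <- sample.int(length(probs), K, replace = TRUE,
                            prob = probs) - 1L
  }

  expr <- matrix(stats::rnorm(N * K), N, K,
                 dimnames = list(trait_ids, sample_ids))
  if (!is.null(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      ef <- spec$effects[i, ]
      g <- geno[ef$marker, ]
      shift <- switch(as.character(ef$type),
        "additive" = ef$size * g,
        "dominant" = ef$size * (g >= 1),
        "het-outside" = ef$size * (g == 1))
      expr[ef$trait, ] <- expr[ef$trait, ] + shift
    }
  }

  # positions: 5 chromosomes of 200 Mbp
  n_chr <- 5L; chr_len <- 2e8
  marker_pos <- data.frame(
    id = marker_ids,
    chrom = paste0("chr", sample.int(n_chr, M, replace = TRUE)),
    pos = floor(stats::runif(M, 1, chr_len)))
  gene_pos <- data.frame(
    id = trait_ids,
    chrom = paste0("chr", sample.int(n_chr, N, replace = TRUE)),
    pos = floor(stats::runif(N, 1, chr_len)))
  if (!is.null(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      ef <- spec$effects[i, ]
      gene_pos$chrom[ef$trait] <- marker_pos$chrom[ef$marker]
      offset <- round(stats::runif(1, -5e5, 5e5))
      gene_pos$pos[ef$trait] <- max(1, marker_pos$pos[ef$marker] + offset)
    }
  }

  if (spec$tie_rate > 0) {
    sel <- stats::rbinom(N * K, 1, spec$tie_rate) == 1
    expr[sel] <- round(expr[sel], 1)
  }
  if (spec$missing_rate_geno > 0)
    geno[stats::rbinom(M * K, 1, spec$missing_rate_geno) == 1] <- NA_integer_
  if (spec$missing_rate_expr > 0)
    expr[stats::rbinom(N * K, 1, spec$missing_rate_expr) == 1] <- NA_real_

  truth <- if (is.null(spec$effects)) {
    data.frame(marker = character(0), trait = character(0),
               type = character(0), size = numeric(0))
  } else {
    data.frame(marker = marker_ids[spec$effects$marker],
               trait = trait_ids[spec$effects$trait],
               type = as.character(spec$effects$type),
               size = spec$effects$size)
  }

  structure(list(genotypes = geno, expression = expr,
                 marker_pos = marker_pos, gene_pos = gene_pos,
                 truth = truth, maf = maf, spec = spec),
            class = "eqtl_panel")
}

#' @export
print.eqtl_panel <- function(x, ...) {
  cat(sprintf("Synthetic eQTL panel: %d markers x %d traits x %d samples\n",
              nrow(x$genotypes), nrow(x$expression), ncol(x$genotypes)))
  cat(sprintf("  planted effects: %d; MAF range [%.2f, %.2f]; seed %d\n",
              nrow(x$truth), x$spec$maf_range[1], x$spec$maf_range[2],
              x$spec$seed))
  invisible(x)
}
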