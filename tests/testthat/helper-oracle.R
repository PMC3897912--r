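# Independent per-pair Kruskal-Wallis oracle: ranks within the
# pairwise-complete samples, applies the standard tie correction.
# Deliberately scalar / split-based so it shares nothing with the
# matrix-multiplication engine.
kw_pair_oracle <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  n <- length(y)
  grp <- split(rank(y), g)
  if (n < 3 || length(grp) < 2)
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(grp, sum, 0)^2 / lengths(grp)) - 3 * (n + 1)
  tt <- table(y)
  den <- 1 - sum(tt^3 - tt) / (n^3 - n)
  if (den <= 0)
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  h <- h / den
  df <- length(grp) - 1L
  list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE),
       testable = TRUE)
}

# the uncorrected statistic (no tie division), for negative controls
kw_pair_uncorrected <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  n <- length(y)
  grp <- split(rank(y), g)
  12 / (n * (n + 1)) * sum(vapply(grp, sum, 0)^2 / lengths(grp)) -
    3 * (n + 1)
}

# compare a kw_stats object to the oracle over all (or sampled) pairs
expect_matches_oracle <- function(st, genotypes, expression,
                                  tol = 1e-9, pairs = NULL) {
  N <- length(st$trait_ids); M <- length(st$marker_ids)
  if (is.null(pairs))
    pairs <- cbind(rep(seq_len(N), M), rep(seq_len(M), each = N))
  worst <- 0
  mismatches <- 0L
  for (i in seq_len(nrow(pairs))) {
    n <- pairs[i, 1]; m <- pairs[i, 2]
    o <- kw_pair_oracle(genotypes[m, ], expression[n, ])
    if (!identical(o$testable, st$testable[n, m])) {
      mismatches <- mismatches + 1L
      next
    }
    if (!o$testable) next
    err <- max(abs(o$H - st$statistic[n, m]) / max(1, abs(o$H)),
               abs(o$df - st$df[n, m]))
    worst <- max(worst, err)
  }
  expect_identical(mismatches, 0L)
  expect_lt(worst, tol)
  invisible(worst)
}

# small mixed panel exercising every correction at once
mixed_panel <- function(seed, M = 60, N = 15, K = 40) {
  simulate_eqtl_panel(simulation_spec(
    n_markers = M, n_traits = N, n_samples = K,
    allele_count = rep(c(2L, 3L), length.out = M),
    missing_rate_geno = 0.1, missing_rate_expr = 0.05,
    tie_rate = 0.3, seed = seed))
}
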