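test_that("indicator matrices partition samples by genotype code", {
  ind <- indicator_matrices(rbind(m1 = c(0, 1, 1, 2)))
  expect_equal(as.numeric(ind[["0"]]), c(1, 0, 0, 0))
  expect_equal(as.numeric(ind[["1"]]), c(0, 1, 1, 0))
  expect_equal(as.numeric(ind[["2"]]), c(0, 0, 0, 1))

  # monomorphic marker: all mass in one indicator
  ind <- indicator_matrices(rbind(c(0, 0, 0, 0)), max_allele = 2)
  expect_equal(Matrix::rowSums(ind[["0"]]), 4, ignore_attr = TRUE)
  expect_equal(Matrix::rowSums(ind[["1"]]) + Matrix::rowSums(ind[["2"]]),
               0, ignore_attr = TRUE)

  # missing genotype contributes to no group
  ind <- indicator_matrices(rbind(c(0, NA, 1, 1)))
  tot <- Reduce(`+`, lapply(ind, Matrix::rowSums))
  expect_equal(tot, 3, ignore_attr = TRUE)
  expect_true(all(vapply(ind, function(I) I[1, 2], 1) == 0))

  expect_error(indicator_matrices(rbind(c(0, 3, 1)), max_allele = 2),
               "max_allele")
  expect_error(indicator_matrices(rbind(c(0, 1.5, 1))), "invalid genotype")
})

test_that("group rank sums and counts match their definitions", {
  rd <- rank_traits(rbind(t1 = c(10, 20, 30, 40, 50, 60)))
  ind <- indicator_matrices(rbind(m1 = c(0, 0, 0, 1, 1, 1)))
  gs <- group_rank_sums(rd, ind)
  expect_equal(as.numeric(gs$rank_sums[["0"]]), 6)
  expect_equal(as.numeric(gs$rank_sums[["1"]]), 15)
  expect_equal(as.numeric(gs$counts[["0"]]), 3)

  # missing expression: rank 0 keeps sums right, presence fixes counts
  rd <- suppressWarnings(rank_traits(rbind(t1 = c(3, NA, 1))))
  gs <- group_rank_sums(rd, indicator_matrices(rbind(m1 = c(0, 1, 1))))
  expect_equal(as.numeric(gs$rank_sums[["0"]]), 2)
  expect_equal(as.numeric(gs$rank_sums[["1"]]), 1)
  expect_equal(as.numeric(gs$counts[["0"]]), 1)  # per-pair count matrix
  expect_equal(as.numeric(gs$counts[["1"]]), 1)

  expect_error(
    group_rank_sums(rd, indicator_matrices(rbind(c(0, 1, 1, 0)))),
    "sample count")
})

test_that("statistic matches hand-computed and brute-force values", {
  # ranks [2,3,1,5,4,6] against groups of 3: H = 12/42*(36/3+225/3)-21
  g <- rbind(m = c(0, 0, 0, 1, 1, 1))
  e <- rbind(t = c(1.2, 1.5, 0.1, 8.0, 7.7, 9.9))
  st <- kw_stat_matrix(g, e)
  expect_equal(st$statistic[1, 1], 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_equal(st$statistic[1, 1], 3.857142857, tolerance = 1e-9)
  expect_equal(st$df[1, 1], 1L)
  expect_equal(st$statistic[1, 1],
               unname(kruskal.test(e[1, ], factor(g[1, ]))$statistic))

  # symmetric rank sums force the minimum H = 0
  st0 <- kw_stat_matrix(rbind(c(0, 1, 1, 0)), rbind(c(1.1, 2.2, 3.3, 4.4)))
  expect_equal(st0$statistic[1, 1], 0)

  # one tied pair: uncorrected H divided by 1 - 6/60
  g <- rbind(m = c(0, 0, 1, 1))
  e <- rbind(t = c(5, 5, 8, 9))
  st <- kw_stat_matrix(g, e)
  h_unc <- kw_pair_uncorrected(g[1, ], e[1, ])
  expect_equal(st$statistic[1, 1], h_unc / (1 - 6 / 60))
})

test_that("empty genotype groups reduce the degrees of freedom", {
  g <- rbind(m = c(0, 0, 1, 1, 0, 1))
  e <- rbind(t = c(2.5, 1.1, 7.2, 6.3, 0.4, 9.9))
  st2 <- kw_stat_matrix(g, e, max_allele = 2)  # group 2 empty
  st1 <- kw_stat_matrix(g, e, max_allele = 1)
  expect_equal(st2$statistic, st1$statistic)
  expect_equal(st2$df[1, 1], 1L)
  # raising max_allele further with no carriers changes nothing
  st9 <- kw_stat_matrix(g, e, max_allele = 5)
  expect_equal(st9$statistic, st2$statistic)
  expect_equal(st9$df, st2$df)
})

test_that("missing-genotype patterns partition markers correctly", {
  codes <- rbind(A = c(0, NA, 1, 2),
                 B = c(1, 1, 0, 0),
                 C = c(2, NA, 0, 1))
  parts <- partition_missing_genotypes(codes)
  expect_length(parts, 2)
  expect_equal(parts[[1]]$markers, c(1L, 3L))   # A and C share the pattern
  expect_equal(parts[[1]]$samples, c(1L, 3L, 4L))
  expect_equal(parts[[2]]$markers, 2L)
  expect_equal(parts[[2]]$samples, 1:4)

  # complete matrix: one partition with every sample
  parts <- partition_missing_genotypes(rbind(c(0, 1), c(1, 0)))
  expect_length(parts, 1)
  expect_equal(parts[[1]]$markers, 1:2)

  # marker missing everywhere: empty retained set, untestable downstream
  codes <- rbind(ok = c(0, 1, 0, 1), gone = c(NA, NA, NA, NA))
  parts <- partition_missing_genotypes(codes)
  expect_equal(parts[[2]]$samples, integer(0))
  st <- kw_stat_matrix(codes, rbind(c(1.5, 2.5, 0.5, 3.5)))
  expect_false(st$testable[1, 2])
  expect_true(st$testable[1, 1])
})

test_that("engine equals the per-pair oracle on mixed messy panels", {
  for (seed in 1:3) {
    panel <- mixed_panel(seed)
    st <- suppressMessages(
      kw_stat_matrix(panel$genotypes, panel$expression))
    expect_matches_oracle(st, panel$genotypes, panel$expression)
  }
})

test_that("conservation: group counts and rank sums add up", {
  panel <- mixed_panel(4, M = 20, N = 6, K = 30)
  g <- panel$genotypes; e <- panel$expression
  part <- partition_missing_genotypes(g)[[1]]
  sm <- part$samples
  rd <- suppressWarnings(rank_traits(e[, sm, drop = FALSE]))
  ind <- indicator_matrices(g[part$markers, sm, drop = FALSE],
                            max_allele = 3)
  gs <- group_rank_sums(rd, ind)
  s_tot <- Reduce(`+`, gs$rank_sums)
  for (j in seq_along(part$markers))
    expect_equal(s_tot[, j], rd$eff_n * (rd$eff_n + 1) / 2,
                 ignore_attr = TRUE)
  if (is.matrix(gs$counts[[1]])) {      # per-pair counts (expr missingness)
    n_tot <- Reduce(`+`, gs$counts)
    for (j in seq_along(part$markers))
      expect_equal(n_tot[, j], rd$eff_n, ignore_attr = TRUE)
  } else {
    expect_equal(Reduce(`+`, gs$counts),
                 rep(length(sm), length(part$markers)),
                 ignore_attr = TRUE)
  }
})

test_that("statistics are invariant under monotone trait transforms", {
  panel <- mixed_panel(5, M = 30, N = 8, K = 35)
  a <- suppressMessages(kw_stat_matrix(panel$genotypes, panel$expression))
  b <- suppressMessages(
    kw_stat_matrix(panel$genotypes, exp(panel$expression)))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$df, b$df)
})

test_that("slicing and start_marker reproduce the full run exactly", {
  panel <- mixed_panel(6, M = 23, N = 6, K = 30)
  full <- suppressMessages(
    kw_stat_matrix(panel$genotypes, panel$expression, slice_size = 23))
  for (sz in c(1, 7, 23)) {
    sliced <- suppressMessages(
      kw_stat_matrix(panel$genotypes, panel$expression, slice_size = sz))
    expect_identical(sliced$statistic, full$statistic)
    expect_identical(sliced$df, full$df)
  }
  # a single slice from start_marker equals the matching columns
  one <- suppressMessages(
    kw_stat_matrix(panel$genotypes, panel$expression, slice_size = 7,
                   start_marker = 8))
  expect_identical(one$statistic, full$statistic[, 8:14])
  expect_error(
    kw_stat_matrix(panel$genotypes, panel$expression, start_marker = 99),
    "out of range")
})
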