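test_that("statistic thresholds invert the chi-squared tail", {
  expect_equal(unname(stat_thresholds(1.0, 3)), c(0, 0, 0))
  expect_equal(unname(stat_thresholds(0.05, 1)), 3.841459,
               tolerance = 1e-6)
  # thresholds strictly increase with df at fixed cutoff
  thr <- stat_thresholds(0.01, 5)
  expect_true(all(diff(thr) > 0))
  # threshold crossing is equivalent to p <= cutoff
  h <- seq(0.5, 12, by = 0.25)
  p <- pchisq(h, 2, lower.tail = FALSE)
  expect_equal(h >= stat_thresholds(0.05, 2)[2], p <= 0.05)
  expect_error(stat_thresholds(0, 2), "p_cutoff")
})

test_that("only pairs past their df-matched threshold get p-values", {
  g <- rbind(m1 = c(0, 0, 0, 1, 1, 1),
             m2 = c(0, 1, 0, 1, 0, 1))
  e <- rbind(t1 = c(1.2, 1.5, 0.1, 8.0, 7.7, 9.9),  # strong separation
             t2 = c(5, 3, 1, 6, 2, 7))
  fit <- suppressMessages(kw_scan(g, e, p_cutoff = 0.05))
  expect_equal(nrow(fit$associations), 1L)
  expect_equal(fit$associations$marker, "m1")
  expect_equal(fit$associations$pvalue, 0.04953461, tolerance = 1e-6)
  expect_equal(fit$associations$statistic, 3.857142857, tolerance = 1e-9)
  # H = 0 pairs never appear below a cutoff < 1
  fit_all <- suppressMessages(kw_scan(g, e, p_cutoff = 1))
  expect_equal(nrow(fit_all$associations), 4L)
  expect_true(all(fit_all$associations$pvalue <= 1))
})

test_that("empirical FDR follows the permuted/real count ratio", {
  # at p = 0.02: two real associations; permuted rounds contribute 0, 1, 2
  fdr <- empirical_fdr(c(0.01, 0.02),
                       list(numeric(0), 0.015, c(0.005, 0.02)))
  expect_equal(fdr[2], (0 + 1 + 2) / 3 / 2)
  # monotone enforcement: running maximum from the smallest p
  raw <- empirical_fdr(c(0.01, 0.02), list(c(0.005, 0.006)),
                       monotone = FALSE)
  expect_equal(raw, c(1, 1))      # capped at 1
  non_mono <- empirical_fdr(c(0.001, 0.02), list(c(0.005)),
                            monotone = FALSE)
  expect_equal(non_mono, c(0, 0.5))
  expect_equal(empirical_fdr(numeric(0), list(1)), numeric(0))
  # tied p-values pool and share an FDR value
  tied <- empirical_fdr(c(0.01, 0.01), list(0.005))
  expect_equal(tied[1], tied[2])
})

test_that("null data yields FDR near 1 and uniform-ish p-values", {
  panel <- simulate_eqtl_panel(simulation_spec(
    n_markers = 150, n_traits = 30, n_samples = 60,
    maf_range = c(0.2, 0.5), seed = 21))
  fit <- suppressMessages(kw_scan(panel$genotypes, panel$expression,
                                  p_cutoff = 0.05, n_permutations = 4,
                                  seed = 5))
  # with no signal the permuted scans mirror the real one
  expect_gt(stats::median(fit$associations$fdr), 0.5)
  expect_gt(max(fit$associations$fdr), 0.9)
})

test_that("permutation FDR is reproducible under a fixed seed", {
  panel <- simulate_eqtl_panel(simulation_spec(
    n_markers = 80, n_traits = 15, n_samples = 50,
    effects = data.frame(marker = 1, trait = 1, type = "additive",
                         size = 2),
    seed = 31))
  f1 <- suppressMessages(kw_scan(panel$genotypes, panel$expression,
                                 p_cutoff = 0.01, n_permutations = 3,
                                 seed = 77))
  f2 <- suppressMessages(kw_scan(panel$genotypes, panel$expression,
                                 p_cutoff = 0.01, n_permutations = 3,
                                 seed = 77))
  expect_identical(f1$associations, f2$associations)
  expect_error(kw_scan(panel$genotypes, panel$expression,
                       n_permutations = 2), "seed")
})
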