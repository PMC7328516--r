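test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 100, 200, 4, 8), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(median_ratio_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)))
  # identity and scaling properties
  m2 <- matrix(rpois(30, 50) + 1, 10, 3)
  expect_equal(unname(median_ratio_size_factors(cbind(m2[, 1], m2[, 1]))),
               c(1, 1))
  # scaling a sample by c multiplies its factor relative to the others by c
  # (absolute factors shift together through the per-row geometric means)
  sf <- median_ratio_size_factors(m2)
  m3 <- m2; m3[, 2] <- m3[, 2] * 2
  sf3 <- median_ratio_size_factors(m3)
  expect_equal(sf3[2] / sf3[1], 2 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf3[3] / sf3[1], sf[3] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(median_ratio_size_factors(matrix(c(0, 1, 1, 0), 2, 2)),
               "all-positive")
})

test_that("size factors agree with the reference median-ratios implementation", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(5)
  for (i in 1:5) {
    m <- matrix(rnbinom(200, mu = 80, size = 5), 50, 4)
    m[1, ] <- m[1, ] + 1  # ensure one all-positive row
    expect_equal(unname(median_ratio_size_factors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
  }
})

test_that("per-segment fold changes compare averaged normalized depths", {
  m <- matrix(c(10, 20, 20), 1, 3, dimnames = list("g1:1", c("w", "m1", "m2")))
  sc <- segment_counts(m, c("wt", "mut", "mut"), gene_id = "g1",
                       segment_index = 1L)
  fc <- segment_fold_changes(sc, size_factors = c(w = 1, m1 = 1, m2 = 1))
  expect_equal(fc$fc, 2.0)
  # identical conditions give FC 1, zero reference gives NA
  m2 <- rbind(`g1:1` = c(5, 5, 5), `g1:2` = c(0, 3, 3))
  colnames(m2) <- c("w", "m1", "m2")
  sc2 <- segment_counts(m2, c("wt", "mut", "mut"))
  fc2 <- segment_fold_changes(sc2, size_factors = c(w = 1, m1 = 1, m2 = 1))
  expect_equal(fc2$fc, c(1.0, NA))
})

test_that("BH adjustment matches hand-computed step-up examples", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(-0.1), "\\[0, 1\\]")
})

test_that("APA score: identity, worked example, antisymmetry", {
  # identical usage in both conditions: score 0
  fit0 <- apa_fit(two_seg_counts(10, 10, 10, 10),
                  size_factors = c(wt1 = 1, mut1 = 1))
  expect_equal(fit0$results$apa_score, 0)
  expect_equal(fit0$results$ratio_ref, 1)

  # wt (prox 10, dist 20), mut (prox 20, dist 10): log2((10/20)/(20/10)) = -2
  fit <- apa_fit(two_seg_counts(10, 20, 20, 10),
                 size_factors = c(wt1 = 1, mut1 = 1))
  expect_equal(fit$results$apa_score, -2)

  # swapping condition labels negates the score
  m <- two_seg_counts(10, 20, 20, 10)
  swapped <- segment_counts(m$counts[, c(2, 1)], c("wt", "mut"),
                            gene_id = m$gene_id,
                            segment_index = m$segment_index)
  fit_sw <- apa_fit(swapped, size_factors = c(mut1 = 1, wt1 = 1))
  expect_equal(fit_sw$results$apa_score, 2)
})

test_that("scores are invariant to per-sample scaling", {
  withr::local_seed(11)
  sim <- simulate_apa_counts(simulation_config(n_genes = 40, seed = 11))
  fit1 <- apa_fit(sim$counts)
  scaled <- sim$counts
  scaled$counts[, 2] <- scaled$counts[, 2] * 3
  scaled$depth[, 2] <- scaled$depth[, 2] * 3
  fit2 <- apa_fit(scaled)
  expect_equal(fit2$results$apa_score, fit1$results$apa_score,
               tolerance = 1e-9)
  expect_equal(fit2$size_factors[2] / fit2$size_factors[1],
               3 * fit1$size_factors[2] / fit1$size_factors[1],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("zero segments get finite scores via the pseudocount", {
  fit <- apa_fit(two_seg_counts(10, 0, 10, 20),
                 size_factors = c(wt1 = 1, mut1 = 1))
  expect_true(is.finite(fit$results$apa_score))
  # pseudocount applied to all four averaged depths:
  # log2(((20+.5)/(10+.5)) / ((0+.5)/(10+.5)))
  expect_equal(fit$results$apa_score, log2(20.5 / 0.5))
})

test_that("binomial GLM reproduces the null and strong-shift examples", {
  cond <- factor(c("wt", "wt", "mut", "mut"), levels = c("wt", "mut"))
  # identical distal fractions: coefficient 0, p = 1
  r0 <- binomial_usage_test(c(50, 50, 50, 50), c(50, 50, 50, 50), cond)
  expect_equal(r0$coef, 0)
  expect_equal(r0$p, 1)
  expect_false(r0$flag)

  # wt (prox 100, dist 100) x2 vs mut (prox 180, dist 20) x2
  r1 <- binomial_usage_test(c(100, 100, 20, 20), c(100, 100, 180, 180), cond)
  expect_lt(r1$p, 1e-10)
  # order-of-magnitude agreement with the pooled chi-square oracle
  chi <- stats::chisq.test(matrix(c(200, 200, 40, 360), 2, 2))$p.value
  expect_lt(chi, 1e-10)

  # all-zero gene: missing p
  rz <- binomial_usage_test(c(0, 0, 0, 0), c(0, 0, 0, 0), cond)
  expect_true(is.na(rz$p))

  # complete separation: flagged continuity-corrected fallback
  rs <- binomial_usage_test(c(0, 0, 50, 50), c(50, 50, 0, 0), cond)
  expect_true(rs$flag)
  expect_true(is.finite(rs$p) && rs$p < 0.01)
})

test_that("LRT and quasibinomial options return valid p-values", {
  cond <- factor(c("wt", "wt", "mut", "mut"), levels = c("wt", "mut"))
  d <- c(40, 50, 80, 90); p <- c(60, 50, 20, 10)
  r_wald <- binomial_usage_test(d, p, cond, test = "wald")
  r_lrt <- binomial_usage_test(d, p, cond, test = "lrt")
  r_quasi <- binomial_usage_test(d, p, cond, family = "quasibinomial")
  for (r in list(r_wald, r_lrt, r_quasi)) {
    expect_true(r$p > 0 && r$p < 1)
  }
  # LRT and Wald agree on the coefficient and both detect the shift
  expect_equal(r_lrt$coef, r_wald$coef)
  expect_lt(r_lrt$p, 1e-4)
  expect_lt(r_wald$p, 1e-4)
})

test_that("event classification applies both thresholds", {
  expect_identical(classify_events(-1.5, 0.001), "proximal")
  expect_identical(classify_events(-1.5, 0.02), "unchanged")
  expect_identical(classify_events(0.5, 1e-9), "unchanged")
  expect_identical(classify_events(1.5, 0.001), "distal")
  expect_identical(classify_events(c(NA, 2), c(0.001, NA)),
                   c("unchanged", "unchanged"))
})

test_that("control selection picks non-significant genes nearest zero", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    apa_score = c(0.01, -0.5, 0.02, 1.8),
                    class = c("unchanged", "unchanged", "unchanged", "distal"),
                    stringsAsFactors = FALSE)
  expect_identical(select_unaffected_controls(res, 2), c("g1", "g3"))
  expect_identical(select_unaffected_controls(res, 3), c("g1", "g3", "g2"))
  expect_identical(select_unaffected_controls(res, 0), character(0))
  expect_error(select_unaffected_controls(res, 4), "only 3")
})

test_that("overlap enrichment returns the sample odds ratio and exact tail", {
  U <- sprintf("u%03d", 1:100)
  A <- U[1:20]; B <- U[11:30]  # overlap 10
  r <- overlap_enrichment(A, B, U)
  expect_equal(r$odds_ratio, 7.0)
  expect_equal(r$p_value, oracle_hyper_tail(10, 20, 20, 100),
               tolerance = 1e-12)
  # overlap at the expectation with OR ~ 1 is unremarkable
  A2 <- U[1:20]; B2 <- c(U[1:4], U[21:36])  # overlap 4 = 20*20/100
  expect_gt(overlap_enrichment(A2, B2, U)$p_value, 0.4)
  # A subset of B: minimal p for the margins
  r3 <- overlap_enrichment(U[1:5], U[1:50], U)
  expect_equal(r3$p_value, oracle_hyper_tail(5, 5, 50, 100),
               tolerance = 1e-12)
  expect_error(overlap_enrichment(A, B, character(0)), "empty universe")
})

test_that("fit object methods print, summarize, and expose coefficients", {
  sim <- simulate_apa_counts(simulation_config(n_genes = 30, seed = 2,
                                               frac_shifted = 0.3))
  fit <- apa_fit(sim$counts)
  expect_output(print(fit), "eligible genes")
  expect_output(summary(fit), "Size factors")
  cf <- coef(fit)
  expect_identical(names(cf), fit$results$gene_id)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
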