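test_that("coverage filter keeps comparisons where either allele reaches the threshold", {
  expect_true(coverage_filter(12, 0))
  expect_false(coverage_filter(9, 9))
  expect_true(coverage_filter(10, 3))  # boundary inclusive: "met or exceeded"
  expect_equal(coverage_filter(c(12, 9, 10), c(0, 9, 3)), c(TRUE, FALSE, TRUE))
})

test_that("aeFC is the difference of log2 allele expression values", {
  expect_equal(compute_aefc(40, 10), 2)
  expect_equal(compute_aefc(7, 7), 0)
  expect_equal(compute_aefc(16, 0), Inf)
  expect_equal(compute_aefc(0, 16), -Inf)
  expect_true(is.na(compute_aefc(0, 0)))
  expect_equal(compute_aefc(16, 0, pseudocount = 1), log2(17))
})

test_that("binomial_test implements the minimum-likelihood two-sided p", {
  expect_equal(binomial_test(10, 20), 1)                  # modal outcome
  expect_equal(binomial_test(0, 10), 0.001953125)          # 2 * 0.5^10
  expect_equal(binomial_test(30, 40), oracle_binom(30, 40), tolerance = 1e-12)
  expect_error(binomial_test(1, 0), "n must be")
  # cross-check against the mature implementation on a scattered grid
  for (n in c(5, 17, 33, 58)) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n))) {
      expect_equal(binomial_test(k, n),
                   stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("binomial k <-> n-k symmetry and aeFC antisymmetry hold", {
  set.seed(3)
  k <- sample(0:50, 40, replace = TRUE)
  n <- k + sample(0:50, 40, replace = TRUE)
  n[n == 0] <- 1
  expect_equal(binomial_test(k, n), binomial_test(n - k, n), tolerance = 1e-14)
  e1 <- sample(1:500, 40)
  e2 <- sample(1:500, 40)
  expect_equal(compute_aefc(e1, e2), -compute_aefc(e2, e1))
})

test_that("bh_adjust matches the naive step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    if (runif(1) < 0.3) p[sample(length(p), 1)] <- p[1]  # inject ties
    adj <- bh_adjust(p)
    expect_identical(adj, oracle_bh(p))
    expect_identical(adj, unname(stats::p.adjust(p, "BH")))
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust respects family grouping", {
  p <- c(0.01, 0.04, 0.02, 0.03)
  fam <- c("a", "a", "b", "b")
  within <- bh_adjust(p, fam)
  expect_equal(within[1:2], oracle_bh(p[1:2]))
  expect_equal(within[3:4], oracle_bh(p[3:4]))
  expect_false(identical(within, bh_adjust(p)))
})

test_that("call_ase applies the pipeline in fixed order", {
  res <- call_ase(ae_frame(200, 20))
  expect_equal(res$aefc, log2(10), tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$favored, "h1")
  expect_equal(res$p_adj, res$p_raw)  # singleton family

  res2 <- call_ase(ae_frame(30, 25))
  expect_false(res2$significant)     # |aeFC| ~ 0.26 < 2

  # coverage-filtered comparisons never reach testing
  res3 <- call_ase(ae_frame(c(9, 200), c(9, 20)))
  expect_equal(nrow(res3), 1)
  expect_equal(attr(res3, "n_filtered"), 1L)

  # infinite aeFC passes the fold-change criterion
  res4 <- call_ase(ae_frame(50, 0))
  expect_true(res4$significant)
  expect_equal(res4$favored, "h1")
})

test_that("raising thresholds never gains significant calls", {
  set.seed(21)
  ae <- ae_frame(rnbinom(300, mu = 80, size = 2) + 1L,
                 rnbinom(300, mu = 40, size = 2) + 1L)
  base <- call_ase(ae, significance_config())
  stricter_fc <- call_ase(ae, significance_config(aefc_threshold = 3))
  stricter_a <- call_ase(ae, significance_config(alpha = 0.01))
  expect_true(all(stricter_fc$significant <= base$significant))
  expect_true(all(stricter_a$significant <= base$significant))
})

test_that("type-I error is controlled on balanced comparisons", {
  set.seed(5)
  m <- 1000
  depth <- rnbinom(m, mu = 100, size = 2)
  depth[depth < 1] <- 1
  k <- rbinom(m, depth, 0.5)
  res <- call_ase(ae_frame(k, depth - k))
  frac <- sum(res$significant) / m
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 / m))
})

test_that("imbalance clearly above the fold-change threshold is recovered", {
  # allele fraction 0.9 (true aeFC = log2(9) ~ 3.17, comfortably past 2)
  set.seed(6)
  m <- 400
  depth <- rnbinom(m, mu = 200, size = 2)
  depth[depth < 50] <- 50
  k <- rbinom(m, depth, 0.9)
  res <- call_ase(ae_frame(k, depth - k))
  expect_gte(mean(res$significant), 0.95)
})

test_that("tissue_summary computes half-up percentages", {
  res <- data.frame(
    tissue = rep(c("liver", "heart"), c(3404, 3031)),
    significant = c(rep(c(TRUE, FALSE), c(135, 3404 - 135)),
                    rep(c(TRUE, FALSE), c(62, 3031 - 62)))
  )
  s <- tissue_summary(res)
  expect_equal(s$percent[s$tissue == "liver"], 3.97)
  expect_equal(s$percent[s$tissue == "heart"], 2.05)
  s0 <- tissue_summary(data.frame(tissue = "lung", significant = FALSE))
  expect_equal(s0$percent, 0)
})
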