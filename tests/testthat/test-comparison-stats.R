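# Bland-Altman, percent differences, B1+ RMSE, report round trip,
# uncertainty comparison.

test_that("bland_altman hand arithmetic and degenerate cases", {
  ba <- bland_altman(c(1, 3, 5), c(2, 3, 3))
  expect_equal(ba$mean_diff, 1 / 3)
  expect_equal(ba$points$diff, c(-1, 0, 2))
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  bac <- bland_altman(c(1, 2), c(1.5, 2.5))
  expect_equal(bac$mean_diff, -0.5)
  expect_equal(bac$sd_diff, 0)
  expect_error(bland_altman(1, 1), "pairs")
  # k = 1.96 widens the lines accordingly
  ba2 <- bland_altman(c(1, 3, 5), c(2, 3, 3), k = 1.96)
  expect_equal(unname(diff(ba2$lines)), 2 * 1.96 * ba$sd_diff)
})

test_that("percent_diff_summary conventions and invariances", {
  b <- c(2, 4, 8)
  expect_equal(percent_diff_summary(b, b)$mean_abs_pct, 0)
  p <- percent_diff_summary(1.1 * b, b)
  expect_equal(p$mean_abs_pct, 10, tolerance = 1e-12)
  expect_equal(p$full_range_pct, 10, tolerance = 1e-12)
  expect_error(percent_diff_summary(b, c(1, 0, 1)), "reference")
  # percentile monotonicity and permutation invariance
  set.seed(2)
  a <- runif(500, 1, 3)
  bb <- runif(500, 1, 3)
  s <- percent_diff_summary(a, bb)
  expect_lte(s$p95_pct, s$p99_pct)
  expect_lte(s$p99_pct, s$full_range_pct)
  o <- sample(500)
  s2 <- percent_diff_summary(a[o], bb[o])
  expect_equal(s2[1:4], s[1:4])
  # asymmetric in (a, b) under the target convention
  expect_false(isTRUE(all.equal(percent_diff_summary(a, bb)$mean_abs_pct,
                                percent_diff_summary(bb, a)$mean_abs_pct)))
})

test_that("p99 of a known lognormal ratio matches the analytic quantile", {
  sigma <- 0.15
  set.seed(77)
  b <- exp(rnorm(5000, 1, 0.3))
  a <- b * exp(rnorm(5000, 0, sigma))
  p <- percent_diff_summary(a, b)
  q_true <- oracle_lognormal_pct_quantile(0.99, sigma)
  # Monte-Carlo tolerance at n = 5000 (~4% of the quantile at p99)
  expect_lt(abs(p$p99_pct / q_true - 1), 0.08)
})

test_that("b1_rmse basics", {
  a <- array(complex(real = 1:8), c(2, 2, 2))
  expect_equal(b1_rmse(a, a, array(TRUE, c(2, 2, 2))), 0)
  expect_equal(b1_rmse(a + 1, a, array(TRUE, c(2, 2, 2))), 1)
  expect_error(b1_rmse(a, a, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("comparison report round-trips losslessly", {
  set.seed(5)
  a <- runif(50, 1, 4)
  b <- runif(50, 1, 4)
  rep <- comparison_report(a, b, extras = list(b1_rmse_uT = 1.25))
  stem <- tempfile()
  write_comparison_report(rep, stem)
  rep2 <- read_comparison_report(stem)
  for (k in c("mean_abs_diff", "mean_abs_pct", "p95_pct", "p99_pct",
              "full_range_pct"))
    expect_equal(rep2[[k]], rep[[k]], tolerance = 1e-12)
  expect_equal(rep2$bland_altman$mean_diff, rep$bland_altman$mean_diff,
               tolerance = 1e-12)
})

test_that("uncertainty comparison: identical variants and sigma linearity", {
  q <- fx_qset()
  shims <- generate_shims(60, 8, 5, seed = 13)
  r0 <- uncertainty_comparison(q, q, shims)
  expect_equal(r0$mean_abs_diff, 0)
  expect_equal(r0$mean_abs_pct, 0)
  expect_true(isTRUE(r0$morphometry_identical))
  # sigma x 1.1 with fields held fixed: Q scales by 1.1 exactly -> 10%
  q11 <- q
  q11$pack <- q$pack * 1.1
  q11$eigmax <- q$eigmax * 1.1
  r1 <- uncertainty_comparison(q11, q, shims)
  expect_equal(r1$pairs$a / r1$pairs$b, rep(1.1, 60), tolerance = 1e-9)
  expect_equal(r1$mean_abs_pct, 10, tolerance = 1e-6)
})
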