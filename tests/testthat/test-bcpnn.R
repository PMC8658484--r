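# Frozen 50-digit arbitrary-precision evaluations of the IC expectation
# and variance, computed with an independent transcription of the formulas
# (mpmath, dps = 50).
frozen_oracle <- data.frame(
  n11 = c(5, 0, 1, 0, 86),
  n1p = c(10, 10, 1, 0, 771),
  np1 = c(10, 50, 1, 0, 10802),
  npp = c(100, 1000, 2, 1, 534287),
  e = c(1.471919347349447560323, -0.6404013274864041211598,
        0.4150374992788438185463, -0.1520030934450499849628,
        2.38902291060851500646),
  v = c(0.6682500217674968589773, 2.305524210410941445991,
        1.427224444118131061396, 3.784307238192014177945,
        0.02680102133482347893252))

test_that("expectation and variance match frozen high-precision values", {
  e <- expectation_ic(frozen_oracle$n11, frozen_oracle$n1p,
                      frozen_oracle$np1, frozen_oracle$npp)
  v <- variance_ic(frozen_oracle$n11, frozen_oracle$n1p,
                   frozen_oracle$np1, frozen_oracle$npp)
  expect_equal(e, frozen_oracle$e, tolerance = 1e-12)
  expect_equal(v, frozen_oracle$v, tolerance = 1e-12)
})

test_that("log-space implementation equals the plain-ratio transcription
           on a grid of random small tables", {
  set.seed(2024)
  for (i in 1:100) {
    npp <- sample(20:5000, 1)
    n1p <- sample(0:(npp %/% 2), 1)
    np1 <- sample(0:(npp %/% 2), 1)
    n11 <- sample(0:min(n1p, np1), 1)
    expect_equal(expectation_ic(n11, n1p, np1, npp),
                 oracle_eic(n11, n1p, np1, npp), tolerance = 1e-10)
    expect_equal(variance_ic(n11, n1p, np1, npp),
                 oracle_vic(n11, n1p, np1, npp), tolerance = 1e-10)
  }
})

test_that("IC is strictly increasing in n11 with margins fixed", {
  e <- expectation_ic(0:50, 100, 200, 10000)
  expect_true(all(diff(e) > 0))
})

test_that("shrinkage is bounded and vanishes as counts scale up", {
  # |E(IC)| within half a bit of the crude log ratio on large databases
  set.seed(99)
  for (i in 1:20) {
    npp <- sample(10000:1000000, 1)
    n1p <- sample(10:2000, 1)
    np1 <- sample(10:20000, 1)
    n11 <- sample(1:min(n1p, np1), 1)
    crude <- log2(n11 * npp / (n1p * np1))
    e <- expectation_ic(n11, n1p, np1, npp)
    expect_lte(abs(e), abs(crude) + 0.5)
  }
  # proportional upscaling converges to the crude ratio
  crude <- log2(8 * 1000 / (40 * 50))
  err <- vapply(c(10, 100, 1000), function(k)
    abs(expectation_ic(8 * k, 40 * k, 50 * k, 1000 * k) - crude),
    numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("independent tables score near zero", {
  # n11 * npp = n1p * np1 exactly, n11 >= 100
  for (n11 in c(100, 400)) {
    n1p <- 10 * n11; np1 <- 100 * n11; npp <- 1000 * n11
    expect_lt(abs(expectation_ic(n11, n1p, np1, npp)), 0.05)
  }
})

test_that("zero-count and prior-only tables stay finite", {
  e <- expectation_ic(0, 10, 10802, 534287)
  v <- variance_ic(0, 10, 10802, 534287)
  expect_true(is.finite(e) && is.finite(v) && v > 0)
  # the degenerate prior-only table
  f <- score_counts(0, 0, 0, 1)
  expect_true(all(is.finite(c(f$e_ic, f$v_ic, f$ic025, f$ic975))))
})

test_that("credible interval is E +- 2 sd and symmetric", {
  ci <- credible_interval(1.5, 0.25)
  expect_equal(unname(ci[1, ]), c(0.5, 2.5))
  ci0 <- credible_interval(0.7, 0)
  expect_equal(unname(ci0[1, 1]), unname(ci0[1, 2]))
  expect_error(credible_interval(0, -1), "non-negative")
  set.seed(3)
  e <- rnorm(20); v <- rexp(20)
  ci <- credible_interval(e, v)
  expect_equal(ci[, "ic975"] - e, e - ci[, "ic025"])
})

test_that("variance strictly decreases when the table is doubled", {
  v1 <- variance_ic(20, 100, 200, 10000)
  v2 <- variance_ic(40, 200, 400, 20000)
  expect_lt(v2, v1)
})

test_that("classification follows the credible bounds", {
  expect_equal(classify_ic(2.19, 2.65), "signal")
  expect_equal(classify_ic(-0.75, -0.17), "inverse")
  expect_equal(classify_ic(-0.10, 2.20), "none")
  expect_equal(classify_ic(0, 1), "none")  # bound must strictly exceed 0
  expect_error(classify_ic(1, 0), "exceed")
})

test_that("invalid counts are rejected", {
  expect_error(expectation_ic(5, 3, 10, 100), "margin")
  expect_error(expectation_ic(-1, 3, 10, 100), "non-negative")
  expect_error(expectation_ic(1, 3, 10, 0), "non-negative")
  expect_error(bcpnn_prior(gamma11 = 0), "positive")
})

test_that("ROR matches hand arithmetic and flags zero cells", {
  expect_equal(ror(10, 90, 100, 900)$ror, 1.0)
  r <- ror(20, 80, 100, 900)
  expect_equal(r$ror, 2.25)
  expect_true(r$ci_low < 2.25 && 2.25 < r$ci_high)
  rz <- ror(0, 80, 100, 900)
  expect_equal(rz$ror, 0)
  expect_true(is.na(rz$ci_low) && is.na(rz$ci_high))
  expect_true(is.na(ror(5, 0, 100, 900)$ror))
})

test_that("bcpnn objects carry coef/confint/summary methods", {
  fit <- bcpnn(c(a = 86, b = 26), n1plus = c(771, 2131), nplus1 = 10802,
               nplusplus = 534287)
  expect_s3_class(fit, "bcpnn")
  expect_named(coef(fit), c("a", "b"))
  ci <- confint(fit)
  expect_equal(rownames(ci), c("a", "b"))
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_equal(fit$classification, c("signal", "inverse"))
  expect_output(print(fit), "86")
  expect_output(summary(fit), "signals")
})

test_that("margin calibration recovers a known event margin", {
  # rows generated from a known margin are recovered exactly
  true_np1 <- 700
  e <- expectation_ic(c(12, 3, 0), c(60, 40, 15), true_np1, 20000)
  cal <- calibrate_margin(c(12, 3, 0), c(60, 40, 15), e, 20000,
                          search_range = c(1, 5000))
  expect_equal(cal$nplus1, true_np1)
  expect_lt(cal$rms, 1e-8)
  # a boundary minimum warns
  expect_warning(
    calibrate_margin(c(12, 3, 0), c(60, 40, 15), e, 20000,
                     search_range = c(1, 300)),
    "boundary")
  # rounding the published values to 2 decimals still recovers the margin
  # closely at reference scale
  e2 <- round(expectation_ic(c(86, 48, 17), c(771, 291, 133), 10802,
                             534287), 2)
  cal2 <- calibrate_margin(c(86, 48, 17), c(771, 291, 133), e2, 534287)
  expect_lt(abs(cal2$nplus1 - 10802) / 10802, 0.02)
})

test_that("calibration at 1/10 scale recovers the generator margin within 1", {
  true_np1 <- 1080
  npp <- 53429
  n11 <- c(18, 9, 5, 2, 35)
  n1p <- c(150, 60, 30, 12, 220)
  e <- expectation_ic(n11, n1p, true_np1, npp)
  cal <- calibrate_margin(n11, n1p, e, npp, search_range = c(1, 10000))
  expect_lte(abs(cal$nplus1 - true_np1), 1)
})
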