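test_that("perfect and offset agreement give ICC 1", {
  m <- cbind(1:3, 1:3)
  r <- icc_consistency(m)
  expect_equal(r$icc, 1)
  # a constant offset is invisible to the consistency form
  r2 <- icc_consistency(cbind(1:3, 2:4))
  expect_equal(r2$icc, 1)
})

test_that("ICC is invariant to column shifts and column order", {
  set.seed(31)
  m <- cbind(rnorm(40, 10, 2), rnorm(40, 10, 2))
  r0 <- icc_consistency(m)
  r_shift <- icc_consistency(cbind(m[, 1], m[, 2] + 137))
  expect_equal(r_shift$icc, r0$icc, tolerance = 1e-12)
  r_swap <- icc_consistency(m[, 2:1])
  expect_equal(r_swap$icc, r0$icc, tolerance = 1e-12)
  expect_true(r0$ci_low <= r0$icc && r0$icc <= r0$ci_high)
})

test_that("ICC, CI and F-test match the ANOVA oracle on seeded matrices", {
  set.seed(1234)
  for (i in 1:20) {
    subj <- rnorm(50, 0, 1)
    m <- cbind(subj + rnorm(50, 0, 0.5), subj + rnorm(50, 0, 0.5))
    mine <- icc_consistency(m)
    oracle <- icc_aov_oracle(m)
    expect_equal(mine$icc, oracle$icc, tolerance = 1e-10)
    expect_equal(mine$ci_low, oracle$ci_low, tolerance = 1e-10)
    expect_equal(mine$ci_high, oracle$ci_high, tolerance = 1e-10)
    expect_equal(mine$f_stat, oracle$f, tolerance = 1e-10)
    expect_equal(mine$f_pvalue, oracle$p, tolerance = 1e-10)
  }
})

test_that("ICC estimate converges to the variance-ratio truth", {
  set.seed(77)
  n <- 2000
  sigma_s <- 1; sigma_e <- 0.5
  subj <- rnorm(n, 0, sigma_s)
  m <- cbind(subj + rnorm(n, 0, sigma_e), subj + rnorm(n, 0, sigma_e))
  truth <- sigma_s^2 / (sigma_s^2 + sigma_e^2)  # 0.8
  r <- icc_consistency(m)
  expect_lt(abs(r$icc - truth), 0.03)
})

test_that("identical data is flagged degenerate rather than ICC 1", {
  r <- icc_consistency(cbind(rep(5, 4), rep(5, 4)))
  expect_identical(r$status, "degenerate")
  expect_true(is.na(r$icc))
})

test_that("agreement form penalizes a fixed offset, consistency does not", {
  set.seed(55)
  a <- rnorm(60, 100, 15)
  m <- cbind(a, a + 20 + rnorm(60, 0, 2))
  cons <- icc_consistency(m, type = "consistency")
  agr <- icc_consistency(m, type = "agreement")
  expect_gt(cons$icc, 0.97)
  expect_lt(agr$icc, cons$icc - 0.2)
})

test_that("reliability labels follow the lower CI bound", {
  expect_identical(adipoquant:::.reliability_label(0.95), "excellent")
  expect_identical(adipoquant:::.reliability_label(0.80), "good")
  expect_identical(adipoquant:::.reliability_label(0.60), "moderate")
  expect_identical(adipoquant:::.reliability_label(0.20), "poor")
})

test_that("Bland-Altman statistics and sign convention", {
  pm0 <- paired_measurements(1:5, c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  ba0 <- bland_altman(pm0)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  # B higher than A by 13.7 everywhere: differences are A - B
  a <- c(4000, 4500, 5000, 5500)
  pm <- paired_measurements(1:4, a, a + 13.7)
  ba <- bland_altman(pm)
  expect_equal(ba$mean_diff, -13.7)
  expect_equal(ba$sd_diff, 0)
  expect_identical(nrow(ba$points), 4L)
})

test_that("about 95% of differences fall inside the limits of agreement", {
  set.seed(404)
  n <- 1e4
  a <- rnorm(n, 50, 5); b <- a + rnorm(n, 1, 2)
  ba <- bland_altman(paired_measurements(seq_len(n), a, b))
  inside <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("paired regression matches the normal-equation oracle", {
  set.seed(12)
  a <- rnorm(40, 10, 3); b <- 2 + 0.9 * a + rnorm(40, 0, 0.5)
  pm <- paired_measurements(1:40, a, b)
  r <- paired_regression(pm)
  X <- cbind(1, a)
  beta <- solve(t(X) %*% X, t(X) %*% b)
  expect_equal(r$intercept, beta[1], tolerance = 1e-12)
  expect_equal(r$slope, beta[2], tolerance = 1e-12)
  expect_equal(r$r, cor(a, b), tolerance = 1e-12)
  # identities
  ident <- paired_regression(paired_measurements(1:5, 1:5, 1:5))
  expect_equal(ident$slope, 1); expect_equal(ident$intercept, 0)
  expect_equal(ident$r, 1)
  neg <- paired_regression(paired_measurements(1:5, 1:5, -(1:5)))
  expect_equal(neg$r, -1)
  expect_error(paired_regression(paired_measurements(1:5, rep(3, 5), 1:5)),
               "variance")
})

test_that("rows with missing values are dropped and counted", {
  pm <- paired_measurements(1:5, c(1, 2, NA, 4, 5), c(1, 2, 3, NA, 5))
  expect_identical(length(pm$method_a), 3L)
  expect_identical(pm$n_dropped, 2L)
  expect_error(paired_measurements(1:2, c(NA, 1), c(1, 2)), "at least 2")
})

test_that("CSV round trip works in wide and long layouts", {
  wide <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = 1:4, a_value = c(1, 2, 3, 4),
                       b_value = c(1.1, 2.2, 2.9, 4.3)), wide,
            row.names = FALSE)
  pm <- read_paired_csv(wide)
  expect_identical(length(pm$method_a), 4L)
  long <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = rep(1:3, 2),
                       method = rep(c("imageJ", "qupath"), each = 3),
                       variable = "area",
                       value = c(10, 20, 30, 11, 19, 33)), long,
            row.names = FALSE)
  pm2 <- read_paired_csv(long)
  expect_identical(pm2$variable_name, "area")
  expect_equal(pm2$method_a, c(10, 20, 30))
  res <- agreement_analysis(pm2)
  out <- withr::local_tempfile(fileext = ".csv")
  write_agreement_csv(res, out)
  back <- read.csv(out)
  expect_equal(back$icc, res$icc$icc, tolerance = 1e-8)
})
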