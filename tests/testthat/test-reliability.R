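test_that("the between-session CV reproduces the worked example", {
  expect_equal(round(cv_between_sessions(11.5, 10.8), 2), 4.44)
  expect_equal(cv_between_sessions(7.3, 7.3), 0)
  # hand-computed |delta|/sqrt(2) / mean * 100 for (5, 6)
  expect_equal(round(cv_between_sessions(5, 6), 2), 12.86)
  expect_true(is.nan(cv_between_sessions(2, -2)))
})

test_that("the CV is symmetric in its arguments and scale-invariant", {
  set.seed(11)
  x <- runif(50, 1, 30); y <- runif(50, 1, 30)
  expect_equal(cv_between_sessions(x, y), cv_between_sessions(y, x))
  expect_equal(cv_between_sessions(10 * x, 10 * y), cv_between_sessions(x, y),
               tolerance = 1e-12)
})

test_that("per-level mean CV averages the per-trial CVs", {
  lvl <- rep(10, 3)
  cvs <- c(2, 4, 6)
  d <- cvs / 100 * 10 * sqrt(2)          # build pairs with those exact CVs
  dat <- session_pair_data(lvl, 10 + d / 2, 10 - d / 2)
  expect_equal(as.numeric(mean_cv(dat, 10)), 4, tolerance = 1e-12)

  one <- session_pair_data(5, 5.2, 5.0)
  expect_equal(as.numeric(mean_cv(one, 5)),
               cv_between_sessions(5.2, 5.0))

  same <- session_pair_data(rep(5, 4), rep(5.1, 4), rep(5.1, 4))
  expect_equal(as.numeric(mean_cv(same, 5)), 0)

  # undefined CVs at the zero level are skipped and counted
  z <- session_pair_data(rep(0, 3), c(0.1, -0.1, 0.2), c(-0.1, 0.1, 0.3))
  m <- mean_cv(z, 0)
  expect_equal(attr(m, "n_skipped"), 2)
})

test_that("ICC(2,1) matches an independent ANOVA computation", {
  # oracle: variance components from stats::aov on the long-format data
  icc_oracle <- function(mat) {
    n <- nrow(mat); k <- ncol(mat)
    df <- data.frame(y = as.numeric(mat),
                     trial = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ trial + session, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(rnorm(20, 10, 3), 10, 2)
    expect_equal(icc_2_1(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC(2,1) is perfect for identical sessions and penalizes bias", {
  s1 <- c(1, 5, 9, 14, 20, 3)
  perfect <- icc_2_1(cbind(s1, s1))
  expect_equal(perfect$icc, 1)
  expect_true(perfect$ci_low <= perfect$icc && perfect$icc <= perfect$ci_high)
  biased <- icc_2_1(cbind(s1, s1 + 5))
  expect_lt(biased$icc, perfect$icc)
  expect_true(icc_2_1(matrix(2, 5, 2))$undefined)
  expect_error(icc_2_1(matrix(1:4, 2, 2)), class = "mrikin_data_error")
})

test_that("Bland-Altman limits and heteroscedasticity classification", {
  d0 <- session_pair_data(1:5, c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  ba0 <- bland_altman(d0)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$scedasticity, "degenerate")

  d1 <- session_pair_data(1:4, c(2, 3, 4, 5), c(1, 2, 3, 4))
  ba1 <- bland_altman(d1)
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)

  # Monte-Carlo: with differences independent of means, the limits contain
  # 95% of differences and R^2 stays near zero
  set.seed(31)
  n <- 1e5
  m <- runif(n, 5, 25)
  diff <- rnorm(n, 0, 0.6)
  dd <- session_pair_data(rep(1, n), m + diff / 2, m - diff / 2)
  ba <- bland_altman(dd)
  inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.011)
  expect_lt(ba$r_squared, 0.01)
  expect_equal(ba$scedasticity, "homo")

  # error growing with magnitude flips the classification at R^2 > 0.1
  diff_h <- rnorm(n, 0, 0.05) * m
  dh <- session_pair_data(rep(1, n), m + diff_h / 2, m - diff_h / 2)
  expect_equal(bland_altman(dh)$scedasticity, "hetero")

  expect_error(bland_altman(session_pair_data(1, 1, 1)),
               class = "mrikin_data_error")
})

test_that("ratio LOA reproduces its formula symbol for symbol", {
  d <- session_pair_data(1:3, c(10, 20, 30), c(9, 19, 29))
  r <- ratio_loa(d)
  # direct hand evaluation: SDdiffs = sd(c(1,1,1)) = 0, AVGmeans = 19.5
  expect_equal(r$sd_diff, 0)
  expect_equal(r$avg_means, 19.5)
  expect_equal(r$ratio_loa, 0)
  expect_equal(r$bias, 1)

  set.seed(41)
  s1 <- runif(10, 5, 25); s2 <- s1 + rnorm(10, 0.2, 0.5)
  d2 <- session_pair_data(rep(1, 10), s1, s2)
  r2 <- ratio_loa(d2)
  # the quoted formula, evaluated independently (pins the 1.96 and 100)
  expect_equal(r2$ratio_loa,
               (sd(s1 - s2) / mean((s1 + s2) / 2)) * 1.96 * 100,
               tolerance = 1e-12)
  # scale invariance of the ratio
  d3 <- session_pair_data(rep(1, 10), 10 * s1, 10 * s2)
  expect_equal(ratio_loa(d3)$ratio_loa, r2$ratio_loa, tolerance = 1e-12)

  ident <- session_pair_data(1:3, c(1, 2, 3), c(1, 2, 3))
  expect_equal(ratio_loa(ident)$ratio_loa, 0)
})

test_that("t-tests match the closed formula and its symmetries", {
  x <- c(12.1, 10.4, 11.8, 13.0, 9.9, 11.1)
  y <- c(11.5, 10.9, 11.2, 12.1, 10.6, 11.4)
  tt <- paired_t(x, y, "paired")
  d <- x - y
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), length(d) - 1), tolerance = 1e-12)
  flip <- paired_t(y, x, "paired")
  expect_equal(flip$t, -tt$t, tolerance = 1e-12)
  expect_equal(flip$p, tt$p, tolerance = 1e-12)

  ti <- paired_t(x, y, "independent")
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  expect_equal(ti$t, (mean(x) - mean(y)) / (sp * sqrt(2 / length(x))),
               tolerance = 1e-12)

  degen <- paired_t(x, x, "paired")
  expect_equal(degen$t, 0)
  expect_true(degen$degenerate)
})

test_that("the assembled reliability report has the study layout", {
  lvls <- rep(seq(0, 20, 5), each = 7)
  noiseless <- simulate_session_pair(lvls, rater_sigma = 0, seed = 1)
  rep0 <- reliability_report(session_pair_data(lvls, noiseless$session1,
                                               noiseless$session2))
  expect_equal(nrow(rep0$per_level), 5)  # one row per distinct level
  expect_equal(rep0$icc$icc, 1)
  expect_equal(rep0$overall_cv, 0)

  noisy <- simulate_session_pair(lvls, rater_sigma = 0.4, seed = 2)
  rep1 <- reliability_report(session_pair_data(lvls, noisy$session1,
                                               noisy$session2))
  expect_true(rep1$icc$icc > 0.9 && rep1$icc$icc <= 1)
  expect_true(all(rep1$per_level$mean_cv >= 0, na.rm = TRUE))
  out <- capture.output(print(rep1))
  expect_true(any(grepl("Overall mean CV", out)))
  f <- tempfile(fileext = ".csv")
  reliability_write_csv(rep1, f)
  expect_equal(nrow(read.csv(f)), 5)
})
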