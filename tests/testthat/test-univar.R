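test_that("pooled t-test matches hand computation and trivial cases", {
  r <- ttest_raw(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3.6742, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_raw, 0.02131, tolerance = 1e-3)
  same <- ttest_raw(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_raw, 1)
  expect_error(ttest_raw(c(1, 1), c(1, 1)), "variance")
  expect_error(ttest_raw(1, c(1, 2)), "n >= 2")
})

test_that("summary-statistics mode is exact and verifies printed rows", {
  # tryptophan region: strongly decreased in cases
  r <- ttest_summary(0.70, 0.32, 7, 1.94, 0.41, 7)
  expect_equal(r$t_stat, -6.307, tolerance = 1e-3)
  expect_equal(r$df, 12)
  expect_lt(r$p_raw, 0.001)
  # consistency with the raw-data route
  set.seed(81)
  for (i in 1:5) {
    a <- rnorm(6, 2); b <- rnorm(9, 2.5)
    raw <- ttest_raw(a, b)
    mom <- ttest_summary(mean(a), sd(a), 6, mean(b), sd(b), 9)
    expect_equal(raw$t_stat, mom$t_stat, tolerance = 1e-12)
    expect_equal(raw$df, mom$df)
    expect_equal(raw$p_raw, mom$p_raw, tolerance = 1e-12)
  }
  expect_equal(ttest_summary(3, 1, 5, 3, 1, 5)$t_stat, 0)
  # Welch variant agrees with stats::t.test
  w1 <- ttest_raw(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  w2 <- ttest_summary(mean(c(1, 2, 3, 9)), sd(c(1, 2, 3, 9)), 4,
                      mean(c(4, 5, 6)), sd(c(4, 5, 6)), 3, welch = TRUE)
  expect_equal(w1$t_stat, w2$t_stat, tolerance = 1e-12)
  expect_equal(w1$df, w2$df, tolerance = 1e-10)
})

test_that("null p-values are uniform (calibration)", {
  set.seed(82)
  p <- replicate(2000, ttest_raw(rnorm(7), rnorm(7))$p_raw)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.012)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(83)
  for (m in c(2, 10, 137, 1000)) {
    p <- runif(m)^2
    a <- bh_adjust(p)
    expect_equal(a, bh_bruteforce(p))
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
    # monotone: adjusted ranks respect raw ranks
    expect_true(all(diff(a[order(p)]) >= 0))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("percent change reproduces the printed table values", {
  expect_equal(round(percent_change(21.95, 30.95), 1), -29.1)
  expect_equal(round(percent_change(5.84, 3.65), 1), 60.0)
  expect_equal(percent_change(4, 4), 0)
  # scale invariance
  expect_equal(percent_change(21.95 * 13, 30.95 * 13),
               percent_change(21.95, 30.95))
  expect_error(percent_change(1, 0), "zero control")
})

test_that("three-criterion selection is a strict conjunction", {
  u <- data.frame(var_id = 1:3, p_adj = c(0.004, 0.20, 0.004),
                  p_raw = c(0.001, 0.1, 0.001),
                  mean_case = 1, sd_case = 1, mean_control = 2,
                  sd_control = 1, t_stat = -1, df = 12,
                  pct_change = -50, direction = "down")
  s <- data.frame(variable = paste0("var_", 1:3),
                  p_ctr = c(1, 2, 0.5),
                  p_corr = c(0.890, 0.95, 0.3),
                  vip = c(2.07, 3, 2))
  out <- select_discriminators(u, s)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE))
  # raising any threshold never adds a selection
  for (args in list(list(alpha_adj = 0.01), list(pcorr_min = 0.9),
                    list(vip_min = 2.5))) {
    out2 <- do.call(select_discriminators, c(list(u = u, s = s), args))
    expect_true(all(out$selected | !out2$selected))
  }
  expect_error(select_discriminators(u, s[1:2, ]), "misaligned")
  expect_error(select_discriminators(u, s, alpha_adj = -1), "> 0")
})

test_that("univariate table wires tests, BH and direction together", {
  d <- generate_profiles(n_case = 7, n_control = 7, seed = 85)
  u <- univariate_table(d$profile)
  expect_equal(nrow(u), 110)
  expect_true(all(u$p_adj >= u$p_raw - 1e-15))
  expect_identical(u$direction, ifelse(u$pct_change >= 0, "up", "down"))
  # glucose region goes up in cases, olefinic lipid region goes down
  expect_gt(u$pct_change[u$var_id == 52], 0)
  expect_lt(u$pct_change[u$var_id == 18], 0)
  # consistency with the direct t-test
  j <- which(u$var_id == 18)
  g <- d$profile$meta$group
  r <- ttest_raw(d$profile$X[g == "case", j], d$profile$X[g == "control", j])
  expect_equal(u$t_stat[j], r$t_stat, tolerance = 1e-12)
})
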