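test_that("packaged default scheme has the published variable bookkeeping", {
  rt <- default_region_table()
  expect_equal(nrow(rt), 110)
  expect_equal(sum(rt$is_glucose), 15)
  expect_true(all(diff(rt$ppm_hi) < 0))
  # the published fatty-acid olefinic region sits at its printed index
  expect_equal(rt$ppm_hi[18], 5.4300)
  expect_equal(rt$ppm_lo[18], 5.2752)
  expect_false(rt$is_glucose[18])
  expect_true(all(rt$is_glucose[c(38, 41, 42, 43, 44, 51, 52, 54)]))
})

test_that("region validation rejects malformed tables naming the rows", {
  df <- data.frame(var_id = 1:2, ppm_hi = c(4.0, 3.5), ppm_lo = c(3.0, 2.5),
                   assignment = "x", is_glucose = FALSE)
  expect_error(region_table(df), "1")          # overlap names var_ids
  expect_error(region_table(df), "2")
  df2 <- data.frame(var_id = c(1, 1), ppm_hi = c(4, 2), ppm_lo = c(3, 1),
                    assignment = "x", is_glucose = FALSE)
  expect_error(region_table(df2), "duplicate")
  df3 <- data.frame(var_id = 1, ppm_hi = 2, ppm_lo = 3,
                    assignment = "x", is_glucose = FALSE)
  expect_error(region_table(df3), "ppm_hi")
  # row with bounds stated high-to-low is accepted and preserved
  df4 <- data.frame(var_id = 18, ppm_hi = 5.4300, ppm_lo = 5.2752,
                    assignment = "-HC=CH- in fatty acid chain",
                    is_glucose = FALSE)
  rt <- region_table(df4)
  expect_equal(rt$ppm_hi, 5.4300)
  expect_equal(rt$ppm_lo, 5.2752)
})

test_that("trapezoidal integration matches analytic areas", {
  rt1 <- region_table(data.frame(var_id = 1, ppm_hi = 5, ppm_lo = 4,
                                 assignment = "a", is_glucose = FALSE))
  expect_equal(unname(integrate_spectrum(make_flat_spectrum(), rt1)), 1.0,
               tolerance = 1e-9)
  # intensity equal to ppm: integral of x over [1,2] is 1.5
  ppm <- seq(6, 0.5, by = -0.001)
  s <- spectrum(ppm, ppm)
  rt2 <- region_table(data.frame(var_id = 1, ppm_hi = 2, ppm_lo = 1,
                                 assignment = "a", is_glucose = FALSE))
  expect_equal(unname(integrate_spectrum(s, rt2)), 1.5, tolerance = 1e-9)
  # triangle, base 3.4-3.6, height 2: area 0.5 * 0.2 * 2 = 0.2
  tri <- pmax(0, 2 * (1 - abs(ppm - 3.5) / 0.1))
  rt3 <- region_table(data.frame(var_id = 1, ppm_hi = 3.6, ppm_lo = 3.4,
                                 assignment = "a", is_glucose = FALSE))
  expect_equal(unname(integrate_spectrum(spectrum(ppm, tri), rt3)), 0.2,
               tolerance = 1e-6)
})

test_that("integration is linear, direction-invariant and grid-robust", {
  rt <- make_tiny_regions()
  ppm <- seq(6, 0.5, by = -0.001)
  set.seed(7)
  y1 <- abs(rnorm(length(ppm))); y2 <- abs(rnorm(length(ppm)))
  v1 <- integrate_spectrum(spectrum(ppm, y1), rt)
  v2 <- integrate_spectrum(spectrum(ppm, y2), rt)
  v12 <- integrate_spectrum(spectrum(ppm, 2 * y1 + 3 * y2), rt)
  expect_equal(v12, 2 * v1 + 3 * v2, tolerance = 1e-10)
  # ascending storage gives the same integrals
  v1r <- integrate_spectrum(spectrum(rev(ppm), rev(y1)), rt)
  expect_equal(v1, v1r, tolerance = 1e-12)
  # refining the grid 10x barely moves a piecewise-linear peak's integral
  coarse <- seq(6, 0.5, by = -0.01)
  tri_f <- function(x) pmax(0, 2 * (1 - abs(x - 3.5) / 0.1))
  fine <- seq(6, 0.5, by = -0.001)
  rt3 <- region_table(data.frame(var_id = 1, ppm_hi = 3.6, ppm_lo = 3.4,
                                 assignment = "a", is_glucose = FALSE))
  a <- integrate_spectrum(spectrum(coarse, tri_f(coarse)), rt3)
  b <- integrate_spectrum(spectrum(fine, tri_f(fine)), rt3)
  expect_lt(abs(a - b) / abs(b), 1e-6)
})

test_that("integration errors on uncovered regions and empty input", {
  rt <- region_table(data.frame(var_id = 9, ppm_hi = 11, ppm_lo = 10,
                                assignment = "a", is_glucose = FALSE))
  expect_error(integrate_spectrum(make_flat_spectrum(), rt), "9")
  expect_error(spectrum(numeric(0), numeric(0)), "empty")
  expect_error(bin_dataset(list(), make_tiny_regions()), "empty dataset")
})

test_that("bin_dataset stacks samples and propagates context", {
  rt <- make_tiny_regions()
  s <- make_flat_spectrum()
  pm <- bin_dataset(list(a = s, b = s), rt)
  expect_equal(dim(pm), c(2L, 4L))
  expect_equal(pm$X[1, ], pm$X[2, ])
  bad <- make_flat_spectrum(from = 3, to = 0.5)
  expect_error(bin_dataset(list(good = s, oops = bad), rt), "oops")
})

test_that("glucose exclusion drops exactly the flagged columns", {
  rt <- default_region_table()
  d <- generate_profiles(n_case = 3, n_control = 3, seed = 5)
  pm95 <- exclude_glucose(d$profile, rt)
  expect_equal(ncol(pm95$X), 95)
  expect_false(any(pm95$region_ids %in% rt$var_id[rt$is_glucose]))
  # no flags: identity
  rt0 <- make_tiny_regions()
  rt0$is_glucose <- FALSE
  pm <- profile_matrix(matrix(1:8, 2), region_ids = rt0$var_id)
  expect_equal(exclude_glucose(pm, rt0)$X, pm$X)
  # all flags: degenerate
  rt1 <- make_tiny_regions(); rt1$is_glucose <- TRUE
  pm2 <- profile_matrix(matrix(1:8, 2), region_ids = rt1$var_id)
  expect_error(exclude_glucose(pm2, rt1), "no variables remain")
})
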