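test_that("with no orthogonal components the fit equals the PLS1 oracle", {
  for (seed in 1:5) {
    f <- make_xy(n = 8, k = 5, seed = seed)
    m <- fit_oplsda(f$X, f$y, a_ortho = 0)
    o <- pls1_oracle(f$X, f$y)
    expect_equal(as.numeric(m$w), as.numeric(o$w), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(m$t_pred, o$t, tolerance = 1e-10)
    expect_equal(m$q, o$q, tolerance = 1e-10)
  }
})

test_that("a response leaked into X is modelled almost perfectly", {
  set.seed(20)
  y <- rep(c(1, -1), each = 6)
  X <- cbind(y + rnorm(12, sd = 1e-4),
             matrix(rnorm(12 * 4, sd = 0.05), 12, 4))
  m <- fit_oplsda(scale(X, scale = FALSE), y, a_ortho = 0)
  expect_gt(m$r2y_cum, 0.99)
})

test_that("orthogonal scores are uncorrelated with the predictive score", {
  d <- generate_profiles(n_case = 7, n_control = 7, seed = 31)
  p <- fit_scaling(d$profile$X)
  Xs <- apply_scaling(d$profile$X, p)
  m <- fit_oplsda(Xs, d$profile$meta$y, a_ortho = 2)
  for (o in 1:2)
    expect_lt(abs(cor(m$t_pred, m$T_o[, o])), 1e-8)
  expect_equal(sqrt(sum(m$w^2)), 1, tolerance = 1e-12)
  expect_true(m$r2y_cum >= 0 && m$r2y_cum <= 1)
})

test_that("flipping the label signs negates scores but not fit metrics", {
  d <- generate_profiles(n_case = 7, n_control = 7, seed = 32)
  p <- fit_scaling(d$profile$X)
  Xs <- apply_scaling(d$profile$X, p)
  y <- d$profile$meta$y
  m1 <- fit_oplsda(Xs, y, a_ortho = 1)
  m2 <- fit_oplsda(Xs, -y, a_ortho = 1)
  expect_equal(m2$t_pred, -m1$t_pred, tolerance = 1e-10)
  # q = y't/t't is even in the sign flip; fitted responses t*q negate
  expect_equal(m2$q, m1$q, tolerance = 1e-10)
  expect_equal(m2$t_pred * m2$q, -(m1$t_pred * m1$q), tolerance = 1e-10)
  expect_equal(m2$r2y_cum, m1$r2y_cum, tolerance = 1e-10)
  expect_equal(vip(m2), vip(m1), tolerance = 1e-10)
  s1 <- sline(m1, Xs); s2 <- sline(m2, Xs)
  expect_equal(s2$p_ctr, -s1$p_ctr, tolerance = 1e-10)
  expect_equal(s2$p_corr, -s1$p_corr, tolerance = 1e-10)
})

test_that("degenerate responses are rejected", {
  f <- make_xy()
  expect_error(fit_oplsda(f$X, rep(1, 8)), "single class")
  set.seed(33)
  X <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
  y <- rep(c(1, -1), 4)
  # make every column orthogonal to centered y
  Xo <- X - outer(y, as.numeric(crossprod(X, y)) / sum(y^2))
  expect_error(fit_oplsda(Xo, y), "no predictive direction")
})

test_that("S-line statistics equal their textbook definitions", {
  f <- make_xy(n = 10, k = 6, seed = 41)
  m <- fit_oplsda(f$X, f$y, a_ortho = 1)
  s <- sline(m, f$X)
  for (j in 1:6) {
    expect_equal(s$p_ctr[j], cov(m$t_pred, f$X[, j]), tolerance = 1e-12)
    expect_equal(s$p_corr[j], cor(m$t_pred, f$X[, j]), tolerance = 1e-12)
  }
  expect_true(all(abs(s$p_corr) <= 1 + 1e-12))
  # a column equal to t_pred has p_corr 1; -2 t_pred has p_corr -1
  X2 <- cbind(f$X, m$t_pred, -2 * m$t_pred)
  s2 <- sline(m, X2)
  expect_equal(s2$p_corr[7], 1.0, tolerance = 1e-12)
  expect_equal(s2$p_corr[8], -1.0, tolerance = 1e-12)
  expect_equal(s2$p_ctr[8], -2 * var(m$t_pred), tolerance = 1e-12)
  expect_error(sline(m, cbind(f$X[, 1:5], 0)), "zero-variance")
})

test_that("VIP normalisation and informative-variable ranking hold", {
  f <- make_xy(n = 30, k = 12, seed = 51, effect = 3)
  m <- fit_oplsda(f$X, f$y, a_ortho = 1)
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-12)
  expect_equal(mean(vip(m, "total")^2), 1, tolerance = 1e-8)
  hits <- sapply(1:20, function(s) {
    f <- make_xy(n = 40, k = 15, seed = 200 + s, effect = 3)
    m <- fit_oplsda(f$X, f$y, a_ortho = 0)
    which.max(vip(m)) == 1
  })
  expect_gte(mean(hits), 0.99)
})

test_that("prediction reproduces in-sample fits and is continuous", {
  d <- generate_profiles(n_case = 7, n_control = 7, seed = 61)
  m <- oplsda(d$profile, a_ortho = 1, cv = FALSE)
  pr <- predict(m, d$profile)
  expect_equal(pr$yhat, m$t_pred * m$q, tolerance = 1e-10)
  # a duplicated training row with tiny noise keeps its label
  x1 <- d$profile$X[1, , drop = FALSE]
  pr1 <- predict(m, x1)
  pr2 <- predict(m, x1 * (1 + 1e-9))
  expect_identical(pr1$label, pr2$label)
  expect_error(predict(m, x1[, 1:10, drop = FALSE]), "columns")
})

test_that("held-out classification on distinct synthetic cohorts is accurate", {
  accs <- sapply(1:25, function(s) {
    tr <- generate_profiles(n_case = 7, n_control = 7, seed = 1000 + s)
    te <- generate_profiles(n_case = 7, n_control = 7, seed = 5000 + s)
    m <- oplsda(tr$profile, a_ortho = 1, cv = FALSE)
    pr <- predict(m, te$profile)
    truth <- te$profile$meta$group
    mean(c(mean(pr$label[truth == "case"] == "case"),
           mean(pr$label[truth == "control"] == "control")))
  })
  expect_gt(mean(accs), 0.8)
})
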