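# shared fixtures built in code

# flat-top spectrum on a uniform descending grid
make_flat_spectrum <- function(value = 1, from = 6, to = 0.5, step = 0.001) {
  ppm <- seq(from, to, by = -step)
  spectrum(ppm, rep(value, length(ppm)))
}

# tiny region table: non-overlapping, descending
make_tiny_regions <- function() {
  region_table(data.frame(
    var_id = 1:4,
    ppm_hi = c(5.0, 3.6, 2.0, 0.95),
    ppm_lo = c(4.0, 3.4, 1.0, 0.80),
    assignment = c("a", "b", "c", "d"),
    is_glucose = c(FALSE, TRUE, FALSE, FALSE)))
}

# random scaled matrix with guaranteed class structure for OPLS fits
make_xy <- function(n = 8, k = 5, seed = 1, effect = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(rnorm(n * k), n, k)
  X[, 1] <- X[, 1] + effect * y
  list(X = scale(X, scale = FALSE), y = y)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o[i:m]] / seq(i, m)))
  }
  # enforce monotone min-over-tail on the sorted scale
  s <- p[o]
  a <- pmin(1, m * s / seq_len(m))
  for (i in rev(seq_len(m - 1))) a[i] <- min(a[i], a[i + 1])
  adj2 <- numeric(m); adj2[o] <- a
  adj2
}

# one-component PLS1 via the eigen decomposition of X'yy'X
pls1_oracle <- function(X, y) {
  y_c <- y - mean(y)
  M <- crossprod(X, y_c) %*% crossprod(y_c, X)
  w <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (sum(w * crossprod(X, y_c)) < 0) w <- -w
  t <- as.numeric(X %*% w)
  list(w = w, t = t, q = sum(y_c * t) / sum(t^2))
}
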