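#' Principal component analysis by NIPALS, with outlier diagnostics
#'
#' Unsupervised PCA of the scaled profile matrix, used to look for
#' clustering and confounders and to screen samples by Hotelling's T2 and
#' distance-to-model (DModX) before any supervised modelling. Components are
#' extracted sequentially by NIPALS with deflation; loadings are normalised
#' and sign-fixed so that each loading vector's largest-magnitude element is
#' positive, making output reproducible across platforms.
#'
#' @param Xs Scaled N x K matrix (see [fit_scaling()]).
#' @param A Number of components, \code{1 <= A <= min(N - 1, K)}; default 2,
#'   matching a two-component score plot.
#' @param tol Convergence tolerance on the relative score change.
#' @param max_iter Iteration cap per component.
#' @return An object of class \code{nmr_pca}: scores \code{T} (N x A),
#'   loadings \code{P} (K x A, orthonormal), per-component and cumulative
#'   explained fractions \code{r2x} / \code{r2x_cum}, residual matrix
#'   \code{E}, and the total sum of squares \code{ssx}.
#' @export
fit_pca <- function(Xs, A = 2, tol = 1e-12, max_iter = 500) {
  Xs <- as_matrix(Xs)
  N <- nrow(Xs); K <- ncol(Xs)
  if (A < 1 || A > min(N - 1, K))
    stopf("A must lie in [1, %d]", min(N - 1, K))
  ssx <- sum(Xs^2)
  Tm <- matrix(0, N, A); P <- matrix(0, K, A)
  r2x <- numeric(A)
  X <- Xs
  for (a in seq_len(A)) {
    t <- X[, which.max(apply(X, 2, stats::var))]
    for (it in seq_len(max_iter)) {
      p <- crossprod(X, t) / sum(t^2)
      p <- p / sqrt(sum(p^2))
      t_new <- X %*% p
      if (sqrt(sum((t_new - t)^2)) <= tol * sqrt(sum(t_new^2))) {
        t <- t_new; break
      }
      t <- t_new
      if (it == max_iter)
        stopf("NIPALS failed to converge for component %d", a)
    }
    flip <- sign(p[which.max(abs(p))]); if (flip < 0) { p <- -p; t <- -t }
    Tm[, a] <- t; P[, a] <- p
    r2x[a] <- sum(t^2) / ssx
    X <- X - tcrossprod(t, p)
  }
  rownames(Tm) <- rownames(Xs); rownames(P) <- colnames(Xs)
  structure(list(A = A, T = Tm, P = P, r2x = r2x, r2x_cum = cumsum(r2x),
                 E = X, ssx = ssx, N = N, K = K),
            class = "nmr_pca")
}

#' @export
print.nmr_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d components on %d x %d matrix\n", x$A, x$N, x$K))
  cat(sprintf("  R2X per component: %s\n",
              paste(sprintf("%.1f%%", 100 * x$r2x), collapse = ", ")))
  cat(sprintf("  R2X(cum): %.1f%%\n", 100 * x$r2x_cum[x$A]))
  invisible(x)
}

#' @param m A fitted \code{nmr_pca} model.
#' @param alpha Significance level of the control limit (default 0.05).
#' @return For \code{hotelling_t2} and \code{dmodx}: a data frame with one
#'   row per sample (\code{sample_id}, the statistic, its limit and a
#'   logical \code{flag}).
#' @rdname fit_pca
#' @export
hotelling_t2 <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "nmr_pca"))
  N <- m$N; A <- m$A
  if (N <= A) stopf("Hotelling's T2 needs N > A")
  v <- apply(m$T, 2, stats::var)
  t2 <- rowSums(sweep(m$T^2, 2, v, "/"))
  lim <- A * (N^2 - 1) / (N * (N - A)) * stats::qf(1 - alpha, A, N - A)
  data.frame(sample_id = rownames(m$T) %||% seq_len(N),
             t2 = t2, t2_limit = lim, flag = t2 > lim,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname fit_pca
#' @export
dmodx <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "nmr_pca"))
  N <- m$N; K <- m$K; A <- m$A
  if (K <= A) stopf("DModX needs K > A")
  s_i <- sqrt(rowSums(m$E^2) / (K - A))
  s0 <- sqrt(sum(m$E^2) / ((N - A - 1) * (K - A)))
  # a numerically exact fit (A = rank) leaves pure floating-point dust
  zero_resid <- sum(m$E^2) <= 1e-16 * m$ssx
  d <- if (!zero_resid) (s_i / s0) * sqrt(N / (N - A - 1)) else rep(0, N)
  lim <- sqrt(stats::qf(1 - alpha, K - A, (N - A - 1) * (K - A)))
  data.frame(sample_id = rownames(m$T) %||% seq_len(N),
             dmodx = d, dmodx_limit = lim, flag = d > lim,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @param x A fitted \code{nmr_pca}.
#' @param meta Optional metadata for colouring (a factor/vector per sample,
#'   e.g. group, sex, age bins) -- the confounder "staining" view.
#' @param components Which two components to plot.
#' @param ... Passed to [graphics::plot()].
#' @rdname fit_pca
#' @export
plot.nmr_pca <- function(x, meta = NULL, components = c(1, 2), ...) {
  a <- components[1]; b <- components[2]
  col <- if (is.null(meta)) "black" else as.integer(factor(meta)) + 1
  graphics::plot(x$T[, a], x$T[, b],
                 xlab = sprintf("t[%d] (%.1f%%)", a, 100 * x$r2x[a]),
                 ylab = sprintf("t[%d] (%.1f%%)", b, 100 * x$r2x[b]),
                 col = col, pch = 19, ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  if (!is.null(meta))
    graphics::legend("topright", legend = levels(factor(meta)),
                     col = seq_along(levels(factor(meta))) + 1, pch = 19)
  invisible(x)
}
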