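#' Mean-centering and Pareto scaling
#'
#' Fits per-column location/scale parameters on a training matrix so the
#' identical transform can later be applied to held-out samples (no
#' information leaks from test folds into the scaling). Pareto scaling
#' divides each mean-centered column by the square root of its sample
#' standard deviation (n - 1 denominator), damping but not flattening the
#' intensity differences between strong and weak spectral regions.
#'
#' @param X Numeric matrix (N x K) or \code{profile_matrix}, N >= 3.
#' @param mode \code{"pareto"} (default) or \code{"none"} (centering only).
#' @return A \code{scaling_params} object with fields \code{mu}, \code{s},
#'   \code{mode}.
#' @examples
#' p <- fit_scaling(matrix(c(1, 2, 3, 0, 0, 4), 3))
#' @export
fit_scaling <- function(X, mode = c("pareto", "none")) {
  mode <- match.arg(mode)
  X <- as_matrix(X)
  if (nrow(X) < 3) stopf("need N >= 3 samples to fit scaling")
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  zero <- which(s <= 0 | !is.finite(s))
  if (length(zero))
    stopf("constant column(s), degenerate under Pareto scaling: %s",
          paste(colnames(X)[zero] %||% zero, collapse = ", "))
  structure(list(mu = mu, s = s, mode = mode), class = "scaling_params")
}

#' @param p A \code{scaling_params} from [fit_scaling()].
#' @rdname fit_scaling
#' @export
apply_scaling <- function(X, p) {
  stopifnot(inherits(p, "scaling_params"))
  X <- as_matrix(X)
  if (ncol(X) != length(p$mu))
    stopf("dimension mismatch: %d columns vs %d fitted", ncol(X), length(p$mu))
  Xc <- sweep(X, 2, p$mu, "-")
  if (p$mode == "pareto") Xc <- sweep(Xc, 2, sqrt(p$s), "/")
  Xc
}

#' @rdname fit_scaling
#' @export
invert_scaling <- function(X, p) {
  stopifnot(inherits(p, "scaling_params"))
  X <- as_matrix(X)
  if (p$mode == "pareto") X <- sweep(X, 2, sqrt(p$s), "*")
  sweep(X, 2, p$mu, "+")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("Scaling parameters (%s): %d variables\n", x$mode, length(x$mu)))
  invisible(x)
}

as_matrix <- function(X) {
  if (inherits(X, "profile_matrix")) X$X else as.matrix(X)
}
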