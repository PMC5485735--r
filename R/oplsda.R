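#' Orthogonal PLS discriminant analysis for a two-class response
#'
#' Fits a single-response OPLS-DA model: one predictive component whose
#' scores separate the two classes, plus \code{a_ortho} orthogonal
#' components capturing structured X-variation uncorrelated with class.
#' The class response is encoded control = +1, case = -1 and mean-centered;
#' X is mean-centered and Pareto-scaled by default. Model quality is
#' reported as R2X(cum) and R2Y(cum), and -- when cross-validation is
#' requested -- the sevenfold cross-validated Q2(cum), together with S-line
#' statistics (p(ctr), p(corr)) and VIP with jack-knife standard errors over
#' the cross-validation submodels.
#'
#' @param x A \code{profile_matrix} (class labels taken from its metadata
#'   \code{group} column) or a numeric N x K matrix.
#' @param y Class labels (two levels), required when \code{x} is a bare
#'   matrix. The level named by \code{positive} is coded +1, the other -1.
#' @param a_ortho Number of orthogonal components (default 1).
#' @param scale \code{"pareto"} or \code{"none"}; fitted on \code{x} and
#'   stored for prediction.
#' @param positive Label coded +1 (defaults to \code{"control"} when
#'   present, otherwise the first factor level).
#' @param cv Run cross-validation and attach Q2, per-fold submodels and
#'   VIP cvSE (default TRUE).
#' @param n_folds Cross-validation segments (default 7).
#' @param seed Seed for the deterministic stratified fold assignment.
#' @param rescale_per_fold Refit scaling on each training fold (default
#'   TRUE; no information from held-out samples enters the transform).
#' @return An object of class \code{oplsda}; see [fit_oplsda()] for the
#'   component fields. Adds \code{scaling}, \code{y_labels}, \code{sline}
#'   (data frame of p(ctr)/p(corr)/VIP), and \code{cv} (an \code{oplsda_cv}).
#' @seealso [fit_oplsda()], [cross_validate()], [sline()], [vip()]
#' @examples
#' d <- generate_profiles(n_case = 7, n_control = 7, seed = 1)
#' m <- oplsda(d$profile, seed = 1)
#' summary(m)
#' @export
oplsda <- function(x, y = NULL, a_ortho = 1, scale = c("pareto", "none"),
                   positive = NULL, cv = TRUE, n_folds = 7, seed = 1,
                   rescale_per_fold = TRUE) {
  scale <- match.arg(scale)
  X <- as_matrix(x)
  if (is.null(y)) {
    if (!inherits(x, "profile_matrix") || is.null(x$meta) ||
        !"group" %in% names(x$meta))
      stopf("y is required when x carries no group metadata")
    y <- x$meta$group
  }
  cls <- class_vector(y, positive = positive)
  params <- fit_scaling(X, mode = scale)
  m <- fit_oplsda(apply_scaling(X, params), cls$y, a_ortho = a_ortho)
  m$scaling <- params
  m$y_labels <- cls$labels
  m$call <- match.call()
  Xs <- apply_scaling(X, params)
  sl <- sline(m, Xs)
  sl$vip <- vip(m)
  if (cv) {
    m$cv <- cross_validate(X, cls$y, a_ortho = a_ortho, n_folds = n_folds,
                           seed = seed, scale = scale,
                           rescale_per_fold = rescale_per_fold)
    v <- vip_with_cvse(m, m$cv)
    sl$vip_cvse <- v$vip_cvse
  }
  m$sline <- sl
  m
}

# two-level class labels -> numeric +1/-1 vector (+1 = `positive` level)
class_vector <- function(y, positive = NULL) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(-1, 1)) || length(u) != 2)
      stopf("numeric y must contain both +1 and -1")
    return(list(y = y, labels = c(pos = "1", neg = "-1")))
  }
  f <- factor(y)
  if (nlevels(f) != 2) stopf("y must have exactly two classes")
  pos <- positive %||% (if ("control" %in% levels(f)) "control" else levels(f)[1])
  if (!pos %in% levels(f)) stopf("positive level '%s' not found in y", pos)
  neg <- setdiff(levels(f), pos)
  list(y = ifelse(f == pos, 1, -1), labels = c(pos = pos, neg = neg))
}

#' Core OPLS fit on a pre-scaled matrix
#'
#' Implements the single-response OPLS sequence: the predictive weight
#' \code{w} is the normalised covariance direction \code{X'y}; each
#' orthogonal component is extracted from the current X-loading by removing
#' its projection on \code{w}, and X is deflated before the final predictive
#' component is computed.
#'
#' @param Xs Scaled N x K matrix.
#' @param y Numeric class vector (+1/-1 or any centered two-value coding).
#' @param a_ortho Number of orthogonal components, \code{<= N - 2}.
#' @return List of class \code{oplsda}: \code{w} (unit predictive weights),
#'   \code{t_pred}, \code{p_pred}, \code{q}, orthogonal \code{W_o},
#'   \code{T_o}, \code{P_o}, per-component X-variation
#'   \code{component_r2x}, \code{r2x_cum}, \code{r2y_cum}.
#' @export
fit_oplsda <- function(Xs, y, a_ortho = 1) {
  Xs <- as_matrix(Xs)
  N <- nrow(Xs); K <- ncol(Xs)
  if (N < 4) stopf("need N >= 4 samples")
  if (length(y) != N) stopf("y length does not match X")
  if (length(unique(y)) < 2) stopf("y has a single class")
  if (min(table(y)) < 2) stopf("both classes need >= 2 samples")
  if (a_ortho > N - 2) stopf("a_ortho must be <= N - 2")
  y_c <- y - mean(y)
  ssx <- sum(Xs^2); ssy <- sum(y_c^2)

  w <- crossprod(Xs, y_c)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12 * sqrt(ssx * ssy)) stopf("no predictive direction: y is orthogonal to X")
  w <- as.numeric(w / nw)

  W_o <- matrix(0, K, a_ortho); T_o <- matrix(0, N, a_ortho)
  P_o <- matrix(0, K, a_ortho); r2x_o <- numeric(a_ortho)
  X <- Xs
  for (o in seq_len(a_ortho)) {
    t <- X %*% w
    p <- as.numeric(crossprod(X, t) / sum(t^2))
    w_o <- p - sum(w * p) * w
    nw_o <- sqrt(sum(w_o^2))
    if (nw_o < 1e-12) stopf("no orthogonal variation left at component %d", o)
    w_o <- w_o / nw_o
    t_o <- as.numeric(X %*% w_o)
    p_o <- as.numeric(crossprod(X, t_o) / sum(t_o^2))
    W_o[, o] <- w_o; T_o[, o] <- t_o; P_o[, o] <- p_o
    r2x_o[o] <- sum(t_o^2) * sum(p_o^2) / ssx
    X <- X - tcrossprod(t_o, p_o)
  }
  t_pred <- as.numeric(X %*% w)
  p_pred <- as.numeric(crossprod(X, t_pred) / sum(t_pred^2))
  q <- sum(y_c * t_pred) / sum(t_pred^2)
  r2y <- 1 - sum((y_c - t_pred * q)^2) / ssy
  r2x_p <- sum(t_pred^2) * sum(p_pred^2) / ssx
  names(w) <- names(p_pred) <- colnames(Xs)
  structure(list(w = w, t_pred = t_pred, p_pred = p_pred, q = q,
                 W_o = W_o, T_o = T_o, P_o = P_o, a_ortho = a_ortho,
                 component_r2x = c(pred = r2x_p,
                                   stats::setNames(r2x_o, if (a_ortho)
                                     paste0("ortho", seq_len(a_ortho)))),
                 r2x_cum = r2x_p + sum(r2x_o), r2y_cum = r2y,
                 ssx = ssx, ssy = ssy, y_c = y_c, N = N, K = K),
            class = "oplsda")
}

#' Predict class membership for new samples
#'
#' New rows are scaled with the training parameters (when the model was fit
#' through [oplsda()]), stripped of orthogonal variation using the stored
#' orthogonal weights/loadings, and projected on the predictive weights;
#' \code{yhat = t_pred_new * q} and the class label is its sign (+1 ->
#' positive class).
#'
#' @param object A fitted \code{oplsda}.
#' @param newdata N x K matrix or \code{profile_matrix} on the original
#'   (unscaled) measurement scale if the model stores scaling parameters,
#'   otherwise already scaled.
#' @param ... Unused.
#' @return Data frame with \code{t_pred}, \code{yhat} and \code{label}.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  X <- as_matrix(newdata)
  if (ncol(X) != object$K)
    stopf("newdata has %d columns; model expects %d", ncol(X), object$K)
  if (!is.null(object$scaling)) X <- apply_scaling(X, object$scaling)
  for (o in seq_len(object$a_ortho)) {
    t_o <- as.numeric(X %*% object$W_o[, o])
    X <- X - outer(t_o, object$P_o[, o])
  }
  t_new <- as.numeric(X %*% object$w)
  yhat <- t_new * object$q
  lab <- if (!is.null(object$y_labels))
    ifelse(yhat > 0, object$y_labels["pos"], object$y_labels["neg"])
  else ifelse(yhat > 0, 1, -1)
  data.frame(t_pred = t_new, yhat = yhat, label = lab,
             row.names = rownames(X) %||% NULL, stringsAsFactors = FALSE)
}

#' S-line statistics: covariance and correlation loadings
#'
#' For every variable, \code{p_ctr} is the covariance (n - 1 denominator)
#' between the predictive score and the scaled variable -- large for intense
#' signals -- and \code{p_corr} is the corresponding correlation
#' coefficient, a scale-free reliability measure bounded by 1 in magnitude.
#'
#' @param m A fitted \code{oplsda}.
#' @param Xs The scaled matrix the model was fitted on (the model working
#'   space). Defaults to reconstructing nothing: it must be supplied for a
#'   bare [fit_oplsda()] model.
#' @return Data frame with \code{variable}, \code{p_ctr}, \code{p_corr}.
#' @export
sline <- function(m, Xs) {
  stopifnot(inherits(m, "oplsda"))
  Xs <- as_matrix(Xs)
  t <- m$t_pred
  sds <- apply(Xs, 2, stats::sd)
  zero <- which(sds <= 0)
  if (length(zero))
    stopf("zero-variance column(s), p_corr undefined: %s",
          paste(colnames(Xs)[zero] %||% zero, collapse = ", "))
  p_ctr <- as.numeric(stats::cov(t, Xs))
  p_corr <- p_ctr / (stats::sd(t) * sds)
  data.frame(variable = colnames(Xs) %||% seq_len(ncol(Xs)),
             p_ctr = p_ctr, p_corr = as.numeric(p_corr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variable importance for the projection
#'
#' Default mode \code{"predictive"} scores importance on the predictive
#' component only: \code{VIP_j = sqrt(K) * |w_j|}, so the mean squared VIP
#' over variables is exactly 1. Mode \code{"total"} additionally weighs the
#' orthogonal weight vectors by their share of modelled X-variation.
#'
#' @param m A fitted \code{oplsda}.
#' @param mode \code{"predictive"} (default) or \code{"total"}.
#' @return Numeric vector of length K.
#' @export
vip <- function(m, mode = c("predictive", "total")) {
  mode <- match.arg(mode)
  K <- m$K
  if (mode == "predictive") return(sqrt(K) * abs(m$w))
  ss <- m$component_r2x
  W <- cbind(m$w, m$W_o)
  as.numeric(sqrt(K * (W^2 %*% ss) / sum(ss)))
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA model: 1 predictive + %d orthogonal component(s), N = %d, K = %d\n",
              x$a_ortho, x$N, x$K))
  cat(sprintf("  R2X(cum) = %.1f%%  R2Y(cum) = %.1f%%", 100 * x$r2x_cum,
              100 * x$r2y_cum))
  if (!is.null(x$cv)) cat(sprintf("  Q2(cum) = %.1f%%", 100 * x$cv$q2_cum))
  cat("\n")
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  print(object)
  cat(sprintf("  X-variation per component: %s\n",
              paste(sprintf("%s %.1f%%", names(object$component_r2x),
                            100 * object$component_r2x), collapse = ", ")))
  if (!is.null(object$sline)) {
    top <- object$sline[order(-abs(object$sline$p_corr)), ]
    cat("  Top |p(corr)| variables:\n")
    print(utils::head(top, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.oplsda <- function(object, ...) {
  cbind(w = object$w, p_pred = object$p_pred)
}

#' @export
residuals.oplsda <- function(object, ...) {
  object$y_c - object$t_pred * object$q
}

#' @param y Unused (S3 signature).
#' @rdname oplsda
#' @export
plot.oplsda <- function(x, y = NULL, ...) {
  to <- if (x$a_ortho >= 1) x$T_o[, 1] else residuals(x)
  grp <- x$y_c > 0
  graphics::plot(x$t_pred, to, col = ifelse(grp, "blue", "red"), pch = 19,
                 xlab = sprintf("t[1]P (%.1f%%)", 100 * x$component_r2x["pred"]),
                 ylab = if (x$a_ortho >= 1)
                   sprintf("t[1]O (%.1f%%)", 100 * x$component_r2x["ortho1"])
                 else "y residual", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
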