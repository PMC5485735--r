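#' Sevenfold cross-validation of an OPLS-DA model
#'
#' Samples are assigned to folds by a deterministic stratified round-robin:
#' within each class the sample order is shuffled under \code{seed} and
#' members are dealt to folds cyclically, so fold sizes differ by at most
#' one and every sample is held out exactly once. For each fold, scaling is
#' (by default) refitted on the training rows only, the model is refitted,
#' and the held-out responses are predicted after stripping orthogonal
#' variation; \code{Q2(cum) = 1 - PRESS / SS}, with SS the total sum of
#' squares of the full centered response.
#'
#' @param X Unscaled N x K matrix or \code{profile_matrix}.
#' @param y Class labels or numeric +1/-1 vector.
#' @param a_ortho Orthogonal components per submodel.
#' @param n_folds Number of segments (default 7; \code{n_folds = N} is
#'   leave-one-out).
#' @param seed Seed for the fold shuffle.
#' @param scale Scaling mode handed to [fit_scaling()].
#' @param rescale_per_fold Refit scaling per training fold (default TRUE).
#' @param positive Label coded +1 (see [oplsda()]).
#' @return An \code{oplsda_cv} object: \code{q2_cum}, \code{press},
#'   \code{fold_assignment}, \code{yhat} (out-of-fold predictions), and
#'   \code{fold_models} (per-fold predictive weights and VIPs for
#'   jack-knifing).
#' @export
cross_validate <- function(X, y, a_ortho = 1, n_folds = 7, seed = 1,
                           scale = c("pareto", "none"),
                           rescale_per_fold = TRUE, positive = NULL) {
  scale <- match.arg(scale)
  X <- as_matrix(X)
  cls <- class_vector(y, positive = positive)
  yv <- cls$y
  N <- nrow(X)
  if (n_folds > N) stopf("n_folds (%d) exceeds N (%d)", n_folds, N)
  if (n_folds < 2) stopf("need at least 2 folds")

  fold <- integer(N)
  with_local_seed(sub_seed(seed, 4), {
    dealt <- 0
    for (g in unique(yv)) {
      idx <- which(yv == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (dealt + seq_along(idx) - 1) %% n_folds + 1
      dealt <- dealt + length(idx)
    }
  })
  for (f in seq_len(n_folds)) {
    if (length(unique(yv[fold != f])) < 2 || min(table(yv[fold != f])) < 2)
      stopf("training fold %d lacks both classes; use fewer folds", f)
  }

  y_c_full <- yv - mean(yv)
  ss <- sum(y_c_full^2)
  press <- 0
  yhat <- numeric(N)
  fold_models <- vector("list", n_folds)
  params_all <- if (!rescale_per_fold) fit_scaling(X, mode = scale)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    params <- if (rescale_per_fold) fit_scaling(X[tr, , drop = FALSE],
                                                mode = scale) else params_all
    m <- fit_oplsda(apply_scaling(X[tr, , drop = FALSE], params),
                    yv[tr], a_ortho = a_ortho)
    Xte <- apply_scaling(X[te, , drop = FALSE], params)
    for (o in seq_len(a_ortho)) {
      t_o <- as.numeric(Xte %*% m$W_o[, o])
      Xte <- Xte - outer(t_o, m$P_o[, o])
    }
    pred <- as.numeric(Xte %*% m$w) * m$q
    obs <- yv[te] - mean(yv[tr])
    press <- press + sum((obs - pred)^2)
    yhat[te] <- pred
    fold_models[[f]] <- list(w = m$w, vip = vip(m), q = m$q)
  }
  structure(list(q2_cum = 1 - press / ss, press = press,
                 fold_assignment = fold, yhat = yhat,
                 fold_models = fold_models, n_folds = n_folds,
                 seed = as.integer(seed), rescale_per_fold = rescale_per_fold),
            class = "oplsda_cv")
}

#' @export
print.oplsda_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: Q2(cum) = %.3f (PRESS = %.3f)\n",
              x$n_folds, x$q2_cum, x$press))
  invisible(x)
}

#' VIP with jack-knife standard errors over cross-validation submodels
#'
#' The point estimate is the full-model VIP; its uncertainty is the
#' jack-knife standard error across the G cross-validation submodels:
#' \code{cvse_j = sqrt(((G - 1) / G) * sum_g (VIP_jg - mean_g VIP_jg)^2)}.
#'
#' @param m A fitted \code{oplsda}.
#' @param cv An \code{oplsda_cv} with retained submodels.
#' @return Data frame with \code{variable}, \code{vip}, \code{vip_cvse}.
#' @export
vip_with_cvse <- function(m, cv) {
  stopifnot(inherits(m, "oplsda"))
  if (!inherits(cv, "oplsda_cv") || is.null(cv$fold_models))
    stopf("cross-validation submodels unavailable; run cross_validate() first")
  V <- vapply(cv$fold_models, function(fm) fm$vip, numeric(m$K))
  G <- ncol(V)
  vbar <- rowMeans(V)
  cvse <- sqrt(((G - 1) / G) * rowSums((V - vbar)^2))
  data.frame(variable = names(m$w) %||% seq_len(m$K),
             vip = as.numeric(vip(m)), vip_cvse = as.numeric(cvse),
             row.names = NULL, stringsAsFactors = FALSE)
}
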