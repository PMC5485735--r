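#' Two-sample t-tests, BH adjustment, and percent change
#'
#' Univariate screening of region integrals: Student's pooled-variance
#' two-sample t-test (two-sided) per variable, Benjamini-Hochberg adjustment
#' across variables, and the percent change of the case-group mean relative
#' to the control-group mean. \code{ttest_summary()} computes the identical
#' statistic from group summary statistics (means, SDs, ns), so published
#' summary tables can be verified without raw data.
#'
#' @param x_case,x_control Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) test instead of pooled.
#' @return For the t-test functions: list with \code{t_stat}, \code{df},
#'   \code{p_raw}.
#' @examples
#' ttest_raw(c(1, 2, 3), c(4, 5, 6))
#' ttest_summary(0.70, 0.32, 7, 1.94, 0.41, 7)   # tryptophan region
#' @export
ttest_raw <- function(x_case, x_control, welch = FALSE) {
  if (length(x_case) < 2 || length(x_control) < 2)
    stopf("each group needs n >= 2")
  if (stats::var(x_case) + stats::var(x_control) <= 0)
    stopf("zero pooled variance")
  ht <- stats::t.test(x_case, x_control, var.equal = !welch)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_raw = ht$p.value)
}

#' @param mean1,sd1,n1 Case-group mean, SD and size.
#' @param mean2,sd2,n2 Control-group mean, SD and size.
#' @rdname ttest_raw
#' @export
ttest_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stopf("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || sd1 + sd2 <= 0) stopf("zero pooled variance")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t_stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t_stat = t_stat, df = df,
       p_raw = 2 * stats::pt(-abs(t_stat), df))
}

#' @param p Vector of raw p-values in [0, 1].
#' @rdname ttest_raw
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @param mean_case,mean_control Group means (control nonzero).
#' @rdname ttest_raw
#' @export
percent_change <- function(mean_case, mean_control) {
  if (any(mean_control == 0)) stopf("zero control mean")
  100 * (mean_case - mean_control) / mean_control
}

#' Per-variable univariate summary table
#'
#' @param pm A \code{profile_matrix} whose metadata has a two-level
#'   \code{group} column.
#' @param case,control Group labels; default \code{"case"}-like level is
#'   whichever is not \code{"control"}.
#' @param welch Use Welch's t-test.
#' @return Data frame with one row per variable: group means and SDs,
#'   t-statistic, df, raw and BH-adjusted p, percent change and direction.
#' @export
univariate_table <- function(pm, case = NULL, control = NULL, welch = FALSE) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (is.null(pm$meta) || !"group" %in% names(pm$meta))
    stopf("profile matrix lacks group metadata")
  g <- factor(pm$meta$group)
  if (nlevels(g) != 2) stopf("group must have exactly two levels")
  control <- control %||% (if ("control" %in% levels(g)) "control" else levels(g)[2])
  case <- case %||% setdiff(levels(g), control)
  Xa <- pm$X[g == case, , drop = FALSE]
  Xb <- pm$X[g == control, , drop = FALSE]
  tests <- lapply(seq_len(ncol(pm$X)), function(j)
    ttest_raw(Xa[, j], Xb[, j], welch = welch))
  out <- data.frame(
    var_id = pm$region_ids,
    mean_case = colMeans(Xa), sd_case = apply(Xa, 2, stats::sd),
    mean_control = colMeans(Xb), sd_control = apply(Xb, 2, stats::sd),
    t_stat = vapply(tests, `[[`, numeric(1), "t_stat"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_raw = vapply(tests, `[[`, numeric(1), "p_raw"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p_raw)
  out$pct_change <- percent_change(out$mean_case, out$mean_control)
  out$direction <- ifelse(out$pct_change >= 0, "up", "down")
  out
}

#' Three-criterion selection of discriminating variables
#'
#' A variable is declared a strong contributor to the group discrimination
#' only when all three criteria hold: (1) BH-adjusted p below
#' \code{alpha_adj}, (2) \code{|p(corr)|} above \code{pcorr_min}, and
#' (3) VIP above \code{vip_min}.
#'
#' @param u Univariate table from [univariate_table()].
#' @param s S-line table with \code{p_corr} and \code{vip} columns, aligned
#'   with \code{u} (same variables, e.g. from a fitted [oplsda()] model's
#'   \code{$sline}).
#' @param alpha_adj Adjusted-p threshold (default 0.05).
#' @param pcorr_min Minimum \code{|p(corr)|} (default 0.6).
#' @param vip_min Minimum VIP (default 0.5).
#' @return \code{u} with the multivariate columns appended and a logical
#'   \code{selected} verdict, ordered by \code{var_id}.
#' @export
select_discriminators <- function(u, s, alpha_adj = 0.05, pcorr_min = 0.6,
                                  vip_min = 0.5) {
  if (any(c(alpha_adj, pcorr_min, vip_min) <= 0))
    stopf("all thresholds must be > 0")
  if (nrow(u) != nrow(s)) stopf("univariate and S-line tables are misaligned")
  if ("variable" %in% names(s)) {
    sv <- sub("^var_", "", s$variable)
    if (!identical(as.character(u$var_id), sv))
      stopf("univariate and S-line tables are misaligned")
  }
  out <- u
  out$p_ctr <- s$p_ctr
  out$p_corr <- s$p_corr
  out$vip <- s$vip
  out$vip_cvse <- if ("vip_cvse" %in% names(s)) s$vip_cvse else NA_real_
  out$selected <- out$p_adj < alpha_adj & abs(out$p_corr) > pcorr_min &
    out$vip > vip_min
  out[order(out$var_id), ]
}
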