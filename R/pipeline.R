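#' Ingest a binned profile matrix with sample metadata
#'
#' @param matrix_path CSV whose first column is \code{sample_id} and whose
#'   remaining columns are \code{var_<id>} region integrals.
#' @param metadata_path CSV with \code{sample_id}, a two-level \code{group}
#'   column, and optionally \code{age}, \code{sex}, \code{bmi_sds}.
#' @return A \code{profile_matrix}. Missing values are rejected outright --
#'   imputation would silently change every downstream statistic.
#' @export
ingest_matrix <- function(matrix_path, metadata_path) {
  mat <- utils::read.csv(matrix_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (names(mat)[1] != "sample_id") stopf("first matrix column must be sample_id")
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stopf("metadata needs sample_id and group columns")
  if (length(unique(meta$group)) != 2)
    stopf("group column must have exactly two levels, found %d",
          length(unique(meta$group)))
  X <- as.matrix(mat[, -1, drop = FALSE])
  rownames(X) <- mat$sample_id
  if (anyNA(X) || anyNA(meta))
    stopf("missing values in input; imputation is not supported")
  pm <- profile_matrix(X, meta = meta)
  sm <- metadata_summary(pm)
  if (!is.null(sm))
    message(paste(utils::capture.output(print(sm, row.names = FALSE)),
                  collapse = "\n"))
  pm
}

#' Group-wise metadata summary (the subject-table analog)
#'
#' @param pm A \code{profile_matrix} with metadata.
#' @return Data frame with per-group n and mean/SD of every numeric
#'   metadata column, or NULL when there is no metadata.
#' @export
metadata_summary <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  meta <- pm$meta
  if (is.null(meta) || !"group" %in% names(meta)) return(NULL)
  num <- names(meta)[vapply(meta, is.numeric, logical(1))]
  num <- setdiff(num, "y")
  groups <- unique(meta$group)
  out <- data.frame(group = groups,
                    n = vapply(groups, function(g) sum(meta$group == g),
                               integer(1)),
                    stringsAsFactors = FALSE)
  for (v in num) {
    out[[paste0(v, "_mean")]] <- vapply(groups, function(g)
      mean(meta[[v]][meta$group == g]), numeric(1))
    out[[paste0(v, "_sd")]] <- vapply(groups, function(g)
      stats::sd(meta[[v]][meta$group == g]), numeric(1))
  }
  out
}

#' Run the full profiling analysis
#'
#' Executes the complete workflow in fixed order: bin (when spectra are
#' supplied) -> scale -> PCA quality control with Hotelling's T2 and DModX
#' -> OPLS-DA on all variables with sevenfold cross-validation -> univariate
#' tests with BH correction -> three-criterion selection -> optional refit
#' with the glucose-flagged regions excluded. All defaults reproduce the
#' published settings (Pareto scaling, 7 folds, |p(corr)| > 0.6, VIP > 0.5,
#' glucose-excluded rerun on). Identical config + seed gives identical
#' outputs.
#'
#' @param profile A \code{profile_matrix}, or NULL if paths/spectra given.
#' @param matrix_path,metadata_path CSV inputs for [ingest_matrix()].
#' @param spectra Named list of \code{spectrum} objects to bin.
#' @param regions A \code{region_table} (default: the packaged 110-region
#'   scheme). Required for binning and for the glucose-excluded branch.
#' @param scale Scaling mode, default \code{"pareto"}.
#' @param pca_components Components for the QC PCA (default 2).
#' @param a_ortho Orthogonal OPLS-DA components (default 1).
#' @param n_folds Cross-validation segments (default 7).
#' @param seed Integer seed controlling fold assignment.
#' @param alpha Outlier-limit significance (default 0.05).
#' @param alpha_adj,pcorr_min,vip_min Selection thresholds (defaults 0.05,
#'   0.6, 0.5).
#' @param rescale_per_fold Refit scaling within each CV training fold.
#' @param run_glucose_excluded Refit after dropping glucose regions.
#' @param out_dir If non-NULL, write results CSVs and a model-summary JSON
#'   there.
#' @return A \code{profiling_run} object: fields \code{profile}, \code{pca},
#'   \code{outliers}, \code{model_full}, \code{results_full},
#'   \code{model_noglc}, \code{results_noglc}, \code{meta_summary},
#'   \code{config}.
#' @export
run_pipeline <- function(profile = NULL, matrix_path = NULL,
                         metadata_path = NULL, spectra = NULL,
                         regions = default_region_table(),
                         scale = "pareto", pca_components = 2, a_ortho = 1,
                         n_folds = 7, seed = 1, alpha = 0.05,
                         alpha_adj = 0.05, pcorr_min = 0.6, vip_min = 0.5,
                         rescale_per_fold = TRUE,
                         run_glucose_excluded = TRUE, out_dir = NULL) {
  cfg <- list(scale = scale, pca_components = pca_components,
              a_ortho = a_ortho, n_folds = n_folds, seed = seed,
              alpha = alpha, alpha_adj = alpha_adj, pcorr_min = pcorr_min,
              vip_min = vip_min, rescale_per_fold = rescale_per_fold,
              run_glucose_excluded = run_glucose_excluded)
  pm <- if (!is.null(profile)) profile
  else if (!is.null(spectra)) bin_dataset(spectra, regions)
  else if (!is.null(matrix_path)) ingest_matrix(matrix_path, metadata_path)
  else stopf("no input: supply profile, spectra, or matrix_path")
  if (inherits(pm, "synthetic_dataset")) pm <- pm$profile
  N <- nrow(pm$X)
  if (n_folds > N)
    stopf("config error: n_folds (%d) exceeds sample count (%d)", n_folds, N)

  params <- fit_scaling(pm$X, mode = scale)
  Xs <- apply_scaling(pm$X, params)
  pca <- fit_pca(Xs, A = min(pca_components, N - 1, ncol(Xs)))
  outliers <- merge(hotelling_t2(pca, alpha), dmodx(pca, alpha),
                    by = "sample_id", sort = FALSE)

  analyse <- function(pmx) {
    m <- oplsda(pmx, a_ortho = a_ortho, scale = scale, cv = TRUE,
                n_folds = n_folds, seed = seed,
                rescale_per_fold = rescale_per_fold)
    u <- univariate_table(pmx)
    res <- select_discriminators(u, m$sline, alpha_adj = alpha_adj,
                                 pcorr_min = pcorr_min, vip_min = vip_min)
    idx <- match(res$var_id, regions$var_id)
    res <- cbind(res[, "var_id", drop = FALSE],
                 ppm_hi = regions$ppm_hi[idx], ppm_lo = regions$ppm_lo[idx],
                 assignment = regions$assignment[idx],
                 res[, setdiff(names(res), "var_id")])
    list(model = m, results = res)
  }
  full <- analyse(pm)
  noglc <- NULL
  if (run_glucose_excluded && any(regions$is_glucose)) {
    pm95 <- exclude_glucose(pm, regions)
    stopifnot(!any(pm95$region_ids %in% regions$var_id[regions$is_glucose]))
    noglc <- analyse(pm95)
  }
  run <- structure(list(profile = pm, pca = pca, outliers = outliers,
                        model_full = full$model, results_full = full$results,
                        model_noglc = noglc$model, results_noglc = noglc$results,
                        meta_summary = metadata_summary(pm), config = cfg),
                   class = "profiling_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.profiling_run <- function(x, ...) {
  cat("Metabolic-profiling run\n")
  cat(sprintf("  samples: %d, variables: %d\n",
              nrow(x$profile$X), ncol(x$profile$X)))
  cat(sprintf("  PCA R2X: %s; outliers flagged: %d (T2), %d (DModX)\n",
              paste(sprintf("%.1f%%", 100 * x$pca$r2x), collapse = "/"),
              sum(x$outliers$flag.x), sum(x$outliers$flag.y)))
  cat("  Full model: "); print(x$model_full)
  if (!is.null(x$model_noglc)) {
    cat(sprintf("  Glucose-excluded model (%d variables): ",
                x$model_noglc$K))
    print(x$model_noglc)
  }
  cat(sprintf("  Selected discriminators: %d (full)%s\n",
              sum(x$results_full$selected),
              if (!is.null(x$results_noglc))
                sprintf(", %d (glucose-excluded)",
                        sum(x$results_noglc$selected)) else ""))
  invisible(x)
}

# Write run artifacts: results tables, scores, outliers, model summary JSON.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
  wcsv(run$results_full, "results_full.csv")
  if (!is.null(run$results_noglc)) wcsv(run$results_noglc, "results_noglc.csv")
  wcsv(run$outliers, "outliers.csv")
  sc <- data.frame(sample_id = rownames(run$pca$T), run$pca$T)
  names(sc)[-1] <- paste0("t", seq_len(run$pca$A))
  wcsv(sc, "scores_pca.csv")
  m <- run$model_full
  so <- data.frame(sample_id = rownames(run$profile$X), t_pred = m$t_pred)
  if (m$a_ortho >= 1) so$t_ortho1 <- m$T_o[, 1]
  wcsv(so, "scores_oplsda.csv")
  wcsv(m$sline, "sline.csv")
  summ <- list(
    n_samples = m$N, n_variables = m$K,
    r2x_cum = m$r2x_cum, r2y_cum = m$r2y_cum,
    q2_cum = if (!is.null(m$cv)) m$cv$q2_cum else NULL,
    component_r2x = as.list(m$component_r2x),
    pca_r2x = run$pca$r2x,
    glucose_excluded = if (!is.null(run$model_noglc)) list(
      n_variables = run$model_noglc$K,
      r2x_cum = run$model_noglc$r2x_cum,
      r2y_cum = run$model_noglc$r2y_cum,
      q2_cum = run$model_noglc$cv$q2_cum) else NULL,
    config = run$config,
    conventions = list(
      y_coding = "control = +1, case = -1",
      scaling = "mean-center + Pareto (sample SD, n-1)",
      vip_mode = "predictive",
      cvse = "jack-knife over CV submodels",
      t2_limit = "A(N^2-1)/(N(N-A)) * F(1-alpha; A, N-A)"))
  jsonlite::write_json(summ, file.path(out_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
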