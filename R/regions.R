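#' Integration-region schemes for 1D 1H-NMR spectra
#'
#' A region table defines the ordered set of chemical-shift intervals
#' (\code{[ppm_lo, ppm_hi]}, stated high-to-low) whose intensity integrals
#' form the metabolic phenotype of a sample. The packaged default scheme has
#' 110 regions spanning 0.80--8.60 ppm (the 4.50--5.00 ppm water band is not
#' covered), of which 15 are flagged as glucose-related; dropping those
#' leaves the 95-variable glucose-excluded phenotype. Boundaries and
#' assignments of the regions not anchored to published values are synthetic
#' fillers and are labelled as such in the \code{assignment} column.
#'
#' @param path Delimited file (CSV or TSV, autodetected) with columns
#'   \code{var_id, ppm_hi, ppm_lo, assignment, is_glucose}.
#' @param name Scheme identifier stored on the object.
#' @return A \code{region_table}: a data frame with the columns above,
#'   sorted by descending \code{ppm_hi}, plus attribute \code{name}.
#' @examples
#' rt <- default_region_table()
#' nrow(rt)            # 110
#' sum(rt$is_glucose)  # 15
#' @export
load_region_table <- function(path, name = basename(path)) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  region_table(df, name = name)
}

#' @rdname load_region_table
#' @export
default_region_table <- function() {
  load_region_table(system.file("extdata", "regions_default.csv",
                                package = "metabofinger"),
                    name = "default-110")
}

#' @param df Data frame with the region columns.
#' @rdname load_region_table
#' @export
region_table <- function(df, name = "custom") {
  need <- c("var_id", "ppm_hi", "ppm_lo", "assignment", "is_glucose")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("region table missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[, need]
  df$var_id <- as.integer(df$var_id)
  df$is_glucose <- as.logical(df$is_glucose)
  bad <- which(df$ppm_hi <= df$ppm_lo)
  if (length(bad))
    stopf("ppm_hi <= ppm_lo for var_id %s", paste(df$var_id[bad], collapse = ", "))
  if (anyDuplicated(df$var_id))
    stopf("duplicate var_id: %s",
          paste(unique(df$var_id[duplicated(df$var_id)]), collapse = ", "))
  df <- df[order(-df$ppm_hi), ]
  # overlap check on the sorted table; shared boundaries are allowed
  if (nrow(df) > 1) {
    ov <- which(df$ppm_lo[-nrow(df)] < df$ppm_hi[-1] - 1e-9)
    if (length(ov))
      stopf("overlapping regions: var_id %s and %s",
            paste(df$var_id[ov], collapse = ","),
            paste(df$var_id[ov + 1], collapse = ","))
  }
  rownames(df) <- NULL
  structure(df, name = name, class = c("region_table", "data.frame"))
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("Integration-region scheme '%s': %d regions (%d glucose-flagged), %.2f-%.2f ppm\n",
              attr(x, "name"), nrow(x), sum(x$is_glucose),
              min(x$ppm_lo), max(x$ppm_hi)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a 1D spectrum from two-column delimited text
#'
#' @param path Text file with two numeric columns (ppm, intensity);
#'   \code{#} comment lines allowed; comma, tab or whitespace separated.
#' @return A \code{spectrum} object: list with \code{ppm} (descending) and
#'   \code{intensity}.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          sep = "", stringsAsFactors = FALSE)
  if (ncol(df) == 1)  # comma-separated fallback
    df <- utils::read.table(path, header = FALSE, comment.char = "#", sep = ",")
  spectrum(df[[1]], df[[2]])
}

#' Construct a spectrum object
#'
#' @param ppm Strictly monotone chemical-shift axis (either direction;
#'   stored descending).
#' @param intensity Signal amplitudes, same length, finite.
#' @export
spectrum <- function(ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stopf("ppm and intensity lengths differ (%d vs %d)",
          length(ppm), length(intensity))
  if (length(ppm) < 2) stopf("empty spectrum")
  d <- diff(ppm)
  if (all(d > 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  else if (!all(d < 0)) stopf("ppm axis not strictly monotone")
  if (!all(is.finite(intensity))) stopf("non-finite intensities")
  structure(list(ppm = ppm, intensity = intensity), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, %.3f-%.3f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# trapezoidal integral of (x, y) over [lo, hi]; x ascending; endpoints
# included by linear interpolation at the exact bounds
trapz_interval <- function(x, y, lo, hi) {
  ylo <- stats::approx(x, y, xout = lo)$y
  yhi <- stats::approx(x, y, xout = hi)$y
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(ylo, y[inside], yhi)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)])) / 2
}

#' Integrate a spectrum over a region scheme
#'
#' Computes, for each region, the trapezoidal integral of intensity over the
#' closed ppm interval \code{[ppm_lo, ppm_hi]}, with both endpoints included
#' by linear interpolation at the exact bounds. Units: intensity x ppm.
#'
#' @param s A \code{spectrum}.
#' @param rt A \code{region_table}; every region must lie inside the
#'   spectral range.
#' @return Numeric vector of length \code{nrow(rt)}, named \code{var_<id>},
#'   in region-table order.
#' @export
integrate_spectrum <- function(s, rt) {
  stopifnot(inherits(s, "spectrum"), inherits(rt, "region_table"))
  x <- rev(s$ppm); y <- rev(s$intensity)   # ascending for interpolation
  out_of_range <- rt$ppm_lo < min(x) - 1e-12 | rt$ppm_hi > max(x) + 1e-12
  if (any(out_of_range))
    stopf("region(s) outside spectral range [%.4f, %.4f]: var_id %s",
          min(x), max(x), paste(rt$var_id[out_of_range], collapse = ", "))
  v <- vapply(seq_len(nrow(rt)), function(i)
    trapz_interval(x, y, rt$ppm_lo[i], rt$ppm_hi[i]), numeric(1))
  names(v) <- paste0("var_", rt$var_id)
  v
}

#' Bin a set of spectra into a profile matrix
#'
#' @param spectra Named list of \code{spectrum} objects (names become sample
#'   ids).
#' @param rt A \code{region_table}.
#' @param meta Optional sample metadata data frame with a \code{sample_id}
#'   column (plus e.g. \code{group, age, sex, bmi_sds}).
#' @return A \code{profile_matrix} (see [profile_matrix()]).
#' @export
bin_dataset <- function(spectra, rt, meta = NULL) {
  if (length(spectra) == 0) stopf("empty dataset")
  ids <- names(spectra) %||% paste0("S", seq_along(spectra))
  if (is.null(names(spectra))) names(spectra) <- ids
  rows <- lapply(ids, function(id) {
    tryCatch(integrate_spectrum(spectra[[id]], rt),
             error = function(e) stopf("sample '%s': %s", id, conditionMessage(e)))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  profile_matrix(X, meta = meta, region_ids = rt$var_id)
}

#' Samples-by-regions profile matrix
#'
#' The central data container: an N x K numeric matrix of region integrals
#' (rows = samples, columns = \code{var_<id>}) with optional sample
#' metadata.
#'
#' @param X Numeric matrix; rownames are sample ids.
#' @param meta Optional data frame with \code{sample_id} matching rownames.
#' @param region_ids Integer var_ids in column order.
#' @export
profile_matrix <- function(X, meta = NULL, region_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(region_ids)) {
    if (!is.null(colnames(X)) && all(grepl("^var_\\d+$", colnames(X))))
      region_ids <- as.integer(sub("^var_", "", colnames(X)))
    else region_ids <- seq_len(ncol(X))
  }
  colnames(X) <- paste0("var_", region_ids)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (!is.null(meta)) {
    if (!"sample_id" %in% names(meta)) stopf("metadata lacks sample_id column")
    idx <- match(rownames(X), meta$sample_id)
    if (anyNA(idx))
      stopf("metadata missing sample(s): %s",
            paste(rownames(X)[is.na(idx)], collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(X = X, meta = meta, region_ids = as.integer(region_ids)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile matrix: %d samples x %d regions\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$meta) && "group" %in% names(x$meta))
    print(table(x$meta$group))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$X)

#' Drop glucose-related regions from a profile matrix
#'
#' Removes the columns whose regions carry \code{is_glucose = TRUE},
#' reducing the packaged default scheme from 110 to 95 variables; used to
#' refit the classifier without the dominant glucose signals.
#'
#' @param pm A \code{profile_matrix} aligned with \code{rt}.
#' @param rt The \code{region_table} that produced \code{pm}.
#' @return A \code{profile_matrix} with the glucose columns removed.
#' @export
exclude_glucose <- function(pm, rt) {
  stopifnot(inherits(pm, "profile_matrix"), inherits(rt, "region_table"))
  if (!identical(pm$region_ids, rt$var_id))
    stopf("profile matrix columns do not align with region table")
  keep <- !rt$is_glucose
  if (!any(keep)) stopf("no variables remain after glucose exclusion")
  profile_matrix(pm$X[, keep, drop = FALSE], meta = pm$meta,
                 region_ids = rt$var_id[keep])
}
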