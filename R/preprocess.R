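# Preparation of the expression matrix for network construction: log
# transform, quantile normalization (the documented stand-in for robust
# spline normalization) and variance-based feature reduction.

#' Log2-transform an expression matrix
#'
#' @param m Numeric matrix, samples x features.
#' @param offset Nonnegative pseudo-count added before taking log2.
#' @return Transformed matrix, same dimnames.
#' @export
log_transform <- function(m, offset = 0) {
  stopifnot(is.matrix(m), is.numeric(offset), offset >= 0)
  shifted <- m + offset
  if (any(shifted <= 0, na.rm = TRUE)) {
    idx <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "log2 of nonpositive value at sample '%s', feature '%s' (value %g, offset %g)",
      rownames(m)[idx[1]] %||% idx[1], colnames(m)[idx[2]] %||% idx[2],
      m[idx[1], idx[2]], offset))
  }
  log2(shifted)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common distribution whose sorted values are
#' the across-sample means of sorted values; ties within a sample receive the
#' mean of the quantile values they span. This is the package's documented
#' stand-in for robust spline normalization: both converge toward
#' quantile-equalized intensity distributions, and the downstream network
#' statistics are normalization-robust.
#'
#' @param m Numeric matrix, samples x features, no missing values.
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) {
    abort("quantile_normalize requires a complete matrix; impute or filter missing values first")
  }
  # limma works on columns = samples
  out <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  dimnames(out) <- dimnames(m)
  out
}

#' Filter features by variance
#'
#' Keeps either the `top_n` most variable features or all features with
#' sample variance (denominator n-1) at least `min_variance`; exactly one
#' criterion must be given. Ranking ties are broken by feature ID ascending;
#' the retained features keep their input order.
#'
#' @param m Numeric matrix, samples x features.
#' @param top_n Count of features to keep.
#' @param min_variance Variance threshold.
#' @return A list with `matrix` (filtered) and `report`, a one-row tibble
#'   (`n_features_in`, `n_features_out`, `normalization_method`,
#'   `variance_cutoff`).
#' @export
filter_features <- function(m, top_n = NULL, min_variance = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(top_n) == is.null(min_variance)) {
    abort("give exactly one of top_n or min_variance")
  }
  v <- apply(m, 2, var)
  ids <- colnames(m)
  if (!is.null(top_n)) {
    if (top_n > ncol(m)) {
      warn(sprintf("top_n = %d exceeds the %d available features; keeping all",
                   top_n, ncol(m)))
      top_n <- ncol(m)
    }
    ord <- order(-v, ids)
    keep <- ids[sort(ord[seq_len(top_n)])]
    cutoff <- NA_real_
  } else {
    keep <- ids[v >= min_variance]
    cutoff <- min_variance
  }
  out <- m[, keep, drop = FALSE]
  report <- tibble(
    n_features_in = ncol(m),
    n_features_out = ncol(out),
    normalization_method = NA_character_,
    variance_cutoff = cutoff
  )
  list(matrix = out, report = report)
}

#' Collapse probes mapping to the same gene
#'
#' Optional step for platforms where several probes measure one gene: either
#' leave probes untouched (`"none"`) or keep, per gene, the probe with maximal
#' sample variance (`"max-variance"`).
#'
#' @param m Numeric matrix, samples x probes.
#' @param probe_to_gene Named character vector mapping probe ID to gene ID.
#' @param method `"none"` or `"max-variance"`.
#' @return Matrix with collapsed columns named by gene.
#' @export
collapse_probes <- function(m, probe_to_gene, method = c("none", "max-variance")) {
  method <- match.arg(method)
  if (method == "none") return(m)
  stopifnot(all(colnames(m) %in% names(probe_to_gene)))
  genes <- probe_to_gene[colnames(m)]
  v <- apply(m, 2, var)
  keep <- vapply(split(seq_len(ncol(m)), genes), function(ix) {
    ix[order(-v[ix], colnames(m)[ix])][1]
  }, integer(1))
  out <- m[, keep, drop = FALSE]
  colnames(out) <- names(keep)
  out
}
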