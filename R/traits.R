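# Eigengene-trait and feature-trait association: correlation with
# pairwise-complete handling of missing trait values, two-sided p-values from
# the t transform of the correlation, and an optional normality-switched
# choice between Pearson and Spearman.

#' Two-sided p-value for a correlation coefficient
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student t distribution
#' with `n - 2` degrees of freedom; `|r| = 1` gives p = 0. Vectorized over
#' `r` and `n`.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param n Number(s) of paired observations, >= 3.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3, na.rm = TRUE)) abort("correlation_pvalue needs n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  if (length(n) == 1) n <- rep(n, length(r))
  t_stat <- r[ok] * sqrt(n[ok] - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * pt(-abs(t_stat), df = n[ok] - 2)
  p
}

#' Choose Pearson or Spearman by a normality check
#'
#' Shapiro-Wilk at alpha = 0.05: `"pearson"` if the data look Gaussian,
#' `"spearman"` otherwise. Callers applying this pairwise should use Pearson
#' only when both variables pass.
#'
#' @param x Numeric vector with at least 3 finite values.
#' @param alpha Significance level of the normality test (default 0.05).
#' @return `"pearson"` or `"spearman"`.
#' @export
auto_method <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) abort("auto_method needs at least 3 finite values")
  if (var(x) == 0) abort("normality is undefined for a constant vector")
  if (length(x) > 5000) x <- x[seq_len(5000)]
  if (shapiro.test(x)$p.value >= alpha) "pearson" else "spearman"
}

.pair_method <- function(x, y, method) {
  if (method != "auto") return(method)
  if (auto_method(x) == "pearson" && auto_method(y) == "pearson") {
    "pearson"
  } else {
    "spearman"
  }
}

.cor_cell <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n, method = NA_character_))
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) {
    warn("constant variable in correlation; r reported as 0")
    return(list(r = 0, p = 1, n = n, method = method))
  }
  meth <- .pair_method(x, y, method)
  r <- cor(x, y, method = meth)
  list(r = r, p = correlation_pvalue(r, n), n = n, method = meth)
}

.eigengene_matrix <- function(e) {
  if (inherits(e, "coex_eigengenes")) e$eigengenes else as.matrix(e)
}

#' Correlate module eigengenes with quantitative traits
#'
#' The module-trait matrix: per (module, trait) pair, samples with a missing
#' trait value are dropped pairwise and the correlation, its two-sided
#' p-value, the sample count used and the method are recorded. Cells with
#' fewer than 3 complete pairs are omitted.
#'
#' @param eig A `coex_eigengenes` object (or a samples x modules matrix with
#'   sample IDs as rownames).
#' @param traits Trait tibble with a `sample_id` column.
#' @param method `"pearson"` (default), `"spearman"`, or `"auto"`
#'   (Shapiro-Wilk switch applied pairwise).
#' @param p_adjust `"none"` (default; raw p-values are reported) or `"BH"`.
#' @return A `coex_module_trait` tibble: `module`, `trait`, `r`, `p`
#'   (and `p_adj` when requested), `n_used`, `method`.
#' @export
correlate_with_traits <- function(eig, traits,
                                  method = c("pearson", "spearman", "auto"),
                                  p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  E <- .eigengene_matrix(eig)
  shared <- intersect(rownames(E), traits$sample_id)
  if (!length(shared)) abort("no shared samples between eigengenes and traits")
  E <- E[shared, , drop = FALSE]
  tv <- as.data.frame(traits[match(shared, traits$sample_id), -1, drop = FALSE])
  grid <- tidyr::expand_grid(module = colnames(E), trait = names(tv))
  out <- purrr::pmap(grid, function(module, trait) {
    cell <- .cor_cell(E[, module], tv[[trait]], method)
    tibble(module = module, trait = trait, r = cell$r, p = cell$p,
           n_used = cell$n, method = cell$method)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$n_used >= 3)
  if (!nrow(out)) abort("no (module, trait) cell has >= 3 complete pairs")
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("coex_module_trait", class(out))
  out
}

#' Gene significance: per-feature correlation with one trait
#'
#' @param m Numeric matrix, samples x features.
#' @param traits Trait tibble with a `sample_id` column.
#' @param trait Name of the trait column to correlate against.
#' @param method `"pearson"` (default), `"spearman"` or `"auto"`.
#' @return A `coex_gene_significance` tibble: `feature_id`, `gs`, `p`,
#'   `n_used`; attributes `trait` and `method`.
#' @export
gene_significance <- function(m, traits, trait,
                              method = c("pearson", "spearman", "auto")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (!trait %in% names(traits)) {
    abort(sprintf("unknown trait '%s'; available: %s", trait,
                  paste(setdiff(names(traits), "sample_id"), collapse = ", ")))
  }
  shared <- intersect(rownames(m), traits$sample_id)
  if (length(shared) < 3) abort("fewer than 3 shared samples")
  x <- m[shared, , drop = FALSE]
  tv <- traits[[trait]][match(shared, traits$sample_id)]
  cells <- purrr::map(colnames(x), function(g) {
    if (var(x[, g]) == 0) {
      warn(sprintf("constant feature '%s' assigned gene significance 0", g))
      return(tibble(feature_id = g, gs = 0, p = 1, n_used = sum(is.finite(tv))))
    }
    cell <- .cor_cell(x[, g], tv, method)
    tibble(feature_id = g, gs = cell$r, p = cell$p, n_used = cell$n)
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "trait") <- trait
  attr(out, "method") <- method
  class(out) <- c("coex_gene_significance", class(out))
  out
}

#' @export
#' @method tidy coex_module_trait
tidy.coex_module_trait <- function(x, ...) as_tibble(unclass(x))

#' @export
#' @method glance coex_module_trait
glance.coex_module_trait <- function(x, ...) {
  tibble(n_modules = dplyr::n_distinct(x$module),
         n_traits = dplyr::n_distinct(x$trait),
         min_p = min(x$p, na.rm = TRUE),
         max_abs_r = max(abs(x$r), na.rm = TRUE))
}

#' Module-trait heatmap
#'
#' Tile heatmap of eigengene-trait correlations, each cell annotated with r
#' and the p-value in parentheses.
#'
#' @param object A `coex_module_trait` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot coex_module_trait
autoplot.coex_module_trait <- function(object, ...) {
  df <- tidy(object)
  df$label <- sprintf("%.2f\n(%.1g)", df$r, df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "darkred", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}
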