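# Module detection: average-linkage clustering of TOM dissimilarity, static
# tree cut with a minimum module size, module eigengenes (first principal
# component of the standardized module expression), module membership (kME)
# and eigengene-based module merging.
#
# Features not assigned to any module carry the reserved label "grey".
# Modules are labelled "M1", "M2", ... in decreasing size order, ties broken
# by the lexicographically smallest member feature ID.

GREY_LABEL <- "grey"

#' Cluster features on TOM dissimilarity
#'
#' Average-linkage agglomerative clustering of `1 - TOM`.
#'
#' @param tom Topological overlap matrix (features x features).
#' @return An [stats::hclust] tree whose labels are the feature IDs.
#' @export
cluster_features <- function(tom) {
  stopifnot(is.matrix(tom))
  if (ncol(tom) < 2) abort("need at least 2 features to cluster")
  hclust(as.dist(1 - tom), method = "average")
}

.relabel_by_size <- function(feature_id, raw_label) {
  # raw_label: arbitrary cluster codes with NA for grey
  keep <- !is.na(raw_label)
  sizes <- table(raw_label[keep])
  firsts <- vapply(split(feature_id[keep], raw_label[keep]),
                   function(f) min(f), character(1))
  ord <- names(sizes)[order(-as.integer(sizes), firsts[names(sizes)])]
  new <- setNames(paste0("M", seq_along(ord)), ord)
  out <- rep(GREY_LABEL, length(feature_id))
  out[keep] <- new[as.character(raw_label[keep])]
  out
}

#' Cut the dendrogram into modules
#'
#' Static height cut: branches joined below `height` on the `1 - TOM` scale
#' form clusters; clusters smaller than `min_size` are relabelled grey.
#'
#' @param dend An [stats::hclust] tree from [cluster_features()].
#' @param height Cut height in (0, 1); default 0.95.
#' @param min_size Minimum module size; default 30.
#' @return A `coex_module_assignment` tibble: `feature_id`, `module`.
#' @export
cut_tree <- function(dend, height = 0.95, min_size = 30) {
  stopifnot(inherits(dend, "hclust"))
  if (height <= 0 || height >= 1) abort("height must lie in (0, 1)")
  cl <- cutree(dend, h = height)
  ids <- dend$labels %||% as.character(seq_along(cl))
  sizes <- table(cl)
  raw <- ifelse(sizes[as.character(cl)] >= min_size, cl, NA)
  out <- tibble(feature_id = ids, module = .relabel_by_size(ids, raw))
  class(out) <- c("coex_module_assignment", class(out))
  out
}

.module_members <- function(assignment, include_grey = FALSE) {
  a <- assignment
  if (!include_grey) a <- a[a$module != GREY_LABEL, ]
  split(a$feature_id, a$module)
}

.eigengene_one <- function(xs, members, module) {
  # xs: standardized expression of the module, samples x members
  pc <- svd(xs, nu = 1, nv = 0)
  e <- pc$u[, 1] * pc$d[1]
  ve <- pc$d[1]^2 / sum(pc$d^2)
  e <- e / sd(e)
  avg <- rowMeans(xs)
  ref <- if (sd(avg) > 0) avg else xs[, order(members)[1]]
  orient <- cor(e, ref)
  if (is.na(orient) || abs(orient) < 1e-12) {
    orient <- cor(e, xs[, order(members)[1]])
  }
  if (orient < 0) e <- -e
  list(e = e, ve = ve)
}

#' Module eigengenes
#'
#' Per non-grey module: features are standardized (mean 0, sd 1 across
#' samples) and summarized by their first principal component across samples,
#' scaled to unit variance. The sign is oriented so the eigengene correlates
#' positively with the module's average standardized profile (falling back to
#' the lexicographically smallest member feature when the average is
#' degenerate). Variance explained is the leading eigenvalue share.
#'
#' @param m Numeric matrix, samples x features, no missing values.
#' @param assignment A `coex_module_assignment` tibble.
#' @return A `coex_eigengenes` object: list with `eigengenes` (matrix,
#'   samples x modules), `var_explained` (named numeric) and `assignment`.
#' @export
compute_eigengenes <- function(m, assignment) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) abort("compute_eigengenes requires a complete matrix")
  members <- .module_members(assignment)
  if (!length(members)) abort("no non-grey modules to summarize")
  bad <- names(members)[lengths(members) < 2]
  if (length(bad)) {
    abort(sprintf("module(s) with fewer than 2 features: %s",
                  paste(bad, collapse = ", ")))
  }
  res <- purrr::imap(members, function(f, module) {
    x <- m[, f, drop = FALSE]
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("module %s contains constant feature(s): %s", module,
                    paste(head(f[sds == 0], 5), collapse = ", ")))
    }
    .eigengene_one(scale(x), f, module)
  })
  labels <- names(members)[order(as.integer(sub("^M", "", names(members))))]
  E <- vapply(labels, function(l) res[[l]]$e, numeric(nrow(m)))
  rownames(E) <- rownames(m)
  structure(list(
    eigengenes = E,
    var_explained = vapply(labels, function(l) res[[l]]$ve, numeric(1)),
    assignment = assignment
  ), class = "coex_eigengenes")
}

#' Module membership (kME)
#'
#' Pearson correlation of each feature's profile with each module eigengene.
#'
#' @param m Numeric matrix, samples x features.
#' @param eig A `coex_eigengenes` object.
#' @return Numeric matrix, features x modules.
#' @export
module_membership <- function(m, eig) {
  stopifnot(is.matrix(m), inherits(eig, "coex_eigengenes"))
  constant <- apply(m, 2, function(v) var(v) == 0)
  kme <- suppressWarnings(cor(m, eig$eigengenes))
  if (any(constant)) {
    warn(sprintf("%d constant feature(s) assigned kME 0", sum(constant)))
    kme[constant, ] <- 0
  }
  kme
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene correlation
#' is at least `1 - max_dissimilarity`, recomputing eigengenes after every
#' merge, until no pair qualifies. Final modules are relabelled by size.
#'
#' @param m Numeric matrix, samples x features (needed to recompute
#'   eigengenes after each merge).
#' @param assignment A `coex_module_assignment` tibble.
#' @param eigengenes Optional precomputed `coex_eigengenes` for the input
#'   assignment (recomputed if omitted).
#' @param max_dissimilarity Merge threshold on `1 - cor(E_a, E_b)`;
#'   default 0.2.
#' @return List with `assignment` and `eigengenes` after merging.
#' @export
merge_similar_modules <- function(m, assignment, eigengenes = NULL,
                                  max_dissimilarity = 0.2) {
  stopifnot(is.matrix(m))
  if (!length(.module_members(assignment))) abort("no modules to merge")
  asg <- assignment
  eig <- eigengenes %||% compute_eigengenes(m, asg)
  repeat {
    E <- eig$eigengenes
    if (ncol(E) < 2) break
    cc <- cor(E)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] < 1 - max_dissimilarity) break
    keep_lab <- colnames(E)[min(best)]
    drop_lab <- colnames(E)[max(best)]
    asg$module[asg$module == drop_lab] <- keep_lab
    eig <- compute_eigengenes(m, asg)
  }
  # canonical relabel by size
  raw <- ifelse(asg$module == GREY_LABEL, NA, asg$module)
  asg$module <- .relabel_by_size(asg$feature_id, raw)
  class(asg) <- unique(c("coex_module_assignment", class(asg)))
  list(assignment = asg, eigengenes = compute_eigengenes(m, asg))
}

#' @export
#' @method print coex_eigengenes
print.coex_eigengenes <- function(x, ...) {
  cat(sprintf("<coex_eigengenes> %d modules x %d samples\n",
              ncol(x$eigengenes), nrow(x$eigengenes)))
  ve <- format(round(x$var_explained, 3))
  cat("  variance explained:",
      paste(sprintf("%s=%s", colnames(x$eigengenes), ve), collapse = " "), "\n")
  invisible(x)
}

#' Tidy module eigengenes
#'
#' @param x A `coex_eigengenes` object.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `module`, `eigengene`.
#' @export
#' @method tidy coex_eigengenes
tidy.coex_eigengenes <- function(x, ...) {
  as_tibble(x$eigengenes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module",
                        values_to = "eigengene")
}

#' @export
#' @method glance coex_eigengenes
glance.coex_eigengenes <- function(x, ...) {
  tibble(n_modules = ncol(x$eigengenes),
         n_samples = nrow(x$eigengenes),
         min_var_explained = min(x$var_explained),
         median_var_explained = median(x$var_explained))
}

#' Module size summary with color aliases
#'
#' Reports non-grey module sizes and, for familiarity with the conventional
#' color labelling of co-expression modules, a stable color alias per label.
#'
#' @param assignment A `coex_module_assignment` tibble.
#' @return Tibble: `module`, `size`, `color_alias`.
#' @export
module_sizes <- function(assignment) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue")
  sizes <- assignment |>
    dplyr::filter(.data$module != GREY_LABEL) |>
    dplyr::count(.data$module, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$module)
  idx <- seq_len(nrow(sizes))
  sizes$color_alias <- ifelse(idx <= length(palette), palette[idx],
                              paste0("color", idx))
  sizes
}
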