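# Candidate nomination: hub ranking inside a trait-correlated module
# (gene significance combined with intramodular centrality), dual Pearson/MIC
# top-k ranking against a trait with intersection and gene-set annotation,
# and the one-sided hypergeometric set-overlap test.

#' Intramodular connectivity (kIM)
#'
#' Sum of a feature's adjacency to the other members of its module.
#'
#' @param a Adjacency (or TOM) matrix, features x features.
#' @param assignment A `coex_module_assignment` tibble.
#' @param module Module label.
#' @return Named numeric vector of kIM over the module members.
#' @export
intramodular_connectivity <- function(a, assignment, module) {
  stopifnot(is.matrix(a))
  members <- assignment$feature_id[assignment$module == module]
  if (!length(members)) {
    abort(sprintf("unknown or empty module '%s'; available: %s", module,
                  paste(setdiff(unique(assignment$module), GREY_LABEL),
                        collapse = ", ")))
  }
  if (length(members) < 2) abort(sprintf("module '%s' has fewer than 2 members", module))
  sub <- a[members, members, drop = FALSE]
  colSums(sub) - diag(sub)
}

#' Rank module members by gene significance and centrality
#'
#' Members are ranked by `|gs|` descending (gene significance rank) and by
#' centrality descending; the combined score is the mean of the two ranks and
#' the combined rank orders by ascending score, ties broken by the better
#' gene-significance rank, then by feature ID.
#'
#' @param gs A `coex_gene_significance` tibble (or any tibble with
#'   `feature_id` and `gs`).
#' @param centrality Named numeric vector (kIM or kME) over the module
#'   members.
#' @param members Character vector of module member feature IDs.
#' @return A `coex_hub_ranking` tibble: `feature_id`, `gs`, `centrality`,
#'   `gs_rank`, `centrality_rank`, `combined_score`, `combined_rank`, sorted
#'   by `combined_rank`.
#' @export
rank_hub_genes <- function(gs, centrality, members) {
  if (!length(members)) abort("empty module")
  if (!all(members %in% gs$feature_id)) {
    abort("gene significance missing for some module members")
  }
  if (!all(members %in% names(centrality))) {
    abort("centrality missing for some module members")
  }
  df <- tibble(
    feature_id = members,
    gs = gs$gs[match(members, gs$feature_id)],
    centrality = unname(centrality[members])
  )
  df$gs_rank <- order(order(-abs(df$gs), df$feature_id))
  df$centrality_rank <- order(order(-df$centrality, df$feature_id))
  df$combined_score <- (df$gs_rank + df$centrality_rank) / 2
  ord <- order(df$combined_score, df$gs_rank, df$feature_id)
  df$combined_rank <- order(ord)
  df <- df[ord, ]
  class(df) <- c("coex_hub_ranking", class(df))
  df
}

#' Annotate a feature list against gene sets
#'
#' @param features Character vector of feature IDs.
#' @param sets Named list of character vectors (see [read_gene_sets()]).
#' @param normalize_ids If `TRUE`, match case-insensitively by uppercasing
#'   both sides; default is case-sensitive matching.
#' @return Tibble: `set`, `n_hits`, `fraction` (of the feature list), `hits`
#'   (list-column of matching feature IDs).
#' @export
annotate_overlap <- function(features, sets, normalize_ids = FALSE) {
  norm <- if (normalize_ids) toupper else identity
  rows <- purrr::imap(sets, function(members, nm) {
    hit <- features[norm(features) %in% norm(members)]
    tibble(set = nm, n_hits = length(hit),
           fraction = if (length(features)) length(hit) / length(features) else 0,
           hits = list(hit))
  })
  dplyr::bind_rows(rows)
}

#' Dual Pearson/MIC ranking of features against a trait
#'
#' Computes, per feature, the Pearson correlation (pairwise-complete) and the
#' maximal information coefficient with the target; takes the top-k features
#' under `|pcc|` and under MIC (descending; ties broken by feature ID), marks
#' their intersection, and annotates both lists against optional gene sets.
#' Features with fewer than 8 complete pairs are excluded with a warning (the
#' MIC grid needs that resolution).
#'
#' @param x Numeric matrix, samples x features.
#' @param target Numeric trait vector, one value per sample (NA allowed).
#' @param k List length (default 100, as in a top-100 candidate list).
#' @param gene_sets Optional named list of gene sets for annotation.
#' @param alpha,c MIC parameters (see [mic()]).
#' @param normalize_ids Case-insensitive annotation matching if `TRUE`.
#' @return A `coex_dual_ranking` object: list with `scores` (tibble:
#'   `feature_id`, `pcc`, `mic`, `pcc_rank`, `mic_rank`), `top_pcc`,
#'   `top_mic`, `intersection` (character vectors), `k`, and `annotation`
#'   (tibble or NULL).
#' @export
dual_rank_features <- function(x, target, k = 100, gene_sets = NULL,
                               alpha = 0.6, c = 15, normalize_ids = FALSE) {
  stopifnot(is.matrix(x), length(target) == nrow(x))
  if (k > ncol(x)) abort("k exceeds the number of features")
  n_pairs <- colSums(is.finite(x) & is.finite(target))
  drop <- colnames(x)[n_pairs < 8]
  if (length(drop)) {
    warn(sprintf("%d feature(s) with fewer than 8 complete pairs excluded: %s",
                 length(drop), paste(head(drop, 5), collapse = ", ")))
    x <- x[, setdiff(colnames(x), drop), drop = FALSE]
    if (k > ncol(x)) k <- ncol(x)
  }
  scores <- purrr::map(colnames(x), function(g) {
    ok <- is.finite(x[, g]) & is.finite(target)
    v <- x[ok, g]
    t_ok <- target[ok]
    pcc <- if (var(v) == 0 || var(t_ok) == 0) 0 else cor(v, t_ok)
    m <- suppressWarnings(mic(v, t_ok, alpha = alpha, c = c)$mic)
    tibble(feature_id = g, pcc = pcc, mic = m)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$feature_id)
  scores$pcc_rank <- order(order(-abs(scores$pcc), scores$feature_id))
  scores$mic_rank <- order(order(-scores$mic, scores$feature_id))
  top_pcc <- scores$feature_id[order(scores$pcc_rank)][seq_len(k)]
  top_mic <- scores$feature_id[order(scores$mic_rank)][seq_len(k)]
  both <- intersect(top_pcc, top_mic)
  annotation <- NULL
  if (!is.null(gene_sets)) {
    annotation <- dplyr::bind_rows(
      dplyr::mutate(annotate_overlap(top_pcc, gene_sets, normalize_ids), list = "pcc"),
      dplyr::mutate(annotate_overlap(top_mic, gene_sets, normalize_ids), list = "mic")
    )
  }
  structure(list(scores = scores, top_pcc = top_pcc, top_mic = top_mic,
                 intersection = both, k = k, annotation = annotation),
            class = "coex_dual_ranking")
}

#' @export
#' @method print coex_dual_ranking
print.coex_dual_ranking <- function(x, ...) {
  cat(sprintf("<coex_dual_ranking> %d features, top-%d lists, %d in intersection\n",
              nrow(x$scores), x$k, length(x$intersection)))
  invisible(x)
}

#' @export
#' @method tidy coex_dual_ranking
tidy.coex_dual_ranking <- function(x, ...) {
  dplyr::mutate(x$scores,
                in_top_pcc = .data$feature_id %in% x$top_pcc,
                in_top_mic = .data$feature_id %in% x$top_mic)
}

#' @export
#' @method glance coex_dual_ranking
glance.coex_dual_ranking <- function(x, ...) {
  tibble(n_features = nrow(x$scores), k = x$k,
         n_intersection = length(x$intersection))
}

#' Pearson vs MIC score scatter
#'
#' @param object A `coex_dual_ranking` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot coex_dual_ranking
autoplot.coex_dual_ranking <- function(object, ...) {
  df <- tidy(object)
  df$list <- dplyr::case_when(
    df$in_top_pcc & df$in_top_mic ~ "both",
    df$in_top_pcc ~ "pcc only",
    df$in_top_mic ~ "mic only",
    TRUE ~ "neither"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$pcc), y = .data$mic,
                                   colour = .data$list)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "|Pearson r|", y = "MIC", colour = sprintf("top-%d", object$k))
}

#' One-sided hypergeometric set-overlap test
#'
#' Upper-tail probability of observing at least `k` shared members between a
#' set of size `K` and a set of size `n` drawn from a universe of size `N`,
#' plus the fold enrichment `(k / n) / (K / N)`.
#'
#' @param k Observed overlap.
#' @param K Size of the first set (e.g. a module geneset).
#' @param n Size of the second set (e.g. a differential-expression list).
#' @param N Universe size.
#' @return A `coex_overlap_test` one-row tibble: `k`, `K`, `n`, `N`,
#'   `p_value`, `fold_enrichment`.
#' @export
#' @examples
#' hypergeometric_overlap(47, 1000, 514, 20000)
hypergeometric_overlap <- function(k, K, n, N) {
  if (K > N || n > N) abort("set sizes cannot exceed the universe size")
  if (k > min(K, n)) abort("overlap cannot exceed the smaller set size")
  if (k < max(0, K + n - N)) {
    abort("overlap below the minimum forced by the set and universe sizes")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (k == 0) 0 else (k / n) / (K / N)
  out <- tibble(k = k, K = K, n = n, N = N, p_value = p,
                fold_enrichment = fold)
  class(out) <- c("coex_overlap_test", class(out))
  out
}
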