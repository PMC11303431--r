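# Weighted co-expression network construction: correlation, soft-threshold
# selection by scale-free topology fit, adjacency, topological overlap.
#
# Adjacency follows the weighted-network convention:
#   unsigned  a_ij = |cor(x_i, x_j)|^beta
#   signed    a_ij = ((1 + cor(x_i, x_j)) / 2)^beta
# and the topological overlap of nodes i != j is
#   TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
#   l_ij = sum_{u != i,j} a_iu a_uj,  k_i = sum_{j != i} a_ij.

.MAX_NETWORK_FEATURES <- 20000L

#' Feature-feature correlation matrix
#'
#' @param m Numeric matrix, samples x features, no missing values.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix (features x features). Constant
#'   features correlate 0 with everything (flagged in the
#'   `constant_features` attribute, with a warning) and 1 with themselves.
#' @export
correlation_matrix <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (nrow(m) < 3) abort("correlation_matrix needs at least 3 samples")
  if (anyNA(m)) abort("correlation_matrix requires a complete matrix")
  if (ncol(m) > .MAX_NETWORK_FEATURES) {
    abort(sprintf("%d features exceeds the %d dense-matrix guard; filter first",
                  ncol(m), .MAX_NETWORK_FEATURES))
  }
  constant <- apply(m, 2, function(v) var(v) == 0)
  cc <- suppressWarnings(cor(m, method = method))
  if (any(constant)) {
    warn(sprintf("%d constant feature(s) assigned zero correlation: %s",
                 sum(constant),
                 paste(head(colnames(m)[constant], 5), collapse = ", ")))
    cc[constant, ] <- 0
    cc[, constant] <- 0
  }
  diag(cc) <- 1
  attr(cc, "constant_features") <- colnames(m)[constant]
  cc
}

#' Soft-thresholded adjacency
#'
#' @param c Correlation matrix with entries in \[-1, 1\].
#' @param power Soft-threshold exponent, >= 1.
#' @param signed If `TRUE` use the signed transform `((1 + cor)/2)^power`;
#'   default is the unsigned `|cor|^power`.
#' @return Adjacency matrix with entries in \[0, 1\], unit diagonal, and
#'   attributes `power` and `signed`.
#' @export
adjacency <- function(c, power, signed = FALSE) {
  stopifnot(is.matrix(c))
  if (power < 1) abort("power must be >= 1")
  if (any(c < -1 - 1e-8 | c > 1 + 1e-8, na.rm = TRUE)) {
    abort("correlation entries must lie in [-1, 1]")
  }
  a <- if (signed) ((1 + c) / 2)^power else abs(c)^power
  diag(a) <- 1
  attr(a, "power") <- power
  attr(a, "signed") <- signed
  attr(a, "constant_features") <- attr(c, "constant_features")
  a
}

.scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) == 1) {
    warn("all connectivities equal; scale-free fit R^2 reported as 0")
    return(c(r_squared = 0, slope = NA_real_))
  }
  # equal-width connectivity bins: bin frequency then reflects the degree
  # density, which is what a power law constrains
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bins <- cut(k, breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  keep <- !is.na(mean_k) & mean_k > 0 & freq > 0
  if (sum(keep) < 2) {
    warn("fewer than 2 usable connectivity bins; scale-free fit R^2 reported as 0")
    return(c(r_squared = 0, slope = NA_real_))
  }
  fit <- lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  c(r_squared = -sign(slope) * r2, slope = slope)
}

#' Scan candidate soft-threshold powers
#'
#' For each candidate power, builds the adjacency and summarizes how well the
#' connectivity distribution follows a power law: connectivities are split
#' into 10 equal-count bins, log10 mean frequency is regressed on log10 mean
#' connectivity, and the fit R^2 is reported with the sign of the slope
#' negated ("signed R^2"; a scale-free topology has a negative slope, hence a
#' positive signed R^2).
#'
#' @param m Numeric matrix, samples x features.
#' @param powers Candidate powers (default 1:10 and even values to 20).
#' @param signed Use the signed adjacency transform.
#' @param method Correlation method.
#' @return A `coex_sft` tibble: `power`, `r_squared`, `slope`, `mean_k`,
#'   `median_k`, `max_k`.
#' @export
scan_soft_threshold <- function(m, powers = c(1:10, 12, 14, 16, 18, 20),
                                signed = FALSE,
                                method = c("pearson", "spearman")) {
  if (!length(powers)) abort("powers must be nonempty")
  cc <- correlation_matrix(m, method = match.arg(method))
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(base) <- 0
  rows <- purrr::map(powers, function(p) {
    k <- colSums(base^p)
    fit <- .scale_free_fit(k)
    tibble(power = p, r_squared = unname(fit["r_squared"]),
           slope = unname(fit["slope"]),
           mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coex_sft", class(out))
  out
}

#' Pick the soft-threshold power from a scan
#'
#' The smallest power whose signed scale-free R^2 reaches `r2_cut`, considering
#' only powers that keep the mean connectivity at or above `min_mean_k`
#' (a network whose average node has fewer than ~2 units of connectivity is
#' effectively disconnected, and both the scale-free fit and downstream
#' clustering become meaningless there). If no admissible power reaches the
#' cutoff, the largest admissible power is returned with a warning: the
#' strongest noise suppression compatible with a non-degenerate network.
#'
#' @param scan A `coex_sft` tibble from [scan_soft_threshold()].
#' @param r2_cut Signed R^2 cutoff (default 0.8).
#' @param min_mean_k Mean-connectivity floor (default 2).
#' @return The selected power (scalar). Attribute `reached_cut` records
#'   whether the cutoff was met.
#' @export
pick_power <- function(scan, r2_cut = 0.8, min_mean_k = 2) {
  if (!nrow(scan)) abort("empty soft-threshold scan")
  admissible <- scan$mean_k >= min_mean_k
  if (!any(admissible)) {
    warn(sprintf(
      "no power keeps mean connectivity >= %g; considering the densest power only",
      min_mean_k))
    admissible <- scan$mean_k == max(scan$mean_k)
  }
  cand <- scan[admissible, ]
  ok <- which(cand$r_squared >= r2_cut)
  if (length(ok)) {
    p <- cand$power[ok[1]]
    reached <- TRUE
  } else {
    p <- max(cand$power)
    reached <- FALSE
    warn(sprintf(
      paste0("no admissible power reached signed R^2 >= %.2f; ",
             "using the largest power with mean connectivity >= %g (power %g, R^2 = %.3f)"),
      r2_cut, min_mean_k, p, cand$r_squared[cand$power == p]))
  }
  structure(p, reached_cut = reached)
}

#' Topological overlap matrix
#'
#' Shared-neighbor similarity of a weighted adjacency. Pairs with a zero
#' denominator get TOM 0; the diagonal is 1.
#'
#' @param a Adjacency matrix (entries in \[0,1\], unit diagonal).
#' @return TOM matrix, symmetric, entries in \[0, 1\], unit diagonal.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a))
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0, 1]")
  k <- colSums(a) - diag(a)
  # (A^2)_ij counts u = i and u = j (diag 1): subtract 2 a_ij off-diagonal
  l <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom[denom <= 0] <- 0
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' @export
#' @rdname scan_soft_threshold
#' @param object,x A `coex_sft` object.
#' @param ... Unused.
#' @method tidy coex_sft
tidy.coex_sft <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Soft-threshold scan diagnostics plot
#'
#' Signed scale-free R^2 and mean connectivity against candidate power.
#'
#' @param object A `coex_sft` tibble.
#' @param r2_cut Cutoff drawn as a horizontal reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot coex_sft
autoplot.coex_sft <- function(object, r2_cut = 0.8, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tidy(object), "power", "r_squared", "mean_k"),
    c("r_squared", "mean_k"), names_to = "metric")
  ref <- tibble(metric = "r_squared", y = r2_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft-threshold power", y = NULL)
}
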