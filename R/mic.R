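# Maximal information coefficient (MIC), implemented from the published MINE
# grid search: MIC(x, y) = max over grid sizes (r, s) with r * s <= B(n),
# r, s >= 2, of I*(r, s) / log2(min(r, s)), where I*(r, s) is the largest
# empirical mutual information achievable by an r x s grid. The maximum is
# approximated by the standard heuristic: equipartition one axis into
# equal-count bins, then optimize the other axis's partition by dynamic
# programming over clump boundaries (points that must stay together), with at
# most c * s candidate clumps; the result is the maximum over both axis
# orientations. B(n) = ceiling(n^alpha).
#
# Because the grid search depends only on the order of the data, MIC is
# exactly invariant under strictly monotone transforms of either variable.

# Assign values to q bins of near-equal count, keeping ties in one bin.
# Returns an integer vector of bin indices (1..q'; q' <= q under heavy ties).
.equipartition <- function(v, q) {
  n <- length(v)
  ord <- order(v, seq_along(v))
  assign <- integer(n)
  target <- n / q
  bin <- 1L
  in_bin <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1L]] == v[ord[i]]) j <- j + 1L
    blk <- j - i + 1L
    if (in_bin > 0L && bin < q &&
        abs(in_bin + blk - target) > abs(in_bin - target)) {
      bin <- bin + 1L
      in_bin <- 0L
    }
    assign[ord[i:j]] <- bin
    in_bin <- in_bin + blk
    i <- j + 1L
  }
  assign
}

# Additive DP contribution of one column with per-row counts cnt out of n
# points: -p log2 p + sum_r p_cr log2 p_cr (so that summing over columns and
# adding H(rows) yields the mutual information).
.column_value <- function(cnt, n) {
  p <- sum(cnt) / n
  nz <- cnt > 0L
  -p * log2(p) + sum((cnt[nz] / n) * log2(cnt[nz] / n))
}

# Given a fixed row assignment Q (1..q), find for every number of columns
# l = 2..lmax the maximal mutual information achievable by partitioning x.
# Candidate boundaries are clump edges: consecutive points (in x order) stay
# in one clump while their row label does not change or their x values are
# tied; clumps are capped at ceiling(c_factor * lmax) superclumps.
.optimize_axis <- function(x, Q, q, lmax, c_factor) {
  n <- length(x)
  ord <- order(x, seq_along(x))
  xo <- x[ord]
  Qo <- Q[ord]
  K <- 0L
  clump <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      K <- 1L
    } else if (xo[i] != xo[i - 1L] && Qo[i] != Qo[i - 1L]) {
      K <- K + 1L
    }
    clump[i] <- K
  }
  cap <- max(2L, as.integer(ceiling(c_factor * lmax)))
  if (K > cap) {
    # clump ids are nondecreasing along x order, so an equal-count
    # repartition of them merges whole clumps into size-balanced superclumps
    clump <- .equipartition(clump, cap)
    K <- max(clump)
  }
  cnt <- matrix(0L, K, q)
  for (i in seq_len(n)) cnt[clump[i], Qo[i]] <- cnt[clump[i], Qo[i]] + 1L
  ccum <- apply(cnt, 2, cumsum)
  if (K == 1L) ccum <- matrix(ccum, 1L, q)
  val <- matrix(-Inf, K + 1L, K)  # val[s + 1, t]: column spanning clumps s+1..t
  for (s in 0:(K - 1L)) {
    for (t in (s + 1L):K) {
      cc <- if (s == 0L) ccum[t, ] else ccum[t, ] - ccum[s, ]
      val[s + 1L, t] <- .column_value(cc, n)
    }
  }
  pq <- colSums(cnt) / n
  h_rows <- -sum(pq[pq > 0] * log2(pq[pq > 0]))
  lmax <- min(lmax, K)
  if (lmax < 2L) return(numeric(0))
  f <- matrix(-Inf, K, lmax)
  f[, 1L] <- val[1L, ]
  for (l in 2:lmax) {
    for (t in l:K) {
      f[t, l] <- max(f[(l - 1L):(t - 1L), l - 1L] + val[l:t, t])
    }
  }
  i_vals <- f[K, 2:lmax] + h_rows
  names(i_vals) <- 2:lmax
  i_vals
}

#' Maximal information coefficient
#'
#' @param x,y Numeric vectors of equal length; at least 8 finite pairs.
#' @param alpha Grid-budget exponent: `B(n) = ceiling(n^alpha)`; default 0.6.
#' @param c Clump factor: at most `c * s` candidate clumps when optimizing a
#'   partition into `s` bins; default 15.
#' @return A `coex_mic` object: list with `mic` in \[0, 1\], `rows`, `cols`
#'   (dimensions of the best grid), `n`, `B`, `alpha`, `c`.
#' @export
#' @examples
#' x <- seq(-2, 2, length.out = 100)
#' mic(x, x^2)$mic      # detects the parabola
#' abs(cor(x, x^2))     # Pearson is blind to it
mic <- function(x, y, alpha = 0.6, c = 15) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 8) abort("mic needs at least 8 finite pairs")
  if (var(x) == 0 || var(y) == 0) {
    warn("constant input; mic reported as 0")
    return(structure(list(mic = 0, rows = NA_integer_, cols = NA_integer_,
                          n = n, B = ceiling(n^alpha), alpha = alpha, c = c),
                     class = "coex_mic"))
  }
  B <- ceiling(n^alpha)
  best <- 0
  best_dim <- c(NA_integer_, NA_integer_)
  for (orient in 1:2) {
    if (orient == 2L) {
      tmp <- x
      x <- y
      y <- tmp
    }
    for (q in 2:max(2L, floor(B / 2))) {
      lmax <- floor(B / q)
      if (lmax < 2L) next
      Q <- .equipartition(y, q)
      qe <- max(Q)
      if (qe < 2L) next
      i_vals <- .optimize_axis(x, Q, qe, lmax, c)
      for (nm in names(i_vals)) {
        l <- as.integer(nm)
        score <- i_vals[[nm]] / log2(min(qe, l))
        if (score > best) {
          best <- score
          # rows = y-axis bins, cols = x-axis bins in the original orientation
          best_dim <- if (orient == 1L) c(qe, l) else c(l, qe)
        }
      }
    }
  }
  structure(list(mic = min(1, best), rows = best_dim[1], cols = best_dim[2],
                 n = n, B = B, alpha = alpha, c = c),
            class = "coex_mic")
}

#' Empirical mutual information of a fixed grid
#'
#' Mutual information (bits) of the 2-D histogram induced by the given bin
#' edges. Points outside the outermost edges are assigned to the boundary
#' bins (closed outer bins).
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_edges,y_edges Strictly increasing interior + outer bin edges; a
#'   vector of k edges defines k - 1 bins.
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information_grid <- function(x, y, x_edges, y_edges) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (is.unsorted(x_edges, strictly = TRUE) ||
      is.unsorted(y_edges, strictly = TRUE)) {
    abort("bin edges must be strictly increasing")
  }
  bin_of <- function(v, edges) {
    b <- findInterval(v, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), length(edges) - 1L)  # closed outer bins
  }
  xa <- bin_of(x, x_edges)
  ya <- bin_of(y, y_edges)
  n <- length(x)
  joint <- table(factor(xa, levels = seq_len(length(x_edges) - 1L)),
                 factor(ya, levels = seq_len(length(y_edges) - 1L))) / n
  pr <- rowSums(joint)
  pc <- colSums(joint)
  total <- 0
  for (i in seq_along(pr)) {
    for (j in seq_along(pc)) {
      if (joint[i, j] > 0) {
        total <- total + joint[i, j] * log2(joint[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  as.numeric(total)
}

# normalized MI of an explicit assignment pair (used by the oracle)
.nmi_assign <- function(xa, ya, r, s) {
  n <- length(xa)
  joint <- table(factor(xa, levels = seq_len(r)),
                 factor(ya, levels = seq_len(s))) / n
  pr <- rowSums(joint)
  pc <- colSums(joint)
  total <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(s)) {
      if (joint[i, j] > 0) {
        total <- total + joint[i, j] * log2(joint[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  total / log2(min(r, s))
}

.cuts_to_assign <- function(v, cut_after) {
  ord <- order(v, seq_along(v))
  n <- length(v)
  a <- integer(n)
  brk <- c(cut_after, n)
  bin <- 1L
  idx <- 1L
  for (i in seq_len(n)) {
    a[ord[i]] <- bin
    if (i == brk[idx]) {
      bin <- bin + 1L
      idx <- idx + 1L
    }
  }
  a
}

#' Exhaustive MIC oracle for tiny inputs
#'
#' Maximizes normalized mutual information over every grid with
#' `rows * cols <= max_cells` and partition boundaries between consecutive
#' sorted data values. Exponential in n; guarded at n <= 12. Intended as an
#' independent reference for testing the heuristic search in [mic()].
#'
#' @param x,y Numeric vectors, length <= 12.
#' @param max_cells Grid budget (default 16, maximum allowed 16).
#' @return The exact maximal normalized mutual information in \[0, 1\].
#' @export
mic_oracle <- function(x, y, max_cells = 16) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n > 12) abort("mic_oracle is limited to n <= 12")
  if (max_cells > 16) abort("max_cells is limited to 16")
  boundary_pos <- function(v) {
    sv <- sort(v)
    which(diff(sv) != 0)
  }
  bx <- boundary_pos(x)
  by <- boundary_pos(y)
  # combn(v, m) with a scalar v enumerates 1:v; guard with an explicit list
  choose_cuts <- function(v, m) {
    if (length(v) < m) return(list())
    if (length(v) == m) return(list(v))
    utils::combn(v, m, simplify = FALSE)
  }
  best <- 0
  for (r in 2:floor(max_cells / 2)) {
    for (s in 2:floor(max_cells / r)) {
      cuts_x <- choose_cuts(bx, r - 1)
      cuts_y <- choose_cuts(by, s - 1)
      if (!length(cuts_x) || !length(cuts_y)) next
      for (cx in cuts_x) {
        xa <- .cuts_to_assign(x, cx)
        for (cy in cuts_y) {
          ya <- .cuts_to_assign(y, cy)
          best <- max(best, .nmi_assign(xa, ya, r, s))
        }
      }
    }
  }
  min(1, best)
}

#' @export
#' @method print coex_mic
print.coex_mic <- function(x, ...) {
  cat(sprintf("MIC = %.4f (best grid %s x %s, B(n) = %d at n = %d, alpha = %g, c = %g)\n",
              x$mic, x$rows, x$cols, x$B, x$n, x$alpha, x$c))
  invisible(x)
}

#' @export
#' @method glance coex_mic
glance.coex_mic <- function(x, ...) {
  tibble(mic = x$mic, rows = x$rows, cols = x$cols, n = x$n, B = x$B,
         alpha = x$alpha, c = x$c)
}
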