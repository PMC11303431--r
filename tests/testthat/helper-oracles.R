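# Independent oracles used by the tests: each recomputes the quantity by a
# different route than the package implementation (exhaustive enumeration,
# direct summation, permutation), so agreement is evidence, not tautology.

# exhaustive hypergeometric upper tail by enumerating every draw of n items
# from a universe of N, counting how many land in the K-item set
enum_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlap <- apply(draws, 2, function(col) sum(col <= K))
  mean(overlap >= k)
}

# topological overlap by direct triple summation of the definition
tom_direct <- function(a) {
  p <- nrow(a)
  out <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      denom <- min(ki, kj) + 1 - a[i, j]
      out[i, j] <- if (denom <= 0) 0 else (l + a[i, j]) / denom
    }
  }
  out
}

# two-sided permutation p-value for a Pearson correlation
perm_pvalue <- function(x, y, n_perm = 10000, seed = 99) {
  set.seed(seed)
  obs <- abs(cor(x, y))
  hits <- sum(replicate(n_perm, abs(cor(x, sample(y))) >= obs - 1e-12))
  (hits + 1) / (n_perm + 1)
}

# plain-loop normalized MI over explicit bin assignments (independent of the
# package's internals)
nmi_plain <- function(xa, ya) {
  n <- length(xa)
  r <- max(xa)
  s <- max(ya)
  joint <- matrix(0, r, s)
  for (i in seq_len(n)) joint[xa[i], ya[i]] <- joint[xa[i], ya[i]] + 1 / n
  pr <- rowSums(joint)
  pc <- colSums(joint)
  mi <- 0
  for (a in seq_len(r)) {
    for (b in seq_len(s)) {
      if (joint[a, b] > 0) mi <- mi + joint[a, b] * log2(joint[a, b] / (pr[a] * pc[b]))
    }
  }
  mi / log2(min(r, s))
}

# small expression fixture: two perfectly separated blocks
two_block_matrix <- function(n_samples = 12, block = 4, seed = 5) {
  set.seed(seed)
  f1 <- rnorm(n_samples)
  f2 <- rnorm(n_samples)
  x <- cbind(
    sapply(seq_len(block), function(i) f1),
    sapply(seq_len(block), function(i) f2)
  )
  dimnames(x) <- list(sprintf("S%02d", seq_len(n_samples)),
                      sprintf("G%02d", seq_len(2 * block)))
  x
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# run the module-detection stage with package defaults; returns assignment,
# eigengenes and the TOM
detect_modules <- function(expr) {
  scan <- scan_soft_threshold(expr)
  p <- suppressWarnings(pick_power(scan))
  a <- suppressWarnings(adjacency(correlation_matrix(expr), as.numeric(p)))
  tom <- topological_overlap(a)
  asg <- cut_tree(cluster_features(tom))
  merged <- merge_similar_modules(expr, asg)
  list(assignment = merged$assignment, eigengenes = merged$eigengenes,
       tom = tom, power = as.numeric(p))
}
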