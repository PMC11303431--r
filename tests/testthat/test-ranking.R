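test_that("intramodular connectivity sums within-module adjacency", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  asg <- tibble::tibble(feature_id = paste0("g", 1:3), module = "M1")
  kim <- intramodular_connectivity(a, asg, "M1")
  expect_equal(unname(kim), rep(1, 3))

  a2 <- diag(3)
  dimnames(a2) <- dimnames(a)
  expect_equal(unname(intramodular_connectivity(a2, asg, "M1")), rep(0, 3))

  expect_error(intramodular_connectivity(a, asg, "M9"), "unknown")
})

test_that("intramodular connectivity matches brute-force restricted row sums", {
  set.seed(17)
  for (rep in 1:5) {
    r <- matrix(runif(64), 8, 8)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:8), paste0("g", 1:8))
    members <- paste0("g", c(1, 3, 5, 7, 8))
    asg <- tibble::tibble(feature_id = paste0("g", 1:8),
                          module = ifelse(paste0("g", 1:8) %in% members, "M1", "grey"))
    kim <- intramodular_connectivity(a, asg, "M1")
    brute <- vapply(members, function(g) {
      sum(vapply(setdiff(members, g), function(h) a[g, h], numeric(1)))
    }, numeric(1))
    expect_equal(kim, brute, tolerance = 1e-12)
  }
})

test_that("hub ranking combines ranks with deterministic tie-breaks", {
  gs <- tibble::tibble(feature_id = c("a", "b", "c"), gs = c(0.9, -0.8, 0.1))
  centr <- c(a = 10, b = 5, c = 1)
  rk <- rank_hub_genes(gs, centr, c("a", "b", "c"))
  expect_equal(rk$feature_id[rk$combined_rank == 1], "a")
  expect_equal(rk$combined_score, c(1, 2, 3))

  # mirrored ranks (1,2) and (2,1): tie on score, gs_rank decides
  gs2 <- tibble::tibble(feature_id = c("a", "b"), gs = c(0.9, 0.5))
  centr2 <- c(a = 1, b = 2)
  rk2 <- rank_hub_genes(gs2, centr2, c("a", "b"))
  expect_equal(rk2$combined_score, c(1.5, 1.5))
  expect_equal(rk2$feature_id[rk2$combined_rank == 1], "a")

  expect_error(rank_hub_genes(gs, centr, character(0)), "empty")
})

test_that("annotation counts hits with configurable case handling", {
  sets <- list(HEM = c("A", "B", "Z"), EMPTY = character(0))
  ann <- annotate_overlap(c("A", "B", "c", "d"), sets)
  expect_equal(ann$n_hits, c(2L, 0L))
  expect_equal(ann$fraction, c(0.5, 0))
  expect_equal(ann$hits[[1]], c("A", "B"))

  sets2 <- list(S = "SPTBN1")
  expect_equal(annotate_overlap("Sptbn1", sets2)$n_hits, 0L)
  expect_equal(annotate_overlap("Sptbn1", sets2, normalize_ids = TRUE)$n_hits, 1L)
})

test_that("dual ranking places exact linear responses in both top lists", {
  set.seed(18)
  t <- rnorm(30)
  x <- cbind(lin = 2 * t + 1, matrix(rnorm(30 * 20), 30, 20))
  colnames(x) <- c("lin", sprintf("N%02d", 1:20))
  res <- dual_rank_features(x, t, k = 5)
  expect_true("lin" %in% res$top_pcc)
  expect_true("lin" %in% res$top_mic)
  sc <- res$scores[res$scores$feature_id == "lin", ]
  expect_equal(abs(sc$pcc), 1)
  expect_equal(sc$mic, 1)
  expect_true(all(res$intersection %in% res$top_pcc))
  expect_true(all(res$intersection %in% res$top_mic))

  res_all <- dual_rank_features(x, t, k = ncol(x))
  expect_setequal(res_all$intersection, colnames(x))
})

test_that("dual ranking is invariant to feature order and drops short features", {
  set.seed(19)
  t <- rnorm(20)
  x <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, sprintf("F%02d", 1:10)))
  res1 <- dual_rank_features(x, t, k = 3)
  res2 <- dual_rank_features(x[, sample(colnames(x))], t, k = 3)
  expect_equal(res1$scores, res2$scores)
  expect_equal(res1$top_mic, res2$top_mic)

  x2 <- x
  x2[3:20, "F01"] <- NA
  expect_warning(res3 <- dual_rank_features(x2, t, k = 3), "excluded")
  expect_false("F01" %in% res3$scores$feature_id)
})

test_that("dual ranking annotates its top lists against gene sets", {
  set.seed(20)
  t <- rnorm(20)
  x <- cbind(lin = t, matrix(rnorm(20 * 5), 20, 5))
  colnames(x) <- c("lin", sprintf("N%02d", 1:5))
  res <- dual_rank_features(x, t, k = 2, gene_sets = list(PLASMA = c("lin", "N01")))
  expect_true(all(c("pcc", "mic") %in% res$annotation$list))
  expect_true(all(res$annotation$n_hits >= 1))
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  res <- hypergeometric_overlap(3, 4, 5, 10)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, enum_hypergeom_upper(3, 4, 5, 10), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (3 / 5) / (4 / 10))

  # k = 0 with room for zero overlap
  expect_equal(hypergeometric_overlap(0, 3, 4, 10)$p_value, 1)

  # forced overlap: N=8, K=6, n=5 forces at least 3 shared
  expect_equal(hypergeometric_overlap(4, 6, 5, 8)$p_value,
               enum_hypergeom_upper(4, 6, 5, 8), tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(3, 6, 5, 8)$p_value, 1)
  expect_error(hypergeometric_overlap(2, 6, 5, 8), "minimum")

  # random sweep over feasible configurations, N <= 12
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    K <- sample(N, 1)
    n <- sample(N, 1)
    feasible <- max(0, K + n - N):min(K, n)
    k <- feasible[sample.int(length(feasible), 1)]
    expect_equal(hypergeometric_overlap(k, K, n, N)$p_value,
                 enum_hypergeom_upper(k, K, n, N), tolerance = 1e-12)
  }

  expect_error(hypergeometric_overlap(5, 4, 5, 10), "smaller set")
  expect_error(hypergeometric_overlap(1, 11, 5, 10), "universe")
})
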