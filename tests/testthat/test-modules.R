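test_that("clustering follows average linkage on 1 - TOM", {
  tom <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc <- cluster_features(tom)
  expect_equal(hc$height, 0.1)

  # hand-traced average linkage on 4 features:
  # d(A,B)=.1 d(C,D)=.2 d(A,C)=.5 d(A,D)=.6 d(B,C)=.7 d(B,D)=.8
  # merges: {A,B}@.1, {C,D}@.2, {AB,CD}@mean(.5,.6,.7,.8)=.65
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["C", "D"] <- d["D", "C"] <- 0.2
  d["A", "C"] <- d["C", "A"] <- 0.5
  d["A", "D"] <- d["D", "A"] <- 0.6
  d["B", "C"] <- d["C", "B"] <- 0.7
  d["B", "D"] <- d["D", "B"] <- 0.8
  hc4 <- cluster_features(1 - d)
  expect_equal(hc4$height, c(0.1, 0.2, 0.65))
  expect_equal(sort(hc4$labels[cutree(hc4, k = 2) == cutree(hc4, k = 2)[["A"]]]),
               c("A", "B"))
})

test_that("block-diagonal TOM separates its blocks at the top merge", {
  tom <- diag(8) * 0.2 + 0.8
  tom[1:4, 5:8] <- 0.05
  tom[5:8, 1:4] <- 0.05
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:8), paste0("g", 1:8))
  hc <- cluster_features(tom)
  top_split <- cutree(hc, k = 2)
  expect_equal(unname(top_split), rep(1:2, each = 4))
})

test_that("static cut relabels by size and sends small clusters to grey", {
  x <- two_block_matrix(n_samples = 12, block = 4)
  tom <- topological_overlap(adjacency(suppressWarnings(correlation_matrix(x)), 2))
  hc <- cluster_features(tom)
  asg <- cut_tree(hc, height = 0.5, min_size = 3)
  expect_equal(sort(unique(asg$module)), c("M1", "M2"))
  expect_equal(as.integer(table(asg$module)), c(4L, 4L))
  # ties in size resolved by smallest member ID: block containing G01 is M1
  expect_equal(asg$module[asg$feature_id == "G01"], "M1")

  all_grey <- cut_tree(hc, height = 0.5, min_size = 5)
  expect_true(all(all_grey$module == "grey"))
  expect_error(cut_tree(hc, height = 1.2), "height")
})

test_that("eigengenes summarize rank-1 modules exactly and deterministically", {
  x <- two_block_matrix()
  asg <- tibble::tibble(feature_id = colnames(x),
                        module = rep(c("M1", "M2"), each = 4))
  class(asg) <- c("coex_module_assignment", class(asg))
  eig <- compute_eigengenes(x, asg)
  expect_equal(unname(eig$var_explained), c(1, 1))
  expect_equal(abs(cor(eig$eigengenes[, "M1"], x[, 1])), 1)
  expect_gte(cor(eig$eigengenes[, "M1"], scale(x[, 1])[, 1]), 0)
  expect_equal(apply(eig$eigengenes, 2, sd), c(M1 = 1, M2 = 1))
  # bit-identical on repeat
  eig2 <- compute_eigengenes(x, asg)
  expect_identical(eig$eigengenes, eig2$eigengenes)
})

test_that("eigengene orientation falls back to the first member on a sign tie", {
  set.seed(6)
  v <- rnorm(10)
  x <- cbind(A = v, B = -v)
  rownames(x) <- paste0("s", 1:10)
  asg <- tibble::tibble(feature_id = c("A", "B"), module = c("M1", "M1"))
  eig <- compute_eigengenes(x, asg)
  expect_equal(unname(eig$var_explained), 1)
  expect_gt(cor(eig$eigengenes[, "M1"], scale(x[, "A"])[, 1]), 0.99)
})

test_that("constant features in a module are rejected by name", {
  x <- two_block_matrix()
  x[, "G02"] <- 1
  asg <- tibble::tibble(feature_id = colnames(x),
                        module = rep(c("M1", "M2"), each = 4))
  expect_error(compute_eigengenes(x, asg), "M1.*G02")
})

test_that("planted factors are recovered by their module eigengene", {
  sim <- generate_modular_expression(n_samples = 40, module_sizes = rep(50, 2),
                                     n_noise_features = 0, seed = 21)
  truth <- sim$truth
  asg <- truth$membership[, c("feature_id", "module")]
  eig <- compute_eigengenes(sim$expression, asg)
  for (m in c("M1", "M2")) {
    expect_gte(abs(cor(eig$eigengenes[, m], truth$factors[, m])), 0.9)
  }
})

test_that("kME is 1 on the eigengene itself and separates planted membership", {
  sim <- generate_modular_expression(n_samples = 40, module_sizes = rep(40, 2),
                                     n_noise_features = 20, seed = 31)
  asg <- sim$truth$membership[, c("feature_id", "module")]
  asg <- asg[asg$module != "grey", ]
  eig <- compute_eigengenes(sim$expression[, asg$feature_id], asg)
  x_aug <- cbind(sim$expression, E1 = eig$eigengenes[, "M1"])
  kme <- module_membership(x_aug, eig)
  expect_equal(kme["E1", "M1"], 1)

  in_m1 <- asg$feature_id[asg$module == "M1"]
  in_m2 <- asg$feature_id[asg$module == "M2"]
  own_higher <- c(abs(kme[in_m1, "M1"]) > abs(kme[in_m1, "M2"]),
                  abs(kme[in_m2, "M2"]) > abs(kme[in_m2, "M1"]))
  expect_gte(mean(own_higher), 0.95)
})

test_that("module merging is iterative and recomputes eigengenes", {
  # three planted modules driven by one shared factor -> all pairwise
  # eigengene correlations high -> collapse to a single module
  set.seed(9)
  n <- 30
  f <- rnorm(n)
  x <- sapply(1:30, function(i) f + rnorm(n, sd = 0.2))
  dimnames(x) <- list(paste0("s", 1:n), sprintf("G%02d", 1:30))
  asg <- tibble::tibble(feature_id = colnames(x),
                        module = rep(c("M1", "M2", "M3"), each = 10))
  merged <- merge_similar_modules(x, asg)
  expect_equal(unique(merged$assignment$module), "M1")
  expect_equal(ncol(merged$eigengenes$eigengenes), 1)

  # independent factors stay unmerged
  sim <- generate_modular_expression(n_samples = 30, module_sizes = c(10, 10),
                                     n_noise_features = 0, seed = 10)
  asg2 <- sim$truth$membership[, c("feature_id", "module")]
  merged2 <- merge_similar_modules(sim$expression, asg2)
  expect_equal(sort(unique(merged2$assignment$module)), c("M1", "M2"))
})

test_that("module recovery on clean block data is near-perfect", {
  for (seed in 1:3) {
    sim <- generate_modular_expression(n_samples = 40, module_sizes = rep(50, 5),
                                       n_noise_features = 0, seed = seed)
    det <- detect_modules(sim$expression)
    truth <- sim$truth$membership
    nz <- det$assignment$module != "grey"
    expect_gte(ari(det$assignment$module[nz],
                   truth$module[match(det$assignment$feature_id[nz],
                                      truth$feature_id)]), 0.8)
  }
})

test_that("module size table carries color aliases", {
  asg <- tibble::tibble(feature_id = paste0("g", 1:7),
                        module = c("M1", "M1", "M1", "M2", "M2", "grey", "grey"))
  sz <- module_sizes(asg)
  expect_equal(sz$module, c("M1", "M2"))
  expect_equal(sz$size, c(3L, 2L))
  expect_equal(sz$color_alias, c("turquoise", "blue"))
})
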