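test_that("correlation p-values match the t transform and its edge cases", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(-1, 5), 0)
  expect_equal(correlation_pvalue(0.9, 5), 0.03738607, tolerance = 1e-6)
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  expect_error(correlation_pvalue(1.5, 10), "<= 1")
  # vectorized
  expect_equal(correlation_pvalue(c(0, 1), 10), c(1, 0))
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(12)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  r <- cor(x, y)
  p_t <- correlation_pvalue(r, 20)
  p_perm <- perm_pvalue(x, y, n_perm = 10000)
  # Monte-Carlo standard error ~ sqrt(p(1-p)/B)
  se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(p_t - p_perm), 4 * se + 0.002)
})

test_that("normality switch has reasonable size and power", {
  n_pearson <- sum(vapply(1:100, function(s) {
    set.seed(s)
    auto_method(rnorm(50)) == "pearson"
  }, logical(1)))
  expect_gte(n_pearson, 90)

  n_spearman <- sum(vapply(1:100, function(s) {
    set.seed(1000 + s)
    auto_method(rexp(200)) == "spearman"
  }, logical(1)))
  expect_gte(n_spearman, 90)

  expect_error(auto_method(rep(1, 10)), "constant")
  expect_error(auto_method(c(1, 2)), "3 finite")
})

test_that("module-trait cells are exact on a planted identity and drop pairwise", {
  set.seed(13)
  E <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("S%02d", 1:20), c("M1", "M2", "M3")))
  E <- scale(E)
  traits <- tibble::tibble(
    sample_id = rownames(E),
    same = E[, "M1"],
    holey = rnorm(20),
    other = rnorm(20)
  )
  traits$holey[1:5] <- NA
  mt <- correlate_with_traits(E, traits)
  cell <- dplyr::filter(tidy(mt), module == "M1", trait == "same")
  expect_equal(cell$r, 1)
  expect_equal(cell$p, 0)
  expect_equal(cell$n_used, 20L)

  holey_cells <- dplyr::filter(tidy(mt), trait == "holey")
  expect_true(all(holey_cells$n_used == 15))
  # pairwise independence: other columns keep all 20 samples
  expect_true(all(dplyr::filter(tidy(mt), trait != "holey")$n_used == 20))

  bad <- tibble::tibble(sample_id = c("X1", "X2"), t = c(1, 2))
  expect_error(correlate_with_traits(E, bad), "no shared samples")
})

test_that("BH adjustment is available but off by default", {
  set.seed(14)
  E <- scale(matrix(rnorm(40), 20, 2,
                    dimnames = list(sprintf("S%02d", 1:20), c("M1", "M2"))))
  traits <- tibble::tibble(sample_id = rownames(E), a = rnorm(20), b = rnorm(20))
  expect_false("p_adj" %in% names(correlate_with_traits(E, traits)))
  adj <- correlate_with_traits(E, traits, p_adjust = "BH")
  expect_equal(adj$p_adj, stats::p.adjust(adj$p, "BH"))
})

test_that("a planted trait anchors its module's eigengene", {
  hits <- vapply(1:5, function(seed) {
    sim <- generate_modular_expression(n_samples = 40, module_sizes = rep(30, 3),
                                       n_noise_features = 0, seed = 40 + seed)
    traits <- generate_traits(sim$truth, links = list(MVD = list(module = "M1", rho = 0.7)),
                              n_null_traits = 2, seed = 140 + seed)
    asg <- sim$truth$membership[, c("feature_id", "module")]
    eig <- compute_eigengenes(sim$expression, asg)
    mvd <- dplyr::filter(tidy(correlate_with_traits(eig, traits)), trait == "MVD")
    mvd$module[which.max(abs(mvd$r))] == "M1"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("gene significance matches direct correlation and validates the trait", {
  set.seed(15)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("S%02d", 1:20), c("g1", "g2", "g3")))
  x[, "g3"] <- 2
  traits <- tibble::tibble(sample_id = rownames(x), MVD = x[, "g1"])
  expect_warning(gs <- gene_significance(x, traits, "MVD"), "constant")
  expect_equal(gs$gs[gs$feature_id == "g1"], 1)
  expect_equal(gs$gs[gs$feature_id == "g3"], 0)
  expect_equal(gs$gs[gs$feature_id == "g2"],
               cor(x[, "g2"], traits$MVD))
  expect_error(gene_significance(x, traits, "nope"), "MVD")
})

test_that("pearson gene significance is affine-invariant with sign flips", {
  set.seed(16)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("S%02d", 1:20), c("g1", "g2")))
  traits <- tibble::tibble(sample_id = rownames(x), t = rnorm(20))
  gs1 <- gene_significance(x, traits, "t")
  traits2 <- dplyr::mutate(traits, t = 3 * t + 7)
  gs2 <- gene_significance(x, traits2, "t")
  expect_equal(gs1$gs, gs2$gs, tolerance = 1e-12)
  traits3 <- dplyr::mutate(traits, t = -2 * t)
  gs3 <- gene_significance(x, traits3, "t")
  expect_equal(gs1$gs, -gs3$gs, tolerance = 1e-12)
})
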