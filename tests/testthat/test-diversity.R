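test_that("Chao1 follows the bias-corrected closed form", {
  expect_equal(chao1(c(5, 3, 2)), 3)          # no singletons
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)     # 4 + 2*1/(2*(1+1))
  expect_warning(empty <- chao1(integer(0)), "empty")
  expect_equal(empty, 0)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("Shannon diversity honours the base and edge cases", {
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(rep(3, 4), base = 2), 2)
  expect_equal(shannon(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-10)
  expect_equal(shannon(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "sum")
})

test_that("rarefaction preserves totals and is monotone in depth", {
  tab <- random_table(4, 30, seed = 71, depth = 300)
  r <- rarefy_table(tab, 300, n_iter = 3, seed = 1)
  expect_equal(apply(r$counts > 0, 1, sum), apply(tab$counts > 0, 1, sum))

  rc <- rarefaction_curve(tab, depths = c(1, 20, 80, 300), n_iter = 5,
                          seed = 2)
  expect_true(all(rc$richness[rc$depth == 1] == 1))
  for (s in unique(rc$sample)) {
    v <- rc$richness[rc$sample == s][order(rc$depth[rc$sample == s])]
    expect_true(all(diff(v) >= 0))
  }
  expect_equal(rc$richness[rc$depth == 300],
               unname(rowSums(tab$counts > 0)))

  uneven <- otu_table(rbind(S1 = c(100L, 100L), S2 = c(20L, 20L)))
  expect_warning(kept <- rarefy_table(uneven, 100, seed = 1), "below depth")
  expect_equal(kept$sample_ids, "S1")
  expect_error(rarefy_table(uneven, 500, seed = 1), "every sample")
  expect_error(rarefaction_curve(tab, depths = c(0, 5)), "> 0")
})

test_that("Bray-Curtis matches its closed form and metric properties", {
  m <- rbind(S1 = c(1, 1, 0), S2 = c(0, 1, 1))
  expect_equal(bray_curtis(m, use_relative = FALSE)[1, 2], 0.5)
  expect_equal(bray_curtis(rbind(a = c(2, 1), b = c(2, 1)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(a = c(2, 0), b = c(0, 5)))[1, 2], 1)
  for (seed in 1:10) {
    tab <- random_table(5, 12, seed = 100 + seed)
    bc <- bray_curtis(tab)
    expect_true(isSymmetric(unname(bc)))
    expect_true(all(bc >= 0 & bc <= 1))
    expect_equal(unname(diag(bc)), rep(0, 5))
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2)), use_relative = FALSE),
               "zero-sum")
})

test_that("PCoA on Euclidean distances reproduces PCA", {
  set.seed(81)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(x))
  ord <- pcoa_ordination(d, k = 2)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    align <- sign(stats::cor(ord$coords[, j], pc$x[, j]))
    expect_equal(unname(ord$coords[, j] * align), unname(pc$x[, j]),
                 tolerance = 1e-8)
  }
  # two points at distance d sit at +/- d/2
  two <- pcoa_ordination(matrix(c(0, 3, 3, 0), 2), k = 1)
  expect_equal(sort(unname(two$coords[, 1])), c(-1.5, 1.5))
  # collinear points: one axis carries everything
  colin <- as.matrix(dist(cbind(1:6, 2 * (1:6))))
  expect_equal(pcoa_ordination(colin)$proportion[1], 1, tolerance = 1e-10)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM separates groups and respects the permutation convention", {
  # perfectly separated groups: all between > all within
  x <- rbind(matrix(rnorm(20, 0, 0.01), 5), matrix(rnorm(20, 10, 0.01), 5))
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 200)
  expect_true(res$R >= -1 && res$R <= 1)
  expect_error(anosim_test(d, rep("a", 10)), "2 groups")
})

test_that("Kruskal-Wallis matches the rank formula and guards constants", {
  res <- group_difference_test(c(1, 2, 3, 10, 11, 12),
                               rep(c("a", "b"), each = 3))
  expect_equal(res$H, 3.857143, tolerance = 1e-6)
  const <- group_difference_test(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$H, 0)
  expect_equal(const$p, 1)
  expect_error(group_difference_test(1:4, c("a", "a", "a", "b")),
               ">= 2 observations")
})

test_that("differential abundance detects planted shifts and controls q", {
  set.seed(91)
  n <- 15
  base <- matrix(rpois(2 * n * 30, 50), 2 * n, 30)
  base[(n + 1):(2 * n), 5] <- rpois(n, 500)  # 10-fold shift in taxon 5
  tab <- otu_table(base, groups = rep(c("g1", "g2"), each = n))
  res <- differential_abundance(tab)
  expect_true(res$significant[res$taxon == "OTU5"])
  expect_lt(res$q[res$taxon == "OTU5"], 0.05)
  expect_equal(res$direction[res$taxon == "OTU5"], "g2")
  # q-values dominate p-values and are monotone in them
  expect_true(all(res$q >= res$p - 1e-12))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # alpha_fdr = 0 silences everything
  res0 <- differential_abundance(tab, alpha_fdr = 0)
  expect_false(any(res0$significant))
})
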