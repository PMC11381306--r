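test_that("simulated phylogenies are deterministic with Brownian traits", {
  pt <- simulate_phylogeny(2, seed = 4)
  D <- patristic_distance(pt$tree)
  expect_equal(D["OTU1", "OTU2"], sum(pt$tree$edge.length))

  a <- simulate_phylogeny(20, seed = 11)
  b <- simulate_phylogeny(20, seed = 11)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$trait, b$trait)

  expect_error(simulate_phylogeny(1, seed = 1), ">= 2")
})

test_that("Brownian tip-trait variance grows with tree depth", {
  # across replicate trees, deeper trees carry more trait variance
  depths <- traitvar <- numeric(200)
  for (i in 1:200) {
    pt <- simulate_phylogeny(8, seed = 5000 + i)
    depths[i] <- max(ape::node.depth.edgelength(pt$tree))
    traitvar[i] <- stats::var(pt$trait)
  }
  expect_gt(stats::cor(depths, traitvar, method = "spearman"), 0.2)
})

test_that("every generator hits the requested depth exactly and is seeded", {
  for (regime in assembly_regimes()) {
    sim <- simulate_community(regime, n_samples = 4, n_taxa = 40,
                              depth = 500, seed = 21)
    expect_equal(unname(rowSums(sim$table$counts)), rep(500, 4),
                 label = regime)
    sim2 <- simulate_community(regime, n_samples = 4, n_taxa = 40,
                               depth = 500, seed = 21)
    expect_identical(sim$table$counts, sim2$table$counts, label = regime)
  }
})

test_that("neutral sampling converges on the regional pool as N m grows", {
  set.seed(99)
  p <- regional_abundance(100)
  mad_at <- function(N) {
    sim <- simulate_neutral(10, depth = N, m = 1, p = p, seed = 7)
    mean(abs(sweep(sim$table$counts, 1, N, "/") -
               matrix(p, 10, 100, byrow = TRUE)))
  }
  m1 <- mad_at(2000)
  m2 <- mad_at(50000)
  expect_lt(m2, m1)

  # a taxon with N m p >> 1 occurs essentially everywhere
  sim <- simulate_neutral(20, depth = 5000, m = 0.5, p = p, seed = 8)
  big <- which.max(p)
  expect_equal(mean(sim$table$counts[, big] > 0), 1)

  expect_error(simulate_neutral(5, 40, 500, m = 0), "in \\(0, 1\\]")
})

test_that("selection regimes shape composition as the niche model predicts", {
  pt <- simulate_phylogeny(60, seed = 31)
  set.seed(32)
  p <- regional_abundance(60)

  # sigma -> Inf removes the filter: composition tracks p
  wide <- simulate_selection(6, pt, optima = rep(0, 6), sigma = 1e6,
                             depth = 20000, p = p, seed = 33)
  rel <- colMeans(relative_abundance(wide$table))
  expect_gt(stats::cor(rel, p), 0.99)

  # shared optimum at small sigma concentrates samples on the same taxa
  narrow <- simulate_selection(6, pt, optima = rep(pt$trait[1], 6),
                               sigma = 0.1, depth = 5000, p = p, seed = 34)
  top <- apply(narrow$table$counts, 1, which.max)
  expect_gt(max(table(top)) / 6, 0.5)

  # contrasting optima separate groups in Bray-Curtis
  opt <- c(rep(min(pt$trait), 3), rep(max(pt$trait), 3))
  contr <- simulate_selection(6, pt, optima = opt, sigma = 0.3,
                              depth = 5000, p = p, seed = 35)
  bc <- bray_curtis(contr$table)
  within <- c(bc[1:3, 1:3][upper.tri(bc[1:3, 1:3])],
              bc[4:6, 4:6][upper.tri(bc[4:6, 4:6])])
  between <- bc[1:3, 4:6]
  expect_gt(mean(between), mean(within))

  expect_error(simulate_selection(3, pt, optima = rep(0, 3), sigma = 0),
               "sigma")
  expect_error(simulate_selection(3, pt, optima = rep(0, 3), access = 0),
               "access")
})

test_that("dispersal regimes produce the expected turnover extremes", {
  # disjoint pools: complete turnover between different-pool samples
  sim0 <- simulate_dispersal("dispersal_limited", 4, 80, 1000,
                             pool_overlap = 0, drift_m = 1, seed = 41)
  bc <- bray_curtis(sim0$table)
  expect_equal(unname(bc[upper.tri(bc)]), rep(1, 6))

  # homogenizing dispersal at large depth: near-zero dissimilarity
  simh <- simulate_dispersal("homogenizing_dispersal", 4, 80, 50000,
                             seed = 42)
  bch <- bray_curtis(simh$table)
  expect_lt(max(bch[upper.tri(bch)]), 0.05)

  # pool_overlap = 1 shares one pool across all samples
  sim1 <- simulate_dispersal("dispersal_limited", 4, 80, 1000,
                             pool_overlap = 1, drift_m = 1, seed = 43)
  expect_true(all(lengths(sim1$truth$pools) == 80))

  expect_error(simulate_dispersal("dispersal_limited", 3, 40, 100,
                                  pool_overlap = 1.2), "pool_overlap")
})

test_that("simulated environments honour shifts, noise and seeds", {
  e0 <- simulate_env(5, noise_scale = 0, seed = 51)
  by_group <- split(as.data.frame(e0$env), e0$groups)
  for (g in by_group)
    expect_equal(unname(apply(g, 2, stats::var)), rep(0, ncol(e0$env)))

  e1 <- simulate_env(10, seed = 52)
  e2 <- simulate_env(10, seed = 52)
  expect_identical(e1$env, e2$env)

  # default seasonal directions: warmer wet season, nitrate-rich dry season
  mu <- apply(e1$env, 2, function(v) tapply(v, e1$groups, mean))
  expect_gt(mu["WS", "T"], mu["DS", "T"])
  expect_gt(mu["WS", "NH4"], mu["DS", "NH4"])
  expect_gt(mu["DS", "NO3"], mu["WS", "NO3"])

  expect_error(simulate_env(5, noise_scale = -1), "noise")
})

test_that("the two-season dataset carries groups, tree and environment", {
  ds <- simulate_dataset(n_per_group = 5, n_taxa = 60, depth = 800,
                         seed = 61)
  expect_equal(nlevels(ds$table$groups), 2)
  expect_equal(nrow(ds$table$counts), 10)
  expect_setequal(ds$tree$tip.label, ds$table$taxon_ids)
  expect_equal(rownames(ds$env$env), ds$table$sample_ids)
})
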