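test_that("betaMNTD matches hand-derived values on toy communities", {
  tr <- ape::read.tree(text = "(A:1,B:1):0;")
  cm <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
               dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(beta_mntd(otu_table(cm), tr)[1, 2], 2)

  same <- matrix(c(3L, 1L, 3L, 1L), 2, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(beta_mntd(otu_table(same), tr)[1, 2], 0)
})

test_that("betaMNTD equals the brute-force double loop on random instances", {
  for (i in 1:20) {
    n_taxa <- sample(3:8, 1)
    n_samp <- sample(2:4, 1)
    tab <- random_table(n_samp, n_taxa, seed = 300 + i, depth = 40)
    tree <- random_tree(n_taxa, seed = 300 + i)
    D <- patristic_distance(tree, tab$taxon_ids)
    for (w in c(TRUE, FALSE)) {
      expect_equal(unname(beta_mntd(tab, tree, abundance_weighted = w)),
                   brute_bmntd(tab$counts, D, weighted = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("picante agrees with the abundance-weighted betaMNTD", {
  skip_if_not_installed("picante")
  tab <- random_table(4, 12, seed = 333)
  tree <- random_tree(12, seed = 333)
  ours <- beta_mntd(tab, tree)
  theirs <- as.matrix(picante::comdistnt(tab$counts,
                                         patristic_distance(tree),
                                         abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(theirs[rownames(ours), colnames(ours)]),
               tolerance = 1e-10)
})

test_that("a star tree forces an undefined betaNTI with a warning", {
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- paste0("OTU", 1:6)
  cm <- rbind(S1 = c(20L, 10L, 5L, 0L, 0L, 0L),
              S2 = c(0L, 0L, 0L, 5L, 10L, 20L))
  colnames(cm) <- star$tip.label
  expect_warning(res <- bnti(otu_table(cm), star, n_null = 99, seed = 1),
                 "undefined")
  expect_true(is.na(res$bnti[1, 2]))
})

test_that("betaNTI is invariant to branch-length scale and column order", {
  tab <- random_table(4, 10, seed = 400)
  tree <- random_tree(10, seed = 400)
  z1 <- suppressWarnings(bnti(tab, tree, n_null = 199, seed = 5))
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * 7.3
  z2 <- suppressWarnings(bnti(tab, tree2, n_null = 199, seed = 5))
  expect_equal(z1$bnti, z2$bnti, tolerance = 1e-9)

  # observed betaMNTD is exactly invariant to taxon column order
  perm <- sample(10)
  tab_p <- subset_otu(tab, taxa = perm)
  expect_equal(beta_mntd(tab_p, tree), beta_mntd(tab, tree),
               tolerance = 1e-12)
})

test_that("Raup-Crick hits its extremes for coherent and disjoint pairs", {
  # near-identical resamples of a rich pool sit below the null: RC -> -1
  set.seed(11)
  p <- regional_abundance(150)
  shared <- t(stats::rmultinom(6, 3000, p))
  dimnames(shared) <- list(paste0("S", 1:6), paste0("OTU", 1:150))
  rc_low <- raup_crick_bray(otu_table(shared), n_null = 99, seed = 2)
  expect_lt(mean(rc_low$rc[upper.tri(rc_low$rc)]), -0.9)
  expect_lt(max(rc_low$rc[upper.tri(rc_low$rc)]), -0.5)

  # disjoint samples against a wide regional pool: RC -> +1
  cm <- matrix(0L, 2, 40, dimnames = list(c("A", "B"), paste0("OTU", 1:40)))
  cm[1, 1:10] <- 30L
  cm[2, 11:20] <- 30L
  pool <- matrix(5L, 6, 40,
                 dimnames = list(paste0("P", 1:6), paste0("OTU", 1:40)))
  rc_high <- raup_crick_bray(otu_table(cm), n_null = 99, seed = 3,
                             pool = otu_table(rbind(cm, pool)))
  expect_gte(rc_high$rc[1, 2], 0.95)

  # range and symmetry on arbitrary input
  tab <- random_table(5, 25, seed = 440)
  rc <- raup_crick_bray(tab, n_null = 99, seed = 4)
  expect_true(isSymmetric(unname(rc$rc)))
  expect_true(all(rc$rc >= -1 & rc$rc <= 1))
})

test_that("the five-way classifier applies the published thresholds", {
  ids <- c("a", "b")
  mk <- function(v) matrix(c(NA, v, v, NA), 2, dimnames = list(ids, ids))
  cls <- function(b, r)
    classify_processes(mk(b), mk(r))$pairs$class
  expect_equal(cls(2.5, 0), "heterogeneous_selection")
  expect_equal(cls(-2.5, 0), "homogeneous_selection")
  expect_equal(cls(0.5, 0.97), "dispersal_limitation")
  expect_equal(cls(0.5, -0.97), "homogenizing_dispersal")
  expect_equal(cls(1.0, 0.0), "undominated")
  # boundary: |betaNTI| = 2 and |RC| = 0.95 are stochastic/undominated
  expect_equal(cls(2, 0.95), "undominated")
})

test_that("classifier fractions are conserved and threshold-monotone", {
  set.seed(55)
  n <- 8
  ids <- paste0("S", 1:n)
  B <- matrix(0, n, n, dimnames = list(ids, ids))
  R <- B
  B[upper.tri(B)] <- rnorm(n * (n - 1) / 2, 0, 2.5)
  R[upper.tri(R)] <- runif(n * (n - 1) / 2, -1, 1)
  B <- B + t(B); R <- R + t(R)
  groups <- rep(c("g1", "g2"), each = 4)
  res <- classify_processes(B, R, groups = groups)
  for (f in res$fractions) expect_equal(sum(f), 100, tolerance = 1e-9)
  expect_equal(sum(!is.na(res$pairs$class)) + res$n_undefined,
               n * (n - 1) / 2)

  sel_frac <- function(th) {
    f <- classify_processes(B, R, bnti_threshold = th)$fractions$overall
    unname(f["heterogeneous_selection"] + f["homogeneous_selection"])
  }
  ths <- c(1, 2, 3, 4)
  expect_true(all(diff(sapply(ths, sel_frac)) <= 1e-12))

  # an undefined betaNTI pair is excluded and counted
  B2 <- B; B2[1, 2] <- B2[2, 1] <- NA
  res2 <- classify_processes(B2, R)
  expect_equal(res2$n_undefined, 1)
})

test_that("betaNTI-environment association flags exact linear dependence", {
  n <- 10
  ids <- paste0("S", 1:n)
  set.seed(66)
  env <- cbind(T = seq(10, 30, length.out = n), pH = rnorm(n, 7, 0.5),
               DO = rnorm(n, 8, 1))
  rownames(env) <- ids
  dT <- abs(outer(env[, "T"], env[, "T"], "-"))
  B <- 0.3 * dT - 2
  diag(B) <- NA
  res <- bnti_env_association(B, env, n_perm = 199, seed = 1)
  rowT <- res[res$variable == "T", ]
  expect_equal(rowT$r, 1, tolerance = 1e-10)
  expect_equal(rowT$slope, 0.3, tolerance = 1e-10)
  expect_equal(rowT$p_partial_mantel, 1 / 200)

  # constant variables are skipped with a note
  env2 <- cbind(env, EC = rep(250, n))
  expect_message(res2 <- bnti_env_association(B, env2, n_perm = 99,
                                              seed = 1), "constant")
  expect_false("EC" %in% res2$variable)
})
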