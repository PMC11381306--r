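test_that("Spearman correlations match a brute-force rank oracle", {
  set.seed(77)
  n <- 30
  counts <- matrix(rpois(n * 6, 40), n, 6,
                   dimnames = list(paste0("S", 1:n), paste0("OTU", 1:6)))
  counts[counts == 0] <- 1L
  tab <- otu_table(counts)
  cm <- correlation_matrix(tab, prevalence_min = 0)
  rel <- relative_abundance(tab)
  for (pair in list(c(1, 2), c(3, 5), c(2, 6))) {
    x <- rel[, pair[1]]; y <- rel[, pair[2]]
    rho <- stats::cor(rank(x), rank(y))  # Pearson on ranks
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    expect_equal(cm$rho[pair[1], pair[2]], rho, tolerance = 1e-10)
    expect_equal(cm$p[pair[1], pair[2]], p, tolerance = 1e-10)
  }
  # exact monotone and anti-monotone pairs
  m2 <- cbind(a = 1:10, b = (1:10)^2, c = 10:1)
  rho2 <- stats::cor(m2, method = "spearman")
  expect_equal(rho2["a", "b"], 1)
  expect_equal(rho2["a", "c"], -1)
})

test_that("prevalence and constancy filters apply before correlation", {
  counts <- matrix(rpois(60, 20), 10, 6,
                   dimnames = list(paste0("S", 1:10), paste0("OTU", 1:6)))
  counts[1:8, 3] <- 0L       # prevalence 0.2
  counts[counts == 0] <- ifelse(col(counts)[counts == 0] == 3, 0L, 1L)
  tab <- otu_table(counts)
  cm <- correlation_matrix(tab, prevalence_min = 0.5)
  expect_false("OTU3" %in% cm$taxa)
})

test_that("edge filtering is inclusive at S_t and monotone", {
  ids <- paste0("t", 1:4)
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  rho[1, 2] <- rho[2, 1] <- 0.78       # exactly at the threshold
  rho[3, 4] <- rho[4, 3] <- -0.9
  rho[1, 3] <- rho[3, 1] <- 0.5
  p <- matrix(0.001, 4, 4, dimnames = dimnames(rho))
  net <- build_network(rho, p, s_t = 0.78)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("positive", "negative"))

  empty <- build_network(rho, p, s_t = 1.01)
  expect_true(empty$empty)

  edges_at <- function(st) nrow(build_network(rho, p, s_t = st)$edges)
  expect_true(all(diff(sapply(c(0.3, 0.5, 0.78, 0.9), edges_at)) <= 0))
})

test_that("topology metrics reproduce closed forms on canonical graphs", {
  tri <- network_from_edges(data.frame(source = c("A", "B", "C"),
                                       target = c("B", "C", "A")))
  m <- topology_metrics(tri)
  expect_equal(m$avgK, 2)
  expect_equal(m$avgCC, 1)
  expect_equal(m$GD, 1)
  expect_equal(m$pct_positive, 100)

  path3 <- network_from_edges(data.frame(source = c("A", "B"),
                                         target = c("B", "C")))
  m3 <- topology_metrics(path3)
  expect_equal(m3$avgCC, 0)
  expect_equal(m3$GD, 4 / 3)

  empty <- build_network(diag(3), matrix(1, 3, 3), s_t = 0.5)
  me <- topology_metrics(empty)
  expect_true(me$empty)
  expect_true(is.na(me$avgK))
})

test_that("modularity matches a brute-force evaluation of the partition", {
  # two 5-cliques joined by one edge
  cl <- expand.grid(1:5, 1:5)
  cl <- cl[cl$Var1 < cl$Var2, ]
  edges <- rbind(
    data.frame(source = paste0("a", cl$Var1), target = paste0("a", cl$Var2)),
    data.frame(source = paste0("b", cl$Var1), target = paste0("b", cl$Var2)),
    data.frame(source = "a1", target = "b1"))
  net <- network_from_edges(edges)
  mods <- module_detection(net)
  g <- as_igraph(net)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  memb <- mods$membership[rownames(adj)]
  expect_equal(mods$Q, brute_modularity(adj, memb), tolerance = 1e-12)
  expect_equal(max(mods$membership), 2)

  # two disconnected triangles: the 2-block partition scores Q = 1/2
  tt <- network_from_edges(data.frame(
    source = c("A", "B", "C", "X", "Y", "Z"),
    target = c("B", "C", "A", "Y", "Z", "X")))
  mt <- module_detection(tt)
  expect_equal(max(mt$membership), 2)
  expect_equal(mt$Q, 0.5, tolerance = 1e-12)

  # complete graph: a single module, Q = 0
  k5 <- expand.grid(1:5, 1:5)
  k5 <- k5[k5$Var1 < k5$Var2, ]
  ck <- network_from_edges(data.frame(source = paste0("n", k5$Var1),
                                      target = paste0("n", k5$Var2)))
  mk <- module_detection(ck)
  expect_equal(max(mk$membership), 1)
  expect_equal(mk$Q, 0)
})

test_that("planted four-block networks are recovered by greedy modules", {
  set.seed(88)
  blocks <- rep(1:4, each = 12)
  n <- length(blocks)
  ids <- paste0("v", seq_len(n))
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pr <- if (blocks[i] == blocks[j]) 0.9 else 0.02
    if (runif(1) < pr)
      edges <- rbind(edges, data.frame(source = ids[i], target = ids[j]))
  }
  net <- network_from_edges(edges)
  mods <- module_detection(net)
  found <- mods$membership[ids[ids %in% names(mods$membership)]]
  truth <- blocks[match(names(found), ids)]
  expect_gt(adjusted_rand(truth, unname(found)), 0.9)
})

test_that("the RMT scan brackets planted correlation structure", {
  set.seed(99)
  n <- 80
  # two latent factors -> within-block correlation ~0.75, between ~0
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:15, function(i) f1 + rnorm(n, 0, 0.6)),
             sapply(1:15, function(i) f2 + rnorm(n, 0, 0.6)))
  rho <- cor(X)
  within <- mean(abs(rho[1:15, 1:15][upper.tri(rho[1:15, 1:15])]))
  between <- mean(abs(rho[1:15, 16:30]))
  scan <- rmt_threshold_scan(rho, grid = seq(0.30, 0.90, 0.02))
  expect_false(is.na(scan$suggested))
  expect_gt(scan$suggested, between)
  expect_lt(scan$suggested, within + 0.15)
  # deterministic: same matrix, same grid, same suggestion
  scan2 <- rmt_threshold_scan(rho, grid = seq(0.30, 0.90, 0.02))
  expect_identical(scan$scan, scan2$scan)

  expect_error(rmt_threshold_scan(diag(10)), "too small")
  expect_error(rmt_threshold_scan(diag(30)), "degenerate")
})

test_that("Zi-Pi values and role thresholds follow their definitions", {
  # hub node h linking four triangle modules
  edges <- NULL
  for (b in 1:4) {
    v <- paste0("m", b, "_", 1:3)
    edges <- rbind(edges,
                   data.frame(source = v[c(1, 2, 3)], target = v[c(2, 3, 1)]),
                   data.frame(source = "h", target = v[1]))
  }
  net <- network_from_edges(edges)
  mods <- module_detection(net)
  roles <- zi_pi(net, mods)
  h <- roles[roles$taxon == "h", ]
  expect_equal(h$degree, 4)
  # h's 4 edges go to 4 different modules; its own-module share depends on
  # the partition, but Pi is high and the role non-peripheral
  expect_gte(h$Pi, 0.62)
  expect_true(h$role %in% c("connector", "network_hub"))

  # all edges inside the module: Pi = 0
  tri <- network_from_edges(data.frame(source = c("A", "B", "C"),
                                       target = c("B", "C", "A")))
  rt <- zi_pi(tri)
  expect_equal(rt$Pi, rep(0, 3))
  expect_equal(rt$Zi, rep(0, 3))  # sd of within-module degree is 0

  # 2/2 split across two modules: Pi = 0.5
  expect_equal(1 - sum((c(2, 2) / 4)^2), 0.5)
  expect_equal(classify_node_role(3.0, 0.5), "module_hub")
  expect_equal(classify_node_role(1.0, 0.7), "connector")
  expect_equal(classify_node_role(1.0, 0.1), "peripheral")
  expect_equal(classify_node_role(2.5, 0.62), "peripheral")  # inclusive
  expect_equal(classify_node_role(2.6, 0.63), "network_hub")
})

test_that("Zi-Pi is invariant to node relabeling", {
  tab <- random_table(20, 15, seed = 500, depth = 500)
  cm <- correlation_matrix(tab, prevalence_min = 0)
  net <- build_network(cm, s_t = 0.3)
  roles <- zi_pi(net)
  perm <- sample(nrow(cm$rho))
  net2 <- build_network(cm$rho[perm, perm], cm$p[perm, perm], s_t = 0.3)
  roles2 <- zi_pi(net2)
  shared <- intersect(roles$taxon, roles2$taxon)
  r1 <- roles[match(shared, roles$taxon), ]
  r2 <- roles2[match(shared, roles2$taxon), ]
  expect_equal(r1$degree, r2$degree)
  expect_equal(r1$Pi, r2$Pi, tolerance = 1e-12)
})

test_that("keystone reporting conserves counts and annotates taxa", {
  roles <- data.frame(taxon = c("t1", "t2", "t3", "t4"),
                      module = c(1, 1, 2, 2), degree = c(3, 2, 5, 1),
                      Zi = c(3, 0, 1, 0), Pi = c(0.1, 0.7, 0.7, 0.1),
                      role = c("module_hub", "connector", "connector",
                               "peripheral"))
  ks <- keystone_report(roles)
  expect_equal(nrow(ks), 3)
  expect_equal(nrow(ks),
               sum(roles$role %in% c("connector", "module_hub",
                                     "network_hub")))
  all_per <- roles; all_per$role <- "peripheral"
  expect_equal(nrow(keystone_report(all_per)), 0)

  tab <- random_table(4, 4, seed = 7)
  tab$taxonomy <- stats::setNames(
    paste0("k__Bacteria;p__Phylum", 1:4), tab$taxon_ids)
  roles$taxon <- tab$taxon_ids
  ks2 <- keystone_report(roles, tab)
  expect_equal(ks2$phylum, paste0("Phylum", which(roles$role != "peripheral")))
  expect_true(all(ks2$mean_rel_abundance > 0))
})
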