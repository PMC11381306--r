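# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately naive: explicit double loops, no shared
# code with the package internals.

# betaMNTD by explicit double loop over taxa.
brute_bmntd <- function(counts, D, weighted = TRUE) {
  n <- nrow(counts)
  out <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (m in seq_len(n)) {
      if (k == m) next
      ik <- which(counts[k, ] > 0)
      jm <- which(counts[m, ] > 0)
      fk <- if (weighted) counts[k, ik] / sum(counts[k, ik])
            else rep(1 / length(ik), length(ik))
      fm <- if (weighted) counts[m, jm] / sum(counts[m, jm])
            else rep(1 / length(jm), length(jm))
      s1 <- 0
      for (a in seq_along(ik)) {
        best <- Inf
        for (b in seq_along(jm)) best <- min(best, D[ik[a], jm[b]])
        s1 <- s1 + fk[a] * best
      }
      s2 <- 0
      for (b in seq_along(jm)) {
        best <- Inf
        for (a in seq_along(ik)) best <- min(best, D[ik[a], jm[b]])
        s2 <- s2 + fm[b] * best
      }
      out[k, m] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# Newman-Girvan modularity Q = sum_s (e_ss - a_s^2) from an adjacency
# matrix and a module assignment.
brute_modularity <- function(adj, membership) {
  total <- sum(adj) / 2
  q <- 0
  for (s in unique(membership)) {
    idx <- which(membership == s)
    e_ss <- sum(adj[idx, idx]) / 2 / total
    a_s <- sum(adj[idx, ]) / 2 / total
    q <- q + e_ss - a_s^2
  }
  q
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small random count table with guaranteed positive row sums.
random_table <- function(n_samples, n_taxa, seed, depth = 200) {
  set.seed(seed)
  counts <- t(stats::rmultinom(n_samples, depth,
                               stats::runif(n_taxa, 0.2, 1)))
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("OTU", seq_len(n_taxa)))
  otu_table(counts)
}

# Random Yule tree whose tips match OTU ids.
random_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- paste0("OTU", seq_len(n_taxa))
  tree
}

# Build a cooc_network directly from an explicit edge list (for topology
# closed-form tests): every edge gets rho = 0.9, p = 0.
network_from_edges <- function(edges) {
  n <- length(unique(c(edges$source, edges$target)))
  ids <- sort(unique(c(edges$source, edges$target)))
  rho <- diag(length(ids))
  dimnames(rho) <- list(ids, ids)
  p <- matrix(1, length(ids), length(ids), dimnames = dimnames(rho))
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    rho[a, b] <- rho[b, a] <- 0.9
    p[a, b] <- p[b, a] <- 0
  }
  build_network(rho, p, s_t = 0.8, p_max = 0.05)
}
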