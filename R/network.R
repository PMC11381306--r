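#' Spearman correlation matrix for network construction
#'
#' Taxa are pre-filtered by prevalence, correlations are computed on
#' relative abundances, and p-values use the tie-corrected t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of freedom.
#'
#' @param table An \code{otu_table}.
#' @param prevalence_min Minimum fraction of samples a taxon must occupy
#'   (default 0.5).
#' @return List with \code{rho}, \code{p} (taxa x taxa matrices) and
#'   \code{taxa} (kept taxon ids).
#' @export
correlation_matrix <- function(table, prevalence_min = 0.5) {
  stopifnot(inherits(table, "otu_table"))
  rel <- relative_abundance(table)
  prev <- colMeans(rel > 0)
  keep <- prev >= prevalence_min
  rel <- rel[, keep, drop = FALSE]
  const <- apply(rel, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant taxon/taxa")
    rel <- rel[, !const, drop = FALSE]
  }
  if (ncol(rel) < 2) stop("fewer than 2 taxa after filtering", call. = FALSE)
  n <- nrow(rel)
  rho <- stats::cor(rel, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  list(rho = rho, p = p, taxa = colnames(rel))
}

#' Build a signed co-occurrence network
#'
#' An edge is kept iff \code{|rho| >= s_t} (inclusive) and \code{p < p_max};
#' its sign is the sign of rho. Taxa left without any edge are dropped, so
#' the node count is the number of connected nodes.
#'
#' @param rho,p Aligned correlation and p-value matrices
#'   (\code{correlation_matrix} output can be passed as \code{rho} with
#'   \code{p} missing).
#' @param s_t Similarity threshold on |rho| (default 0.78).
#' @param p_max Significance threshold on p (default 0.05).
#' @param taxonomy Optional named lineage vector for the nodes.
#' @return A \code{cooc_network}: list with \code{nodes}, \code{edges}
#'   data.frames, \code{graph} (igraph, edge attributes rho/sign),
#'   \code{s_t}, \code{p_max}, \code{empty} flag.
#' @export
build_network <- function(rho, p = NULL, s_t = 0.78, p_max = 0.05,
                          taxonomy = NULL) {
  if (is.list(rho) && is.null(p)) {
    p <- rho$p
    rho <- rho$rho
  }
  stopifnot(identical(dim(rho), dim(p)))
  ids <- rownames(rho)
  ut <- which(upper.tri(rho) & abs(rho) >= s_t & p < p_max, arr.ind = TRUE)
  if (!nrow(ut)) {
    return(structure(list(nodes = data.frame(), edges = data.frame(),
                          graph = igraph::make_empty_graph(directed = FALSE),
                          s_t = s_t, p_max = p_max, empty = TRUE),
                     class = "cooc_network"))
  }
  edges <- data.frame(source = ids[ut[, 1]], target = ids[ut[, 2]],
                      rho = rho[ut], p = p[ut],
                      sign = ifelse(rho[ut] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- data.frame(taxon = igraph::V(g)$name, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) nodes$taxonomy <- unname(taxonomy[nodes$taxon])
  structure(list(nodes = nodes, edges = edges, graph = g,
                 s_t = s_t, p_max = p_max, empty = FALSE),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  if (x$empty) {
    cat("cooc_network: empty (no edge passed |rho| >=", x$s_t,
        "and p <", x$p_max, ")\n")
  } else {
    cat(sprintf("cooc_network: %d nodes, %d edges (S_t = %g, p < %g)\n",
                nrow(x$nodes), nrow(x$edges), x$s_t, x$p_max))
    cat(sprintf("  %.1f%% positive edges\n",
                100 * mean(x$edges$sign == "positive")))
  }
  invisible(x)
}

#' @rdname build_network
#' @param net A \code{cooc_network}.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  net$graph
}

#' @rdname build_network
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  net$edges
}

#' Greedy modularity module detection
#'
#' Deterministic CNM greedy agglomeration maximizing Newman-Girvan
#' modularity on the unsigned, unweighted graph; a stochastic Louvain
#' alternative sits behind the seed.
#'
#' @param net A \code{cooc_network} (or igraph).
#' @param method \code{"greedy"} (default, deterministic) or
#'   \code{"louvain"}.
#' @param seed Integer seed (used by the stochastic method).
#' @return List with \code{membership} (named integer vector) and \code{Q}.
#' @export
module_detection <- function(net, method = c("greedy", "louvain"), seed = 1) {
  method <- match.arg(method)
  g <- if (inherits(net, "cooc_network")) net$graph else net
  if (igraph::ecount(g) < 1) stop("network has no edges", call. = FALSE)
  gu <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  for (a in igraph::edge_attr_names(gu))  # unweighted modularity
    gu <- igraph::delete_edge_attr(gu, a)
  set.seed(seed)
  cl <- switch(method,
               greedy = igraph::cluster_fast_greedy(gu),
               louvain = igraph::cluster_louvain(gu))
  memb <- igraph::membership(cl)
  if (method == "greedy") {
    # pick the dendrogram cut with maximal Q (fewest modules on ties);
    # igraph's default cut can sit one merge short of the optimum
    best_q <- igraph::modularity(gu, memb)
    for (k in seq_len(min(igraph::vcount(gu), length(memb)))) {
      mk <- tryCatch(igraph::cut_at(cl, no = k), error = function(e) NULL)
      if (is.null(mk)) next
      qk <- igraph::modularity(gu, mk)
      if (qk > best_q + 1e-12) {
        best_q <- qk
        memb <- stats::setNames(mk, names(memb))
      }
    }
  }
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       Q = igraph::modularity(gu, memb))
}

#' Topology metrics of a co-occurrence network
#'
#' avgK = 2E/N; avgCC = mean local clustering coefficient (degree-1 nodes
#' contribute 0); GD = mean shortest-path length over connected pairs in the
#' largest connected component (unweighted); modularity Q of the module
#' partition; power-law R2 = coefficient of determination of the
#' log10(frequency) ~ log10(degree) least-squares line over observed
#' degrees; percentage of positive/negative edges.
#'
#' @param net A \code{cooc_network}.
#' @param modules Optional \code{module_detection} output (computed if
#'   missing).
#' @return Named list of metrics. On an empty network all metrics are NA
#'   with \code{empty = TRUE}.
#' @export
topology_metrics <- function(net, modules = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  if (net$empty)
    return(list(empty = TRUE, nodes = 0, edges = 0, avgK = NA, avgCC = NA,
                GD = NA, modularity = NA, powerlaw_r2 = NA,
                pct_positive = NA, pct_negative = NA))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, comp$membership ==
                                    which.max(comp$csize))
  gd <- igraph::mean_distance(big, directed = FALSE)
  if (is.null(modules)) modules <- module_detection(net)
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  plr2 <- if (length(tab) >= 3) {
    fit <- stats::lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
    summary(fit)$r.squared
  } else NA_real_
  pos <- 100 * mean(net$edges$sign == "positive")
  list(empty = FALSE, nodes = n, edges = e, avgK = 2 * e / n,
       avgCC = mean(cc_local), GD = gd, modularity = modules$Q,
       powerlaw_r2 = plr2, pct_positive = pos, pct_negative = 100 - pos)
}

#' Random matrix theory threshold scan
#'
#' For each candidate threshold the absolute correlation matrix is
#' hard-thresholded (entries below the threshold set to 0), its eigenvalue
#' spectrum is unfolded through a smoothed empirical CDF, and the
#' nearest-neighbour spacing distribution is tested against the Poisson
#' (exponential) form by a chi-square goodness-of-fit test. The suggested
#' threshold is the smallest one whose Poisson fit is not rejected
#' (p > 0.05) - the RMT signature of modular, noise-free structure.
#'
#' @param rho Correlation matrix (>= 20 taxa).
#' @param grid Candidate thresholds.
#' @param alpha Rejection level for the chi-square test.
#' @return List with \code{suggested} (NA if no threshold qualifies),
#'   \code{scan} data.frame (threshold, chisq p, degenerate flag).
#' @export
rmt_threshold_scan <- function(rho, grid = seq(0.30, 0.95, by = 0.01),
                               alpha = 0.05) {
  rho <- as.matrix(rho)
  if (nrow(rho) < 20)
    stop("matrix too small for spacing statistics (< 20 taxa); ",
         "use a fixed threshold", call. = FALSE)
  scan <- data.frame(threshold = grid, p = NA_real_, degenerate = FALSE)
  for (i in seq_along(grid)) {
    a <- abs(rho)
    a[a < grid[i]] <- 0
    diag(a) <- 1
    ev <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    if (stats::sd(ev) < 1e-10) {
      scan$degenerate[i] <- TRUE
      next
    }
    s <- .nn_spacings(ev)
    if (is.null(s) || length(s) < 20) {
      scan$degenerate[i] <- TRUE
      next
    }
    scan$p[i] <- .poisson_spacing_test(s)
  }
  ok <- which(!scan$degenerate & !is.na(scan$p) & scan$p > alpha)
  suggested <- if (length(ok)) grid[min(ok)] else NA_real_
  if (is.na(suggested) && all(scan$degenerate))
    stop("spectrum degenerate at every threshold (identity-like matrix)",
         call. = FALSE)
  list(suggested = suggested, scan = scan)
}

# Unfold a sorted spectrum via a smoothed empirical CDF and return the
# nearest-neighbour spacings (unit mean).
.nn_spacings <- function(ev) {
  n <- length(ev)
  if (length(unique(round(ev, 10))) < 10) return(NULL)  # degenerate
  F_emp <- (seq_len(n) - 0.5) / n
  sm <- tryCatch(
    stats::smooth.spline(ev, F_emp, df = min(12, max(4, n %/% 10))),
    error = function(e) NULL)
  if (is.null(sm)) return(NULL)
  unfolded <- n * stats::predict(sm, ev)$y
  s <- diff(sort(unfolded))
  s <- s[is.finite(s)]
  if (mean(s) > 0) s / mean(s) else NULL
}

# Chi-square GOF of unit-mean spacings against the exponential density.
.poisson_spacing_test <- function(s) {
  brk <- c(seq(0, 2.5, by = 0.5), Inf)
  obs <- table(cut(s, brk))
  pr <- diff(stats::pexp(brk))
  suppressWarnings(stats::chisq.test(as.integer(obs), p = pr)$p.value)
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' \code{Zi = (kappa_i - mean kappa) / sd kappa} over node i's module,
#' where kappa_i counts i's edges into its own module (sd 0 gives Zi = 0);
#' \code{Pi = 1 - sum_s (kappa_is / k_i)^2} over modules s. Roles follow
#' the conventional thresholds: peripheral (Zi <= 2.5, Pi <= 0.62),
#' connector (Zi <= 2.5, Pi > 0.62), module hub (Zi > 2.5, Pi <= 0.62),
#' network hub (Zi > 2.5, Pi > 0.62).
#'
#' @param net A \code{cooc_network}.
#' @param modules \code{module_detection} output (computed if missing).
#' @param zi_threshold,pi_threshold Role thresholds.
#' @return data.frame per node: module, degree, Zi, Pi, role.
#' @export
zi_pi <- function(net, modules = NULL, zi_threshold = 2.5,
                  pi_threshold = 0.62) {
  stopifnot(inherits(net, "cooc_network"))
  if (net$empty) stop("empty network", call. = FALSE)
  if (is.null(modules)) modules <- module_detection(net)
  g <- net$graph
  memb <- modules$membership[igraph::V(g)$name]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj[adj > 1] <- 1
  n <- nrow(adj)
  n_mod <- max(memb)
  # kappa[i, s] = number of i's edges into module s
  ind <- matrix(0, n, n_mod)
  ind[cbind(seq_len(n), memb)] <- 1
  kappa <- adj %*% ind
  k <- rowSums(adj)
  own <- kappa[cbind(seq_len(n), memb)]
  zi <- numeric(n)
  for (s in seq_len(n_mod)) {
    idx <- which(memb == s)
    mu <- mean(own[idx])
    sdv <- stats::sd(own[idx])
    zi[idx] <- if (is.na(sdv) || sdv == 0) 0 else (own[idx] - mu) / sdv
  }
  pi <- 1 - rowSums((kappa / k)^2)
  role <- classify_node_role(zi, pi, zi_threshold, pi_threshold)
  data.frame(taxon = rownames(adj), module = as.integer(memb),
             degree = as.integer(k), Zi = zi, Pi = pi, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify node roles from Zi and Pi
#'
#' Peripheral (Zi <= 2.5, Pi <= 0.62), connector (Zi <= 2.5, Pi > 0.62),
#' module hub (Zi > 2.5, Pi <= 0.62), network hub (Zi > 2.5, Pi > 0.62);
#' both thresholds are inclusive on the peripheral side.
#'
#' @param zi,pi Numeric vectors of within-module degree z-scores and
#'   participation coefficients.
#' @param zi_threshold,pi_threshold Role thresholds.
#' @return Character vector of roles.
#' @export
classify_node_role <- function(zi, pi, zi_threshold = 2.5,
                               pi_threshold = 0.62) {
  ifelse(zi > zi_threshold,
         ifelse(pi > pi_threshold, "network_hub", "module_hub"),
         ifelse(pi > pi_threshold, "connector", "peripheral"))
}

#' Keystone taxa report
#'
#' All non-peripheral nodes (connectors, module hubs, network hubs), with
#' phylum-level lineage and mean relative abundance when available.
#'
#' @param roles \code{zi_pi} output.
#' @param table Optional \code{otu_table} supplying taxonomy and abundance.
#' @return data.frame of keystone nodes (possibly empty).
#' @export
keystone_report <- function(roles, table = NULL) {
  ks <- roles[roles$role != "peripheral", , drop = FALSE]
  if (!is.null(table) && nrow(ks)) {
    rel <- relative_abundance(table)
    ks$mean_rel_abundance <- colMeans(rel)[ks$taxon]
    if (!is.null(table$taxonomy))
      ks$phylum <- vapply(table$taxonomy[ks$taxon], .phylum_of, character(1))
  }
  rownames(ks) <- NULL
  ks
}

# Extract the phylum rank from a semicolon-delimited lineage; rank
# prefixes ("p__") optional. Unparseable lineages returned verbatim.
.phylum_of <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) return(NA_character_)
  parts <- trimws(strsplit(lineage, ";")[[1]])
  pref <- grep("^p__", parts, value = TRUE)
  if (length(pref)) return(sub("^p__", "", pref[1]))
  if (length(parts) >= 2) return(parts[2])
  parts[1]
}
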