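#' Simulate a pure-birth phylogeny with a Brownian niche trait
#'
#' Yule tree (birth rate 1, no extinction) over \code{n_taxa} tips, with a
#' single continuous niche trait evolved by Brownian motion along the
#' branches so that ecological similarity is phylogenetically conserved —
#' the precondition for selection regimes to leave a phylogenetic footprint.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate of the Yule process.
#' @param trait_rate Brownian motion rate (variance per unit branch length).
#' @return List with \code{tree} (\code{phylo}, tip labels \code{OTU<i>})
#'   and \code{trait} (named numeric vector over tips).
#' @export
simulate_phylogeny <- function(n_taxa, seed, birth = 1, trait_rate = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth, death = 0)
  tree$tip.label <- paste0("OTU", seq_len(n_taxa))
  trait <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_rate))
  names(trait) <- tree$tip.label
  list(tree = tree, trait = trait)
}

#' Lognormal regional relative abundances
#'
#' @param n_taxa Number of taxa.
#' @param meanlog,sdlog Lognormal parameters of the unnormalized abundances.
#' @return Numeric vector summing to 1.
#' @export
regional_abundance <- function(n_taxa, meanlog = 0, sdlog = 1.5) {
  p <- stats::rlnorm(n_taxa, meanlog, sdlog)
  p / sum(p)
}

# Draw one sample's counts by multinomial sampling at the given depth.
.multinom_sample <- function(weights, depth) {
  as.integer(stats::rmultinom(1, depth, weights))
}

#' @rdname simulate_community
#' @export
assembly_regimes <- function() {
  c("neutral", "heterogeneous_selection", "homogeneous_selection",
    "dispersal_limited", "homogenizing_dispersal")
}

#' Simulate samples under Sloan neutral dynamics
#'
#' The Sloan neutral community model is the exact data-generating process:
#' each sample's latent relative abundance of taxon i is Beta(N m p_i,
#' N m (1 - p_i)) (renormalized across taxa), then counts are drawn
#' multinomially at depth N. Larger migration rate m couples samples more
#' tightly to the regional pool.
#'
#' @param n_samples Number of samples.
#' @param n_taxa Number of taxa (ignored if \code{p} given).
#' @param depth Reads per sample (N).
#' @param m Migration rate in (0, 1].
#' @param p Optional regional relative abundances (summing to 1).
#' @param seed Integer seed.
#' @param sample_prefix Prefix for sample ids.
#' @param shape_floor Lower floor for Beta shape parameters.
#' @return List with \code{table} (\code{otu_table}) and \code{truth}
#'   (regime label, p, m).
#' @export
simulate_neutral <- function(n_samples, n_taxa = 800, depth = 20000,
                             m = 0.1, p = NULL, seed = 1,
                             sample_prefix = "S", shape_floor = 1e-8) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  if (is.null(p)) p <- regional_abundance(n_taxa)
  n_taxa <- length(p)
  lam <- depth * m
  a <- lam * p
  b <- lam * (1 - p)
  if (any(a < shape_floor) || any(b < shape_floor)) {
    warning("Beta shape parameters floored at ", shape_floor)
    a <- pmax(a, shape_floor)
    b <- pmax(b, shape_floor)
  }
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                   paste0("OTU", seq_len(n_taxa))))
  for (s in seq_len(n_samples)) {
    x <- stats::rbeta(n_taxa, a, b)
    if (sum(x) == 0) x <- p
    counts[s, ] <- .multinom_sample(x / sum(x), depth)
  }
  list(table = otu_table(counts),
       truth = list(regime = "neutral", p = p, m = m))
}

#' Simulate samples under environmental selection
#'
#' Sampling weight of taxon i in sample s is proportional to
#' \code{p_i * exp(-(trait_i - optimum_s)^2 / (2 sigma^2))}: Gaussian niche
#' filtering around a per-sample environmental optimum, on top of the
#' regional abundance. Contrasting optima across samples give heterogeneous
#' selection; one shared optimum gives homogeneous selection.
#'
#' @param n_samples Number of samples.
#' @param tree_trait List as returned by \code{simulate_phylogeny}.
#' @param optima Numeric vector of per-sample environmental optima (length
#'   \code{n_samples}), on the trait scale.
#' @param sigma Niche breadth (> 0), trait units.
#' @param depth Reads per sample.
#' @param p Optional regional relative abundances.
#' @param access Fraction of the regional pool each sample can draw from
#'   (site availability, thinned uniformly at random and independently of
#'   the phylogeny). 1 disables thinning; values < 1 create membership
#'   turnover among equally-filtered taxa, which is what makes homogeneous
#'   selection visible to nearest-taxon turnover metrics.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for sample ids.
#' @return List with \code{table} and \code{truth}.
#' @export
simulate_selection <- function(n_samples, tree_trait, optima, sigma = 0.2,
                               depth = 20000, p = NULL, access = 1,
                               seed = 1, sample_prefix = "S") {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (access <= 0 || access > 1)
    stop("access must be in (0, 1]", call. = FALSE)
  if (length(optima) != n_samples)
    stop("optima must have one value per sample", call. = FALSE)
  trait <- tree_trait$trait
  set.seed(seed)
  n_taxa <- length(trait)
  if (is.null(p)) p <- regional_abundance(n_taxa)
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                   names(trait)))
  for (s in seq_len(n_samples)) {
    avail <- if (access < 1) sample.int(n_taxa, round(access * n_taxa))
             else seq_len(n_taxa)
    w <- numeric(n_taxa)
    w[avail] <- p[avail] * exp(-(trait[avail] - optima[s])^2 /
                                 (2 * sigma^2))
    if (sum(w) == 0) w[avail] <- p[avail]  # optimum outside trait range
    counts[s, ] <- .multinom_sample(w / sum(w), depth)
  }
  regime <- if (length(unique(optima)) == 1L) "homogeneous_selection"
            else "heterogeneous_selection"
  list(table = otu_table(counts),
       truth = list(regime = regime, p = p, trait = trait,
                    optima = optima, sigma = sigma, access = access))
}

#' Clade-indicator niche trait
#'
#' A binary niche trait marking membership of one randomly chosen clade of
#' intermediate size: 1 inside the subtree, 0 outside. Models niche
#' conservatism at the lineage level (e.g. a metabolic capability fixed in
#' one clade), giving a selection target that is phylogenetically coherent
#' by construction.
#'
#' @param tree A \code{phylo} tree.
#' @param min_tips,max_tips Acceptable clade size range; if no internal
#'   node qualifies, the closest-sized clade is used.
#' @param seed Integer seed (clade choice is random among candidates).
#' @return Named 0/1 vector over tips.
#' @export
clade_indicator_trait <- function(tree, min_tips = 40, max_tips = 80,
                                  seed = 1) {
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  sizes <- vapply(nodes, function(nd)
    length(ape::extract.clade(tree, nd)$tip.label), integer(1))
  cand <- nodes[sizes >= min_tips & sizes <= max_tips]
  node <- if (length(cand)) cand[sample.int(length(cand), 1)]
          else nodes[order(abs(sizes - min_tips))[1]]
  tips <- ape::extract.clade(tree, node)$tip.label
  tr <- stats::setNames(rep(0, ntip), tree$tip.label)
  tr[tips] <- 1
  tr
}

#' Evenly spread selection optima over the trait range
#'
#' @param trait Named trait vector (tips).
#' @param n Number of optima.
#' @param lo,hi Trait quantiles delimiting the spread.
#' @return Numeric vector of length \code{n}.
#' @export
spread_optima <- function(trait, n, lo = 0.05, hi = 0.95) {
  q <- stats::quantile(trait, c(lo, hi), names = FALSE)
  seq(q[1], q[2], length.out = n)
}

#' Simulate samples under dispersal-dominated regimes
#'
#' \code{dispersal_limited}: each sample assembles from a site-specific
#' species pool (pools share a fraction \code{pool_overlap} of their taxa
#' and are otherwise disjoint) under weak demographic coupling to the pool:
#' the latent composition drifts around the pool abundances with
#' Sloan-type Beta sampling at migration \code{drift_m}, so each site's
#' realized dominants are a largely random subset of the pool. Both
#' mechanisms are independent of the phylogeny (trait-agnostic), so
#' compositional turnover rises above the null expectation while
#' phylogenetic turnover stays within it.
#' \code{homogenizing_dispersal}: every sample is a multinomial resample of
#' one shared regional composition, so turnover collapses below the null.
#'
#' @param regime \code{"dispersal_limited"} or \code{"homogenizing_dispersal"}.
#' @param n_samples Number of samples.
#' @param n_taxa Regional pool size.
#' @param depth Reads per sample.
#' @param pool_overlap Fraction of each site pool shared across sites, in
#'   [0, 1]. Only used by \code{dispersal_limited}. Default 1 (one shared
#'   pool; isolation is expressed through drift) because fragmenting the
#'   realized occupancy also widens the Raup-Crick null envelope.
#' @param drift_m Sloan-type coupling of each site to its pool, in (0, 1];
#'   small values (default 0.01) give strong local drift. 1 approximates
#'   direct multinomial sampling of the pool.
#' @param p Optional regional relative abundances.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for sample ids.
#' @return List with \code{table} and \code{truth}.
#' @export
simulate_dispersal <- function(regime = c("dispersal_limited",
                                          "homogenizing_dispersal"),
                               n_samples, n_taxa = 800, depth = 20000,
                               pool_overlap = 1, drift_m = 0.01, p = NULL,
                               seed = 1, sample_prefix = "S") {
  regime <- match.arg(regime)
  if (pool_overlap < 0 || pool_overlap > 1)
    stop("pool_overlap must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  if (is.null(p)) p <- regional_abundance(n_taxa)
  n_taxa <- length(p)
  ids <- paste0("OTU", seq_len(n_taxa))
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                   ids))
  pools <- NULL
  if (regime == "homogenizing_dispersal") {
    for (s in seq_len(n_samples)) counts[s, ] <- .multinom_sample(p, depth)
  } else {
    # per-site pool size K: shared core of round(K * overlap) taxa plus
    # disjoint private sets, all drawn uniformly (trait-agnostic)
    K <- max(2L, floor(n_taxa / (n_samples * (1 - pool_overlap) +
                                   pool_overlap)))
    n_shared <- round(K * pool_overlap)
    n_private <- min(K - n_shared,
                     floor((n_taxa - n_shared) / n_samples))
    perm <- sample.int(n_taxa)
    shared <- if (n_shared > 0) perm[seq_len(n_shared)] else integer()
    pools <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      priv <- if (n_private > 0)
        perm[n_shared + (s - 1L) * n_private + seq_len(n_private)]
      else integer()
      pool <- c(shared, priv)
      pools[[s]] <- ids[pool]
      w <- p[pool] / sum(p[pool])
      lam <- depth * drift_m
      x <- stats::rbeta(length(pool), lam * w, lam * (1 - w))
      if (sum(x) == 0) x <- w
      wf <- numeric(n_taxa)
      wf[pool] <- x / sum(x)
      counts[s, ] <- .multinom_sample(wf, depth)
    }
  }
  list(table = otu_table(counts),
       truth = list(regime = regime, p = p, pool_overlap = pool_overlap,
                    drift_m = if (regime == "dispersal_limited") drift_m,
                    pools = pools))
}

# Seasonal default environmental contrasts (mean per group, noise sd).
# Directions follow the wet-season/dry-season hydrochemistry of a
# subtropical river: warmer, more alkaline, ammonia- and DOC-rich wet
# season; better-oxygenated, nitrate-rich dry season.
.env_defaults <- function() {
  data.frame(
    variable = c("T", "pH", "DO", "EC", "ORP", "NO3", "NH4", "Cl", "SO4",
                 "HCO3", "DOC"),
    WS = c(31, 7.9, 5.5, 230, 180, 0.8, 1.8, 12, 20, 90, 8),
    DS = c(21, 7.2, 7.5, 260, 220, 2.5, 0.6, 15, 24, 110, 3),
    sd = c(1.5, 0.2, 0.8, 25, 25, 0.4, 0.3, 2, 3, 10, 1.2),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group environmental matrix
#'
#' Each variable is its group mean plus Gaussian noise. Defaults emulate
#' seasonal hydrochemistry contrasts (temperature, pH, ammonium and DOC
#' higher in the wet season; nitrate, DO higher in the dry season).
#'
#' @param n_per_group Samples per group.
#' @param groups Character vector of two group labels.
#' @param shifts Data frame with columns \code{variable}, one column per
#'   group (means) and \code{sd}; defaults to the seasonal table.
#' @param noise_scale Multiplier on the per-variable noise sd (>= 0).
#' @param seed Integer seed.
#' @param sample_prefix Prefix for sample ids.
#' @return An \code{env_matrix} with a group factor.
#' @export
simulate_env <- function(n_per_group = 15, groups = c("WS", "DS"),
                         shifts = NULL, noise_scale = 1, seed = 1,
                         sample_prefix = "S") {
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (is.null(shifts)) shifts <- .env_defaults()
  stopifnot(all(c("variable", groups, "sd") %in% names(shifts)))
  set.seed(seed)
  n <- n_per_group * length(groups)
  env <- matrix(NA_real_, n, nrow(shifts),
                dimnames = list(paste0(sample_prefix, seq_len(n)),
                                shifts$variable))
  glab <- rep(groups, each = n_per_group)
  for (j in seq_len(nrow(shifts))) {
    mu <- unlist(shifts[j, groups])[match(glab, groups)]
    env[, j] <- mu + stats::rnorm(n, 0, shifts$sd[j] * noise_scale)
  }
  suppressWarnings(env_matrix(env, factor(glab, levels = groups)))
}

#' Simulate one community under a named assembly regime
#'
#' Convenience dispatcher used by the regime-recovery tests: builds the
#' phylogeny + trait, the regional pool, and the sample set for one of the
#' five assembly regimes.
#'
#' @param regime One of \code{"neutral"}, \code{"heterogeneous_selection"},
#'   \code{"homogeneous_selection"}, \code{"dispersal_limited"},
#'   \code{"homogenizing_dispersal"}.
#' @param n_samples,n_taxa,depth Community dimensions.
#' @param m Migration rate (neutral regime). The default 0.5 keeps
#'   sample-to-pool coupling strong enough that compositional turnover
#'   stays inside the Raup-Crick null envelope; weaker coupling grades
#'   into the dispersal-limited regime.
#' @param sigma Niche breadth (selection regimes); default 0.15 x the tip
#'   trait standard deviation, so the filter admits a narrow slice of the
#'   realized niche space whatever the tree's depth.
#' @param pool_overlap Site-pool overlap (dispersal-limited regime).
#' @param seed Integer seed.
#' @return List with \code{table}, \code{tree}, \code{trait}, \code{truth}.
#' @export
simulate_community <- function(regime, n_samples = 15, n_taxa = 800,
                               depth = 20000, m = 0.5, sigma = NULL,
                               pool_overlap = 1, seed = 1) {
  regime <- match.arg(regime, assembly_regimes())
  pt <- simulate_phylogeny(n_taxa, seed = seed)
  if (is.null(sigma)) sigma <- 0.15 * stats::sd(pt$trait)
  # Heterogeneous selection spreads contrasting optima of the continuous
  # Brownian trait across samples. Homogeneous selection filters on a
  # clade-indicator niche (one shared optimum on a lineage-level trait)
  # with site-availability thinning, so samples host different close
  # relatives of the favored clade.
  sim <- switch(regime,
    neutral = simulate_neutral(n_samples, n_taxa, depth, m = m,
                               seed = seed + 1L),
    heterogeneous_selection = simulate_selection(
      n_samples, pt, optima = spread_optima(pt$trait, n_samples),
      sigma = sigma, depth = depth, seed = seed + 1L),
    homogeneous_selection = simulate_selection(
      n_samples,
      list(tree = pt$tree,
           trait = clade_indicator_trait(pt$tree, seed = seed + 5L)),
      optima = rep(1, n_samples), sigma = 0.25,
      depth = depth, access = 0.5, seed = seed + 1L),
    dispersal_limited = simulate_dispersal(
      "dispersal_limited", n_samples, n_taxa, depth,
      pool_overlap = pool_overlap, seed = seed + 1L),
    homogenizing_dispersal = simulate_dispersal(
      "homogenizing_dispersal", n_samples, n_taxa, depth,
      seed = seed + 1L))
  list(table = sim$table, tree = pt$tree, trait = pt$trait,
       truth = sim$truth)
}

#' Simulate a full two-season dataset
#'
#' Two groups of neutrally assembled samples with group-specific migration
#' rates (defaults emulate a wet season with high immigration and a dry
#' season with restricted immigration), a shared phylogeny, and a seasonal
#' environmental matrix. The object feeds the end-to-end pipeline.
#'
#' @param n_per_group Samples per group.
#' @param n_taxa Regional pool size.
#' @param depth Reads per sample.
#' @param m Named numeric vector of migration rates, one per group.
#' @param seed Integer seed.
#' @return List with \code{table} (grouped \code{otu_table}), \code{tree},
#'   \code{env}, \code{truth}.
#' @export
simulate_dataset <- function(n_per_group = 15, n_taxa = 800, depth = 20000,
                             m = c(WS = 0.105, DS = 0.026), seed = 1) {
  stopifnot(!is.null(names(m)), length(m) >= 2)
  pt <- simulate_phylogeny(n_taxa, seed = seed)
  set.seed(seed + 1L)
  p <- regional_abundance(n_taxa)
  tabs <- vector("list", length(m))
  for (g in seq_along(m)) {
    tabs[[g]] <- simulate_neutral(n_per_group, n_taxa, depth, m = m[g],
                                  p = p, seed = seed + 1L + g,
                                  sample_prefix = paste0(names(m)[g], "_")
                                  )$table$counts
  }
  counts <- do.call(rbind, tabs)
  groups <- factor(rep(names(m), each = n_per_group), levels = names(m))
  env <- simulate_env(n_per_group, groups = names(m), seed = seed + 99L,
                      sample_prefix = "E")
  rownames(env$env) <- rownames(counts)
  names(env$groups) <- rownames(counts)
  list(table = otu_table(counts, groups = groups), tree = pt$tree,
       env = env, truth = list(p = p, m = m))
}
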