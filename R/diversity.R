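#' Bias-corrected Chao1 richness estimator
#'
#' \code{S_obs + F1 (F1 - 1) / (2 (F2 + 1))}, with F1 the number of
#' singletons and F2 the number of doubletons.
#'
#' @param counts Integer vector of taxon counts for one sample.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    warning("empty sample: Chao1 = 0")
    return(0)
  }
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' \code{-sum(p log p)} in the units of \code{base} (natural log by
#' default; base 2 matches QIIME's convention).
#'
#' @param counts Non-negative vector with positive sum.
#' @param base Logarithm base.
#' @return Shannon index (>= 0).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) stop("sample sum must be > 0", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Per-sample alpha diversity table
#'
#' @param table An \code{otu_table}.
#' @param base Logarithm base for Shannon.
#' @return data.frame with sample, group, observed richness, Chao1, Shannon.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "otu_table"))
  cc <- table$counts
  data.frame(
    sample = rownames(cc),
    group = if (!is.null(table$groups)) as.character(table$groups) else NA,
    richness = rowSums(cc > 0),
    chao1 = apply(cc, 1, chao1),
    shannon = apply(cc, 1, shannon, base = base),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefy an OTU table to even depth
#'
#' Random subsampling without replacement, averaged over \code{n_iter}
#' draws (counts rounded to integers on output). Samples below the target
#' depth are dropped with a warning.
#'
#' @param table An \code{otu_table}.
#' @param depth Target depth (> 0).
#' @param n_iter Number of subsampling iterations.
#' @param seed Integer seed.
#' @return A rarefied \code{otu_table}.
#' @export
rarefy_table <- function(table, depth, n_iter = 10, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  keep <- rowSums(table$counts) >= depth
  if (!any(keep))
    stop("every sample is below depth ", depth, call. = FALSE)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
    table <- subset_otu(table, samples = which(keep))
  }
  set.seed(seed)
  acc <- matrix(0, nrow(table$counts), ncol(table$counts))
  for (i in seq_len(n_iter))
    acc <- acc + vegan::rrarefy(table$counts, depth)
  out <- round(acc / n_iter)
  dimnames(out) <- dimnames(table$counts)
  # guard: rounding of averaged draws can in principle zero an all-ones row
  out[rowSums(out) == 0, 1] <- 1L
  otu_table(out, taxonomy = table$taxonomy, groups = table$groups)
}

#' Rarefaction curves
#'
#' Mean observed richness under random subsampling without replacement at a
#' grid of depths, per sample.
#'
#' @param table An \code{otu_table}.
#' @param depths Integer vector of depths (defaults to 10 points up to the
#'   smallest sample depth).
#' @param n_iter Subsampling iterations per depth.
#' @param seed Integer seed.
#' @return data.frame sample x depth with mean richness and n_iter.
#' @export
rarefaction_curve <- function(table, depths = NULL, n_iter = 10, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(depths)) {
    dmax <- min(rowSums(table$counts))
    depths <- unique(pmax(1, round(seq(1, dmax, length.out = 10))))
  }
  if (any(depths <= 0)) stop("depths must be > 0", call. = FALSE)
  set.seed(seed)
  res <- expand.grid(sample = table$sample_ids, depth = sort(depths),
                     stringsAsFactors = FALSE)
  res$richness <- NA_real_
  res$n_iter <- n_iter
  for (k in seq_len(nrow(res))) {
    x <- table$counts[res$sample[k], ]
    d <- res$depth[k]
    if (d > sum(x)) next
    rich <- numeric(n_iter)
    for (i in seq_len(n_iter))
      rich[i] <- sum(vegan::rrarefy(matrix(x, 1), d) > 0)
    res$richness[k] <- mean(rich)
  }
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{BC(a, b) = 1 - 2 sum(min(x_a, x_b)) / (sum x_a + sum x_b)},
#' computed on relative abundances by default to remove depth artifacts.
#'
#' @param table An \code{otu_table} or a samples x taxa matrix.
#' @param use_relative Convert to relative abundances first.
#' @return Symmetric \code{matrix} of dissimilarities in [0, 1].
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (nrow(m) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(rowSums(m) == 0)) stop("zero-sum sample", call. = FALSE)
  if (use_relative) m <- sweep(m, 1, rowSums(m), "/")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Gower double-centering + eigendecomposition of a dissimilarity matrix.
#' Negative eigenvalues are excluded from the variance denominator and
#' reported separately.
#'
#' @param d Square symmetric dissimilarity matrix (or \code{dist}).
#' @param k Number of axes to return.
#' @return List with \code{coords} (samples x k), \code{eig} (positive
#'   eigenvalues, descending), \code{proportion} (variance share per axis),
#'   \code{negative_eig}.
#' @export
pcoa_ordination <- function(d, k = 2) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  fit <- stats::cmdscale(stats::as.dist(m), k = min(k, n - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coords = coords,
       eig = pos,
       proportion = pos / sum(pos),
       negative_eig = fit$eig[fit$eig < -1e-12])
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- vs within-group dissimilarity;
#' p uses the add-one permutation convention so it is never 0.
#'
#' @param d Dissimilarity matrix or \code{dist}.
#' @param groups Group factor (>= 2 groups, each >= 2 members).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with \code{R} and \code{p}.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(groups) < 2))
    stop("each group needs >= 2 members", call. = FALSE)
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(as.matrix(d)), groups,
                       permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif)
}

#' Kruskal-Wallis group difference test
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group factor.
#' @return List with \code{H} (tie-corrected statistic), \code{df}, \code{p}.
#' @export
group_difference_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(groups) < 2))
    stop("each group needs >= 2 observations", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  fit <- stats::kruskal.test(values, groups)
  list(H = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Per-taxon differential abundance between two groups
#'
#' Two-sided Wilcoxon rank-sum tests on relative abundances with
#' Benjamini-Hochberg FDR control.
#'
#' @param table An \code{otu_table} with exactly two groups (or supply
#'   \code{groups}).
#' @param groups Optional group factor overriding the table's.
#' @param alpha_fdr Significance level on q-values.
#' @return data.frame per taxon: statistic W, p, q, direction (group with
#'   the larger mean relative abundance), significant flag. Taxa absent
#'   everywhere are excluded (attribute \code{excluded}).
#' @export
differential_abundance <- function(table, groups = NULL, alpha_fdr = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(groups)) groups <- table$groups
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups required", call. = FALSE)
  rel <- relative_abundance(table)
  present <- colSums(rel) > 0
  rel <- rel[, present, drop = FALSE]
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  stat <- p <- numeric(ncol(rel))
  dir <- character(ncol(rel))
  for (j in seq_len(ncol(rel))) {
    w <- suppressWarnings(stats::wilcox.test(rel[i1, j], rel[i2, j]))
    stat[j] <- unname(w$statistic)
    p[j] <- w$p.value
    dir[j] <- if (mean(rel[i1, j]) >= mean(rel[i2, j])) g1 else g2
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(taxon = colnames(rel), statistic = stat, p = p, q = q,
                    direction = dir, significant = q < alpha_fdr,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- table$taxon_ids[!present]
  out
}
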