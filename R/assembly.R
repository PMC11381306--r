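# Pairwise beta mean nearest taxon distance for a fixed community layout.
# pres: list of integer taxon indices present per sample; W: samples x
# taxa weight matrix (rows sum to 1, zero where absent); D: taxa x taxa
# patristic distances. For each sample s the column M[, s] holds every
# taxon's distance to its nearest relative in s (max.col gives row minima
# at C speed); the weighted pair sums then collapse to one matrix
# product: betaMNTD(k, m) = 0.5 (W[k, ] M[, m] + W[m, ] M[, k]).
.bmntd_core <- function(pres, W, D) {
  n <- length(pres)
  nt <- ncol(D)
  M <- matrix(0, nt, n)
  for (s in seq_len(n)) {
    sub <- D[, pres[[s]], drop = FALSE]
    M[, s] <- sub[cbind(seq_len(nt),
                        max.col(-sub, ties.method = "first"))]
  }
  B <- W %*% M
  out <- 0.5 * (B + t.default(B))
  diag(out) <- 0
  out
}

.comm_layout <- function(counts, abundance_weighted) {
  pres <- apply(counts, 1, function(x) which(x > 0), simplify = FALSE)
  W <- matrix(0, nrow(counts), ncol(counts))
  for (s in seq_len(nrow(counts))) {
    x <- counts[s, pres[[s]]]
    W[s, pres[[s]]] <- if (abundance_weighted) x / sum(x)
                       else 1 / length(x)
  }
  list(pres = pres, W = W)
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair, the average patristic distance from each taxon in
#' one community to its closest relative in the other, averaged over the
#' two directions; abundance-weighted by default (weights are within-sample
#' relative abundances; the unweighted variant uses 1/richness).
#'
#' @param table An \code{otu_table} (or samples x taxa count matrix).
#' @param tree A \code{phylo} over the table's taxa (or a precomputed
#'   patristic distance matrix).
#' @param abundance_weighted Weight by relative abundance.
#' @return Symmetric samples x samples matrix (branch-length units).
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  counts <- if (inherits(table, "otu_table")) table$counts
            else as.matrix(table)
  if (any(rowSums(counts) == 0)) stop("sample with zero taxa", call. = FALSE)
  D <- if (inherits(tree, "phylo")) patristic_distance(tree, colnames(counts))
       else as.matrix(tree)[colnames(counts), colnames(counts)]
  lay <- .comm_layout(counts, abundance_weighted)
  out <- .bmntd_core(lay$pres, lay$W, D)
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a null in which taxon labels
#' are shuffled across the tree tips (equivalently, rows/columns of the
#' patristic matrix are jointly permuted), recomputed \code{n_null} times:
#' \code{(obs - mean_null) / sd_null} per sample pair. |betaNTI| > 2 is the
#' conventional signature of deterministic selection (> 2 heterogeneous,
#' < -2 homogeneous).
#'
#' @param table An \code{otu_table}.
#' @param tree A \code{phylo} (or patristic matrix) over the table's taxa.
#' @param n_null Number of null randomizations (>= 99).
#' @param seed Integer seed.
#' @param abundance_weighted Weight betaMNTD by relative abundance.
#' @return A \code{bnti_result}: list with \code{bnti}, \code{bmntd_obs},
#'   \code{null_mean}, \code{null_sd} (samples x samples matrices; pairs
#'   with null sd 0 are NA in \code{bnti}), \code{n_null}, \code{seed}.
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1,
                 abundance_weighted = TRUE) {
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  counts <- if (inherits(table, "otu_table")) table$counts
            else as.matrix(table)
  D <- if (inherits(tree, "phylo")) patristic_distance(tree, colnames(counts))
       else as.matrix(tree)[colnames(counts), colnames(counts)]
  lay <- .comm_layout(counts, abundance_weighted)
  obs <- .bmntd_core(lay$pres, lay$W, D)
  n_taxa <- ncol(counts)
  set.seed(seed)
  sum1 <- sum2 <- matrix(0, nrow(counts), nrow(counts))
  for (b in seq_len(n_null)) {
    perm <- sample.int(n_taxa)
    nb <- .bmntd_core(lay$pres, lay$W, D[perm, perm])
    sum1 <- sum1 + nb
    sum2 <- sum2 + nb * nb
  }
  null_mean <- sum1 / n_null
  null_var <- pmax((sum2 - n_null * null_mean^2) / (n_null - 1), 0)
  null_sd <- sqrt(null_var)
  z <- (obs - null_mean) / null_sd
  z[null_sd <= 1e-12] <- NA
  diag(z) <- NA
  if (anyNA(z[upper.tri(z)]))
    warning(sum(is.na(z[upper.tri(z)])),
            " pair(s) with null sd 0: betaNTI undefined")
  dimnames(z) <- dimnames(obs) <- dimnames(null_mean) <-
    dimnames(null_sd) <- list(rownames(counts), rownames(counts))
  structure(list(bnti = z, bmntd_obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_null = n_null, seed = seed),
            class = "bnti_result")
}

# Bray-Curtis between two sparse count vectors (ids + counts).
.bc_sparse <- function(id1, c1, id2, c2) {
  hit <- match(id1, id2)
  sh <- !is.na(hit)
  1 - 2 * sum(pmin(c1[sh], c2[hit[sh]])) / (sum(c1) + sum(c2))
}

#' Bray-Curtis Raup-Crick index (RC-bray)
#'
#' For each sample pair, null community pairs are assembled
#' probabilistically: each null community keeps its empirical richness and
#' total abundance; taxon identities are drawn without replacement with
#' probability proportional to regional occupancy, then the remaining
#' individuals are allocated with probability proportional to regional
#' relative abundance. RC-bray rescales the fraction of null Bray-Curtis
#' values below the observed one to [-1, 1] (ties counted half):
#' > 0.95 indicates dispersal limitation, < -0.95 homogenizing dispersal.
#'
#' @param table An \code{otu_table}.
#' @param n_null Number of null pairs per sample pair (>= 99).
#' @param seed Integer seed.
#' @param pool Optional \code{otu_table} supplying the regional
#'   occupancy/abundance weights (defaults to \code{table} itself).
#' @return An \code{rc_result}: list with \code{rc} (samples x samples
#'   matrix in [-1, 1]), \code{bc_obs}, \code{n_null}, \code{seed}.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1, pool = NULL) {
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  counts <- if (inherits(table, "otu_table")) table$counts
            else as.matrix(table)
  pc <- if (is.null(pool)) counts
        else if (inherits(pool, "otu_table")) pool$counts else as.matrix(pool)
  occ <- colSums(pc > 0)
  abund <- colSums(pc) / sum(pc)
  in_pool <- occ > 0
  pool_idx <- which(in_pool)
  n_pool <- length(pool_idx)
  occ_w <- occ[pool_idx]
  ab_w <- abund[pool_idx]

  n <- nrow(counts)
  rich <- rowSums(counts > 0)
  depth <- rowSums(counts)
  if (any(rich > n_pool))
    stop("sample richness exceeds the regional pool", call. = FALSE)
  bc_obs <- bray_curtis(counts, use_relative = FALSE)

  draw_null <- function(r, ntot) {
    # weighted sampling without replacement via exponential keys
    # (Efraimidis-Spirakis); equivalent to successive draws w/o
    # replacement with probability proportional to occupancy, but
    # O(n log n) instead of O(r n)
    keys <- stats::rexp(n_pool) / occ_w
    ids <- order(keys)[seq_len(r)]
    cnt <- rep(1L, r)
    extra <- ntot - r
    if (extra > 0)
      cnt <- cnt + as.integer(stats::rmultinom(1, extra, ab_w[ids]))
    list(ids = ids, cnt = cnt)
  }

  set.seed(seed)
  rc <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (k in seq_len(n - 1)) {
    for (m in (k + 1):n) {
      less <- eq <- 0L
      for (b in seq_len(n_null)) {
        a <- draw_null(rich[k], depth[k])
        bb <- draw_null(rich[m], depth[m])
        bcn <- .bc_sparse(a$ids, a$cnt, bb$ids, bb$cnt)
        if (bcn < bc_obs[k, m] - 1e-12) less <- less + 1L
        else if (abs(bcn - bc_obs[k, m]) <= 1e-12) eq <- eq + 1L
      }
      rc[k, m] <- rc[m, k] <- 2 * ((less + 0.5 * eq) / n_null) - 1
    }
  }
  structure(list(rc = rc, bc_obs = bc_obs, n_null = n_null, seed = seed),
            class = "rc_result")
}

#' Five-way assembly process classification
#'
#' Per sample pair: betaNTI > 2 is heterogeneous selection, betaNTI < -2
#' homogeneous selection; otherwise RC-bray > 0.95 is dispersal limitation,
#' RC-bray < -0.95 homogenizing dispersal, and the remainder undominated.
#' Fractions are percentages of classified pairs, overall and per group
#' (within-group pairs by default).
#'
#' @param bnti_res A \code{bnti_result} (or betaNTI matrix).
#' @param rc_res An \code{rc_result} (or RC-bray matrix).
#' @param bnti_threshold,rc_threshold Classification thresholds.
#' @param groups Optional group factor over samples.
#' @param include_between Include between-group pairs in per-group
#'   fractions (they are always part of \code{pairs} and \code{overall}).
#' @return A \code{process_partition}: \code{pairs} data.frame,
#'   \code{fractions} (named percentage vectors: \code{overall} plus one
#'   per group), \code{n_undefined}, thresholds.
#' @export
classify_processes <- function(bnti_res, rc_res, bnti_threshold = 2,
                               rc_threshold = 0.95, groups = NULL,
                               include_between = FALSE) {
  B <- if (inherits(bnti_res, "bnti_result")) bnti_res$bnti
       else as.matrix(bnti_res)
  R <- if (inherits(rc_res, "rc_result")) rc_res$rc else as.matrix(rc_res)
  if (!identical(dim(B), dim(R)))
    stop("betaNTI and RC matrices must share sample ordering", call. = FALSE)
  ids <- rownames(B)
  n <- nrow(B)
  ut <- which(upper.tri(B), arr.ind = TRUE)
  b <- B[upper.tri(B)]
  r <- R[upper.tri(R)]
  cls <- rep(NA_character_, length(b))
  ok <- !is.na(b)
  cls[ok & b > bnti_threshold] <- "heterogeneous_selection"
  cls[ok & b < -bnti_threshold] <- "homogeneous_selection"
  stoch <- ok & abs(b) <= bnti_threshold
  cls[stoch & r > rc_threshold] <- "dispersal_limitation"
  cls[stoch & r < -rc_threshold] <- "homogenizing_dispersal"
  cls[stoch & abs(r) <= rc_threshold] <- "undominated"
  pairs <- data.frame(sample_i = ids[ut[, 1]], sample_j = ids[ut[, 2]],
                      bnti = b, rc = r, class = cls,
                      stringsAsFactors = FALSE)
  lv <- c("heterogeneous_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "undominated")
  frac <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(rep(NA_real_, 5), lv))
    100 * table(factor(x, lv)) / length(x)
  }
  fractions <- list(overall = frac(cls))
  if (!is.null(groups)) {
    groups <- factor(groups)
    gi <- groups[ut[, 1]]; gj <- groups[ut[, 2]]
    for (g in levels(groups)) {
      sel <- if (include_between) (gi == g | gj == g)
             else (gi == g & gj == g)
      fractions[[g]] <- frac(cls[sel])
    }
  }
  structure(list(pairs = pairs, fractions = fractions,
                 n_undefined = sum(is.na(cls)),
                 thresholds = c(bnti = bnti_threshold, rc = rc_threshold)),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("Assembly process partition (", nrow(x$pairs), " pairs, ",
      x$n_undefined, " undefined)\n", sep = "")
  for (nm in names(x$fractions)) {
    f <- x$fractions[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s %.1f%%", names(f), f), collapse = ", ")))
  }
  invisible(x)
}

#' Association between betaNTI and environmental differences
#'
#' For each environmental variable, regresses pairwise betaNTI on the
#' pairwise absolute difference of the variable (OLS slope, correlation,
#' two-sided p), and runs a permutation-based partial Mantel test of the
#' betaNTI matrix against the variable's difference matrix, controlling for
#' the aggregate Euclidean difference of the remaining (standardized)
#' variables.
#'
#' @param bnti_res A \code{bnti_result} (or betaNTI matrix).
#' @param env An \code{env_matrix} or samples x variables numeric matrix
#'   aligned with the betaNTI matrix.
#' @param n_perm Number of Mantel permutations.
#' @param seed Integer seed.
#' @return data.frame per variable: slope, r, p_regression,
#'   r_partial_mantel, p_partial_mantel.
#' @export
bnti_env_association <- function(bnti_res, env, n_perm = 1000, seed = 1) {
  B <- if (inherits(bnti_res, "bnti_result")) bnti_res$bnti
       else as.matrix(bnti_res)
  E <- if (inherits(env, "env_matrix")) env$env else as.matrix(env)
  stopifnot(nrow(E) == nrow(B))
  Es <- scale(E)
  y <- B[upper.tri(B)]
  out <- list()
  for (j in seq_len(ncol(E))) {
    v <- E[, j]
    dv <- abs(outer(v, v, "-"))
    x <- dv[upper.tri(dv)]
    if (stats::sd(x) == 0) {
      message("skipping constant variable ", colnames(E)[j])
      next
    }
    keep <- !is.na(y)
    fit <- stats::lm(y[keep] ~ x[keep])
    r <- stats::cor(x[keep], y[keep])
    p_reg <- summary(fit)$coefficients[2, 4]
    rest <- Es[, -j, drop = FALSE]
    dc <- as.matrix(stats::dist(rest))
    set.seed(seed)
    pm <- vegan::mantel.partial(stats::as.dist(B), stats::as.dist(dv),
                                stats::as.dist(dc),
                                permutations = n_perm, na.rm = TRUE)
    out[[colnames(E)[j]]] <- data.frame(
      variable = colnames(E)[j],
      slope = unname(stats::coef(fit)[2]), r = r, p_regression = p_reg,
      r_partial_mantel = unname(pm$statistic),
      p_partial_mantel = pm$signif, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
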