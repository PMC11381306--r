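#' Variance inflation factor screening
#'
#' \code{VIF_j = 1 / (1 - R2_j)} from regressing variable j on all others;
#' the max-VIF variable is dropped iteratively until every retained VIF is
#' at or below the threshold. Perfectly collinear variables get infinite
#' VIF and are dropped first.
#'
#' @param env An \code{env_matrix} or samples x variables numeric matrix.
#' @param threshold VIF retention threshold (default 10).
#' @return A \code{vif_report}: list with \code{vif} (final per-variable
#'   VIF), \code{retained}, \code{removed} (in removal order),
#'   \code{threshold}.
#' @export
vif_screen <- function(env, threshold = 10) {
  E <- if (inherits(env, "env_matrix")) env$env else as.matrix(env)
  if (ncol(E) < 2) stop("need >= 2 variables", call. = FALSE)
  if (nrow(E) <= ncol(E))
    stop("need more samples than variables", call. = FALSE)
  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((M[, j] - mean(M[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  M <- E
  removed <- character()
  repeat {
    if (ncol(M) < 2) break
    v <- vif_of(M)
    if (all(v <= threshold)) break
    drop <- which.max(v)
    removed <- c(removed, colnames(M)[drop])
    M <- M[, -drop, drop = FALSE]
  }
  v <- if (ncol(M) >= 2) stats::setNames(vif_of(M), colnames(M))
       else stats::setNames(1, colnames(M))
  structure(list(vif = v, retained = colnames(M), removed = removed,
                 threshold = threshold),
            class = "vif_report")
}

#' Mantel test between two distance matrices
#'
#' Correlation of the lower-triangle entries, with significance from joint
#' row/column permutations of one matrix; p uses the add-one convention.
#'
#' @param dist_a,dist_b Square symmetric matrices (or \code{dist}), same
#'   sample ordering.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return List with \code{r} and \code{p}.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1,
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  if (stats::sd(a[lower.tri(a)]) == 0 || stats::sd(b[lower.tri(b)]) == 0)
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                       method = method, permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif)
}

#' Partial Mantel test
#'
#' Partial correlation of matrices A and B residualized on C over the
#' lower triangles; permutation p as in \code{mantel_test}. The default
#' 1,000 permutations follows the common convention for
#' turnover-environment screens.
#'
#' @param dist_a,dist_b,dist_c Aligned square symmetric matrices.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param method Correlation method.
#' @return List with \code{r} and \code{p}.
#' @export
partial_mantel_test <- function(dist_a, dist_b, dist_c, n_perm = 1000,
                                seed = 1,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  set.seed(seed)
  fit <- vegan::mantel.partial(stats::as.dist(as.matrix(dist_a)),
                               stats::as.dist(as.matrix(dist_b)),
                               stats::as.dist(as.matrix(dist_c)),
                               method = method, permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif)
}

# R2 of the multivariate least-squares fit of Y on the columns of X
# (both centred): trace of fitted covariance over trace of total.
.constrained_r2 <- function(Y, X) {
  if (is.null(X) || ncol(X) == 0) return(0)
  qx <- qr(cbind(1, X))
  fitted <- qr.fitted(qx, Y)
  fitted <- sweep(fitted, 2, colMeans(Y))
  Yc <- sweep(Y, 2, colMeans(Y))
  sum(fitted^2) / sum(Yc^2)
}

#' Redundancy analysis with hierarchical variance partitioning
#'
#' The community matrix is Hellinger-transformed (square root of
#' row-normalized abundances) and the environmental variables standardized;
#' the constrained fraction is the share of total community variance
#' captured by the multivariate least-squares fit, with the Ezekiel
#' adjustment reported alongside. Per-variable independent contributions
#' come from hierarchical partitioning: the average marginal R2 gain of
#' each variable over all orderings, computed by exact subset enumeration
#' (<= 10 variables), so the contributions sum exactly to the full-model
#' constrained fraction.
#'
#' @param table An \code{otu_table} (or samples x taxa matrix).
#' @param env An \code{env_matrix} or numeric matrix of (VIF-screened)
#'   variables.
#' @param transform \code{"hellinger"} (default), \code{"proportion"} or
#'   \code{"none"}.
#' @return An \code{rda_result}: list with \code{r2} (constrained
#'   fraction), \code{r2_adjusted}, \code{axis_proportion} (per constrained
#'   axis, of total variance), \code{contributions} (per-variable
#'   independent contribution, summing to \code{r2}),
#'   \code{contributions_pct} (share of the constrained fraction).
#' @export
rda_partition <- function(table, env,
                          transform = c("hellinger", "proportion", "none")) {
  transform <- match.arg(transform)
  Y <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  E <- if (inherits(env, "env_matrix")) env$env else as.matrix(env)
  stopifnot(nrow(Y) == nrow(E))
  k <- ncol(E)
  n <- nrow(Y)
  if (k >= n) stop("need more samples than variables", call. = FALSE)
  if (k > 10) stop("hierarchical partitioning enumerates all subsets; ",
                   "<= 10 variables required (screen with vif_screen)",
                   call. = FALSE)
  Y <- switch(transform,
              hellinger = sqrt(sweep(Y, 1, rowSums(Y), "/")),
              proportion = sweep(Y, 1, rowSums(Y), "/"),
              none = Y)
  X <- scale(E)

  subsets <- 0:(2^k - 1)
  r2_sub <- numeric(length(subsets))
  for (s in subsets) {
    idx <- which(bitwAnd(s, bitwShiftL(1, 0:(k - 1))) > 0)
    r2_sub[s + 1] <- .constrained_r2(Y, X[, idx, drop = FALSE])
  }
  # average marginal gain of j over all orderings (exact Shapley weights)
  contrib <- numeric(k)
  lfac <- lfactorial(0:k)
  for (j in seq_len(k)) {
    bit_j <- bitwShiftL(1, j - 1)
    without_j <- subsets[bitwAnd(subsets, bit_j) == 0]
    for (s in without_j) {
      sz <- sum(bitwAnd(s, bitwShiftL(1, 0:(k - 1))) > 0)
      w <- exp(lfac[sz + 1] + lfac[k - sz] - lfac[k + 1])
      contrib[j] <- contrib[j] +
        w * (r2_sub[s + bit_j + 1] - r2_sub[s + 1])
    }
  }
  names(contrib) <- colnames(E)
  r2_full <- r2_sub[2^k]
  r2_adj <- 1 - (1 - r2_full) * (n - 1) / (n - k - 1)

  # per constrained axis: eigenvalues of the fitted-value covariance
  qx <- qr(cbind(1, X))
  fitted <- sweep(qr.fitted(qx, Y), 2, colMeans(Y))
  Yc <- sweep(Y, 2, colMeans(Y))
  ev <- svd(fitted, nu = 0, nv = 0)$d^2
  ev <- ev[ev > 1e-12]
  structure(list(r2 = r2_full, r2_adjusted = r2_adj,
                 axis_proportion = ev / sum(Yc^2),
                 contributions = contrib,
                 contributions_pct = 100 * contrib / r2_full,
                 transform = transform, n_variables = k),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA (%s transform): constrained R2 = %.3f (adjusted %.3f)\n",
              x$transform, x$r2, x$r2_adjusted))
  ord <- order(x$contributions, decreasing = TRUE)
  for (j in ord)
    cat(sprintf("  %-6s %.3f (%.1f%% of constrained)\n",
                names(x$contributions)[j], x$contributions[j],
                x$contributions_pct[j]))
  invisible(x)
}
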