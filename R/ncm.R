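#' Fit the Sloan neutral community model
#'
#' Under neutral drift with immigration at rate m from a regional pool, the
#' expected occurrence frequency of a taxon with mean relative abundance p
#' in communities of size N is
#' \code{F_pred(p) = 1 - pbeta(d, N m p, N m (1 - p))}, with d the detection
#' limit. m is estimated by least squares on the observed frequencies, and
#' each taxon is partitioned against a 95\% Wilson score band around its
#' prediction.
#'
#' @param table An \code{otu_table} (>= 5 samples, >= 10 taxa with
#'   nonzero abundance).
#' @param d Detection limit as relative abundance. The default
#'   \code{log(2)/N} (N = mean sample depth) is the abundance at which a
#'   taxon has a 50\% chance of appearing in a depth-N multinomial read
#'   sample (\code{1 - (1 - x)^N = 1/2}); the hard-threshold convention
#'   \code{1/N} of the classic implementations is available but
#'   overestimates m by roughly a quarter when detection is governed by
#'   read sampling.
#' @param conf Confidence level of the partition band.
#' @param n_starts Number of log-spaced multistart points for the 1-D
#'   bounded optimizer.
#' @return An \code{ncm_fit}: list with \code{m}, \code{N}, \code{d},
#'   \code{R2}, per-taxon data.frame \code{taxa} (p, freq_obs, freq_pred,
#'   ci_low, ci_high, partition), and \code{n_samples}.
#' @export
fit_ncm <- function(table, d = NULL, conf = 0.95, n_starts = 5) {
  stopifnot(inherits(table, "otu_table"))
  cc <- table$counts
  if (nrow(cc) < 5) stop("need >= 5 samples", call. = FALSE)
  depth <- rowSums(cc)
  N <- mean(depth)
  if (is.null(d)) d <- log(2) / N
  rel <- sweep(cc, 1, depth, "/")
  p <- colMeans(rel)
  keep <- p > 0
  p <- p[keep]
  if (length(p) < 10) stop("need >= 10 taxa with nonzero abundance",
                           call. = FALSE)
  f_obs <- colMeans(cc[, keep, drop = FALSE] > 0)
  fit_ncm_freq(p, f_obs, N = N, d = d, n_samples = nrow(cc), conf = conf,
               n_starts = n_starts)
}

#' @rdname fit_ncm
#'
#' @param p Per-taxon mean relative abundances (> 0).
#' @param f_obs Per-taxon observed occurrence frequencies in [0, 1].
#' @param N Community size (reads).
#' @param n_samples Number of samples behind \code{f_obs} (Wilson band n).
#' @export
fit_ncm_freq <- function(p, f_obs, N, d = log(2) / N, n_samples,
                         conf = 0.95, n_starts = 5) {
  stopifnot(length(p) == length(f_obs), all(p > 0),
            all(f_obs >= 0 & f_obs <= 1))
  if (all(f_obs == 1))
    stop("all taxa occur in every sample; occurrence frequencies are ",
         "degenerate - the fit needs prevalence spread", call. = FALSE)
  pred <- function(m) 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
  ssr <- function(m) sum((f_obs - pred(m))^2)

  starts <- exp(seq(log(1e-5), log(1), length.out = n_starts))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, ssr, method = "L-BFGS-B",
                   lower = 1e-6, upper = 1),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("NCM optimizer failed to converge from all starts", call. = FALSE)
  # polish the 1-D optimum to high precision around the best start
  bracket <- c(max(1e-6, best$par / 2), min(1, best$par * 2))
  polish <- stats::optimize(ssr, interval = bracket, tol = 1e-10)
  m_hat <- if (polish$objective <= best$value) polish$minimum else best$par
  best$value <- min(polish$objective, best$value)
  f_pred <- pred(m_hat)
  r2 <- 1 - best$value / sum((f_obs - mean(f_obs))^2)

  # Wilson score band around the predicted frequency, n = number of samples
  n <- n_samples
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (f_pred + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(f_pred * (1 - f_pred) / n + z^2 / (4 * n^2)) /
    (1 + z^2 / n)
  ci_low <- pmax(0, centre - half)
  ci_high <- pmin(1, centre + half)
  partition <- ifelse(f_obs > ci_high, "above",
                      ifelse(f_obs < ci_low, "below", "within"))

  taxon <- if (!is.null(names(p))) names(p) else paste0("t", seq_along(p))
  structure(list(
    m = m_hat, N = N, d = d, R2 = r2, n_samples = n, conf = conf,
    taxa = data.frame(taxon = taxon, p = unname(p),
                      freq_obs = unname(f_obs), freq_pred = unname(f_pred),
                      ci_low = unname(ci_low), ci_high = unname(ci_high),
                      partition = unname(partition),
                      stringsAsFactors = FALSE)),
    class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model fit\n"))
  cat(sprintf("  m = %.4g, N = %.4g, d = %.3g, R2 = %.3f (%d taxa, %d samples)\n",
              x$m, x$N, x$d, x$R2, nrow(x$taxa), x$n_samples))
  tb <- table(factor(x$taxa$partition, c("above", "within", "below")))
  cat(sprintf("  partition: %d above / %d within / %d below the %g%% band\n",
              tb["above"], tb["within"], tb["below"], 100 * x$conf))
  invisible(x)
}

#' Summarize an NCM fit
#'
#' @param fit An \code{ncm_fit}.
#' @return Serializable list: m, N, d, R2, n_taxa, and the above/within/
#'   below partition counts (summing to n_taxa).
#' @export
ncm_report <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  tb <- table(factor(fit$taxa$partition, c("above", "within", "below")))
  list(m = fit$m, N = fit$N, d = fit$d, R2 = fit$R2,
       n_taxa = nrow(fit$taxa), n_samples = fit$n_samples,
       above = unname(tb["above"]), within = unname(tb["within"]),
       below = unname(tb["below"]))
}

#' Fit the NCM separately within each sample group
#'
#' Group-absent taxa are dropped from each group's subset before fitting.
#'
#' @param table A grouped \code{otu_table}.
#' @param ... Passed to \code{fit_ncm}.
#' @return Named list of \code{ncm_fit}, one per group level.
#' @export
fit_ncm_by_group <- function(table, ...) {
  stopifnot(inherits(table, "otu_table"), !is.null(table$groups))
  out <- list()
  for (g in levels(table$groups)) {
    sub <- subset_otu(table, samples = which(table$groups == g),
                      drop_empty_taxa = TRUE)
    out[[g]] <- fit_ncm(sub, ...)
  }
  out
}
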