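#' Assemble and validate a pipeline configuration
#'
#' Either point at input files (\code{table}, \code{tree}, \code{env}
#' paths) or supply a \code{simulate} block (arguments to
#' \code{simulate_dataset}). All stochastic stages derive their seeds from
#' the single mandatory \code{seed}.
#'
#' @param table,tree,env Input file paths (OTU table TSV, Newick, CSV), or
#'   NULL when simulating.
#' @param simulate Optional named list passed to \code{simulate_dataset}.
#' @param seed Integer seed (mandatory).
#' @param outdir Output directory (NULL to skip writing files).
#' @param stages Stages to run, in dependency order.
#' @param n_null Null randomizations for betaNTI / RC-bray.
#' @param s_t Network similarity threshold.
#' @param thresholds Named overrides: bnti, rc, zi, pi, vif, fdr.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(table = NULL, tree = NULL, env = NULL,
                            simulate = NULL, seed, outdir = NULL,
                            stages = c("diversity", "ncm", "assembly",
                                       "network", "envstats"),
                            n_null = 999, s_t = 0.78,
                            thresholds = list()) {
  if (missing(seed) || !is.numeric(seed))
    stop("config error: an integer seed is mandatory", call. = FALSE)
  if (is.null(simulate) && is.null(table))
    stop("config error: provide input paths or a simulate block",
         call. = FALSE)
  th <- utils::modifyList(list(bnti = 2, rc = 0.95, zi = 2.5, pi = 0.62,
                               vif = 10, fdr = 0.05), thresholds)
  if (any(unlist(th) <= 0))
    stop("config error: thresholds must be positive", call. = FALSE)
  structure(list(table = table, tree = tree, env = env, simulate = simulate,
                 seed = as.integer(seed), outdir = outdir, stages = stages,
                 n_null = n_null, s_t = s_t, thresholds = th),
            class = "pipeline_config")
}

#' Run the full community-assembly pipeline
#'
#' Stages run in dependency order (io, diversity, ncm, assembly, network,
#' envstats); a failing stage is recorded and independent stages continue.
#' With a fixed config and seed the numerical outputs are identical across
#' runs.
#'
#' @param config A \code{pipeline_config}.
#' @return A \code{run_report}: list with \code{stages} (status, warnings
#'   per stage), \code{results} (per-stage outputs), \code{config}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(stages = list(), results = list(), config = config)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  run_stage <- function(name, fun) {
    if (!name %in% c("io", config$stages)) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    warns <- character()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        report$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!is.null(res)) {
      report$stages[[name]] <<- list(status = "ok", warnings = warns)
      report$results[[name]] <<- res
    }
    invisible(res)
  }

  io <- run_stage("io", function() {
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_dataset,
                     utils::modifyList(list(seed = config$seed),
                                       config$simulate))
      list(table = sim$table, tree = sim$tree, env = sim$env,
           truth = sim$truth)
    } else {
      tab <- read_otu_table(config$table)
      tree <- if (!is.null(config$tree)) read_newick(config$tree)
      env <- if (!is.null(config$env)) read_env(config$env)
      al <- align_inputs(tab, tree, env)
      if (!is.null(al$env) && !is.null(al$env$groups)) {
        al$table$groups <- al$env$groups[al$table$sample_ids]
      }
      al
    }
  })
  if (is.null(io)) {
    class(report) <- "run_report"
    return(report)
  }
  tab <- io$table; tree <- io$tree; env <- io$env
  groups <- tab$groups

  run_stage("diversity", function() {
    alpha <- alpha_diversity(tab)
    bc <- bray_curtis(tab)
    ord <- pcoa_ordination(bc)
    out <- list(alpha = alpha, bray_curtis = bc, pcoa = ord)
    if (!is.null(groups)) {
      out$anosim <- anosim_test(bc, groups, seed = config$seed + 11L)
      out$kw_shannon <- group_difference_test(alpha$shannon, groups)
      out$kw_chao1 <- group_difference_test(alpha$chao1, groups)
      if (nlevels(groups) == 2)
        out$differential <- differential_abundance(
          tab, alpha_fdr = config$thresholds$fdr)
    }
    if (!is.null(outdir))
      write_results(alpha, file.path(outdir, "alpha_diversity.tsv"), "tsv")
    out
  })

  run_stage("ncm", function() {
    fits <- if (!is.null(groups)) fit_ncm_by_group(tab)
            else list(all = fit_ncm(tab))
    summ <- lapply(fits, ncm_report)
    if (!is.null(outdir))
      write_results(summ, file.path(outdir, "ncm_summary.json"), "json")
    list(fits = fits, summary = summ)
  })

  run_stage("assembly", function() {
    if (is.null(tree)) stop("assembly stage requires a phylogeny")
    bn <- bnti(tab, tree, n_null = config$n_null,
               seed = config$seed + 21L)
    rc <- raup_crick_bray(tab, n_null = config$n_null,
                          seed = config$seed + 22L)
    part <- classify_processes(bn, rc,
                               bnti_threshold = config$thresholds$bnti,
                               rc_threshold = config$thresholds$rc,
                               groups = groups)
    out <- list(bnti = bn, rc = rc, partition = part)
    if (!is.null(env))
      out$env_association <- bnti_env_association(
        bn, env, seed = config$seed + 23L)
    if (!is.null(outdir)) {
      write_results(part$pairs, file.path(outdir, "assembly_pairs.tsv"),
                    "tsv")
      write_results(lapply(part$fractions, as.list),
                    file.path(outdir, "process_fractions.json"), "json")
    }
    out
  })

  run_stage("network", function() {
    nets <- list()
    build_one <- function(sub) {
      cm <- correlation_matrix(sub)
      net <- build_network(cm, s_t = config$s_t, taxonomy = sub$taxonomy)
      if (net$empty) return(list(network = net, empty = TRUE))
      mods <- module_detection(net, seed = config$seed + 31L)
      roles <- zi_pi(net, mods, zi_threshold = config$thresholds$zi,
                     pi_threshold = config$thresholds$pi)
      list(network = net, modules = mods,
           metrics = topology_metrics(net, mods), roles = roles,
           keystone = keystone_report(roles, sub))
    }
    if (!is.null(groups)) {
      for (g in levels(groups))
        nets[[g]] <- build_one(subset_otu(tab,
                                          samples = which(groups == g),
                                          drop_empty_taxa = TRUE))
    } else nets$all <- build_one(tab)
    if (!is.null(outdir)) {
      for (g in names(nets)) {
        if (isTRUE(nets[[g]]$empty)) next
        write_results(nets[[g]]$network,
                      file.path(outdir, paste0("network_", g, ".graphml")),
                      "graphml")
        write_results(nets[[g]]$metrics,
                      file.path(outdir, paste0("network_", g, ".json")),
                      "json")
      }
    }
    nets
  })

  run_stage("envstats", function() {
    if (is.null(env)) stop("envstats stage requires metadata")
    vr <- vif_screen(env, threshold = config$thresholds$vif)
    Er <- env$env[, vr$retained, drop = FALSE]
    bc <- bray_curtis(tab)
    mt <- mantel_test(bc, as.matrix(stats::dist(scale(Er))),
                      seed = config$seed + 41L)
    rda <- rda_partition(tab, Er)
    out <- list(vif = vr, mantel = mt, rda = rda)
    if (!is.null(outdir))
      write_results(list(retained = vr$retained, r2 = rda$r2,
                         r2_adjusted = rda$r2_adjusted,
                         contributions = as.list(rda$contributions)),
                    file.path(outdir, "envstats.json"), "json")
    out
  })

  class(report) <- "run_report"
  report
}

#' Consolidated human-readable report
#'
#' One Markdown and one JSON summary of a pipeline run: per-group alpha
#' diversity, ANOSIM, NCM m/R-squared, assembly process fractions, network
#' topology table and keystone list.
#'
#' @param report A \code{run_report}.
#' @param path Optional output path stem; writes \code{<stem>.md} and
#'   \code{<stem>.json}.
#' @return Invisibly, the JSON-ready summary list.
#' @export
make_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "run_report"))
  res <- report$results
  summ <- list(stages = lapply(report$stages, `[[`, "status"))
  md <- c("# Community assembly pipeline report", "")
  if (!is.null(res$diversity)) {
    a <- res$diversity$alpha
    by_g <- split(a, a$group)
    summ$alpha <- lapply(by_g, function(d)
      list(n = nrow(d), chao1_mean = mean(d$chao1),
           shannon_mean = mean(d$shannon)))
    md <- c(md, "## Alpha diversity", "",
            "| group | n | mean Chao1 | mean Shannon |",
            "|---|---|---|---|",
            vapply(names(by_g), function(g)
              sprintf("| %s | %d | %.1f | %.2f |", g, nrow(by_g[[g]]),
                      mean(by_g[[g]]$chao1), mean(by_g[[g]]$shannon)),
              character(1)), "")
    if (!is.null(res$diversity$anosim)) {
      summ$anosim <- res$diversity$anosim
      md <- c(md, sprintf("ANOSIM: R = %.3f, p = %.4g",
                          res$diversity$anosim$R, res$diversity$anosim$p),
              "")
    }
  }
  if (!is.null(res$ncm)) {
    summ$ncm <- res$ncm$summary
    md <- c(md, "## Neutral community model", "",
            "| group | m | R2 | above | within | below |",
            "|---|---|---|---|---|---|",
            vapply(names(res$ncm$summary), function(g) {
              s <- res$ncm$summary[[g]]
              sprintf("| %s | %.4f | %.3f | %d | %d | %d |", g, s$m, s$R2,
                      s$above, s$within, s$below)
            }, character(1)), "")
  }
  if (!is.null(res$assembly)) {
    fr <- lapply(res$assembly$partition$fractions, function(f)
      as.list(stats::setNames(as.numeric(f), names(f))))
    summ$process_fractions <- fr
    md <- c(md, "## Assembly processes (% of classified pairs)", "")
    for (g in names(fr))
      md <- c(md, sprintf("- %s: %s", g,
                          paste(sprintf("%s %.1f%%", names(fr[[g]]),
                                        unlist(fr[[g]])), collapse = ", ")))
    md <- c(md, "")
  }
  if (!is.null(res$network)) {
    md <- c(md, "## Network topology", "",
            "| group | nodes | edges | avgK | avgCC | GD | Q | power-law R2 | % positive |",
            "|---|---|---|---|---|---|---|---|---|")
    summ$network <- list()
    for (g in names(res$network)) {
      mtr <- res$network[[g]]$metrics
      if (is.null(mtr) || isTRUE(mtr$empty)) {
        md <- c(md, sprintf("| %s | (empty) | | | | | | | |", g))
        next
      }
      summ$network[[g]] <- mtr
      md <- c(md, sprintf(
        "| %s | %d | %d | %.2f | %.3f | %.2f | %.3f | %s | %.1f |",
        g, mtr$nodes, mtr$edges, mtr$avgK, mtr$avgCC, mtr$GD,
        mtr$modularity,
        ifelse(is.na(mtr$powerlaw_r2), "NA",
               sprintf("%.3f", mtr$powerlaw_r2)),
        mtr$pct_positive))
      ks <- res$network[[g]]$keystone
      if (!is.null(ks) && nrow(ks))
        summ$network[[g]]$keystone <- ks$taxon
    }
    md <- c(md, "")
  }
  if (!is.null(res$envstats)) {
    summ$envstats <- list(retained = res$envstats$vif$retained,
                          rda_r2 = res$envstats$rda$r2,
                          rda_r2_adjusted = res$envstats$rda$r2_adjusted,
                          mantel = res$envstats$mantel)
    md <- c(md, "## Environment association", "",
            sprintf("Retained after VIF screen: %s",
                    paste(res$envstats$vif$retained, collapse = ", ")),
            sprintf("RDA constrained R2 = %.3f (adjusted %.3f); Mantel r = %.3f (p = %.4g)",
                    res$envstats$rda$r2, res$envstats$rda$r2_adjusted,
                    res$envstats$mantel$r, res$envstats$mantel$p), "")
  }
  if (!is.null(path)) {
    writeLines(md, paste0(path, ".md"))
    write_results(summ, paste0(path, ".json"), "json")
  }
  invisible(summ)
}
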