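#!/usr/bin/env Rscript
# Alpha diversity (Chao1, Shannon), rarefaction, Bray-Curtis/PCoA, and
# group contrasts (Kruskal-Wallis, ANOSIM, Wilcoxon + FDR) between the
# two seasons of the simulated study.

suppressMessages(library(riverassembly))

outdir <- "results/diversity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tab <- read_otu_table("results/data/otu_table.tsv")
env <- read_env("results/data/metadata.csv")
tab$groups <- env$groups[tab$sample_ids]

alpha <- alpha_diversity(tab)
write_results(alpha, file.path(outdir, "alpha_diversity.tsv"), "tsv")
for (idx in c("chao1", "shannon")) {
  kw <- group_difference_test(alpha[[idx]], tab$groups)
  message(sprintf("%s: WS %.1f vs DS %.1f (Kruskal-Wallis H = %.2f, p = %.3g)",
                  idx, mean(alpha[[idx]][alpha$group == "WS"]),
                  mean(alpha[[idx]][alpha$group == "DS"]), kw$H, kw$p))
}

rcurve <- rarefaction_curve(tab, n_iter = 10, seed = 2)
write_results(rcurve, file.path(outdir, "rarefaction.tsv"), "tsv")

bc <- bray_curtis(tab)
ord <- pcoa_ordination(bc, k = 2)
coords <- data.frame(sample = rownames(ord$coords), ord$coords,
                     group = as.character(tab$groups))
write_results(coords, file.path(outdir, "pcoa_coordinates.tsv"), "tsv")
message(sprintf("PCoA axes 1+2 explain %.1f%% of Bray-Curtis variation",
                100 * sum(ord$proportion[1:2])))

an <- anosim_test(bc, tab$groups, n_perm = 999, seed = 3)
message(sprintf("ANOSIM between seasons: R = %.3f, p = %.4g", an$R, an$p))

da <- differential_abundance(tab)
write_results(da, file.path(outdir, "differential_abundance.tsv"), "tsv")
message(sprintf("%d/%d taxa differentially abundant at FDR 0.05",
                sum(da$significant), nrow(da)))

write_results(list(anosim_R = an$R, anosim_p = an$p,
                   pcoa_axis12_pct = 100 * sum(ord$proportion[1:2]),
                   n_significant_taxa = sum(da$significant)),
              file.path(outdir, "summary.json"), "json")
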