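#!/usr/bin/env Rscript
# Environment-community association: VIF screening of the hydrochemical
# variables, Mantel test of community vs environmental distance, and RDA
# with exact hierarchical partitioning of the constrained variance.

suppressMessages(library(riverassembly))

outdir <- "results/envstats"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tab <- read_otu_table("results/data/otu_table.tsv")
env <- read_env("results/data/metadata.csv")
tab$groups <- env$groups[tab$sample_ids]

vr <- suppressWarnings(vif_screen(env, threshold = 10))
message("VIF screen retained: ", paste(vr$retained, collapse = ", "))
if (length(vr$removed))
  message("  removed (in order): ", paste(vr$removed, collapse = ", "))

Er <- env$env[, vr$retained, drop = FALSE]
bc <- bray_curtis(tab)
mt <- mantel_test(bc, as.matrix(dist(scale(Er))), n_perm = 999, seed = 31)
message(sprintf("Mantel (community vs environment): r = %.3f, p = %.4g",
                mt$r, mt$p))

Er10 <- Er[, seq_len(min(10, ncol(Er))), drop = FALSE]
rda <- rda_partition(tab, Er10)
print(rda)
write_results(list(
  vif = as.list(vr$vif), retained = vr$retained, removed = vr$removed,
  mantel_r = mt$r, mantel_p = mt$p,
  rda_r2 = rda$r2, rda_r2_adjusted = rda$r2_adjusted,
  contributions_pct = as.list(rda$contributions_pct)),
  file.path(outdir, "envstats.json"), "json")
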