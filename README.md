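# riverassembly

Quantifies the ecological processes that assemble microbial communities
— the balance of deterministic selection and stochastic
dispersal/drift — from an OTU/ASV count table, a rooted phylogeny and
sample metadata. It is written for microbial ecologists analysing
amplicon surveys of environmental communities (the motivating use case
is seasonal river bacterioplankton), and covers the full standard
workflow as tested, seeded, scriptable R functions.

## What it computes

**Sloan neutral community model.** A taxon with regional mean relative
abundance *p* has latent local abundance *x* ~ Beta(*Nmp*, *Nm*(1−*p*))
under neutral drift with immigration rate *m* into communities of size
*N*; its predicted occurrence frequency is
F(*p*) = 1 − BetaCDF(*d*; *Nmp*, *Nm*(1−*p*)). `fit_ncm()` estimates *m*
by least squares on the observed frequencies, reports R², and partitions
taxa against a 95% Wilson band (above / within / below the neutral
expectation).

**Null-model process partitioning.** `bnti()` computes the beta nearest
taxon index — the z-score of abundance-weighted βMNTD against a
tip-shuffling null — and `raup_crick_bray()` the Bray–Curtis Raup–Crick
index against probabilistically assembled null communities (richness and
depth preserved; identities ∝ occupancy, reads ∝ regional abundance).
`classify_processes()` applies the conventional thresholds per sample
pair: βNTI > 2 heterogeneous selection, βNTI < −2 homogeneous selection,
otherwise RC_bray > 0.95 dispersal limitation, RC_bray < −0.95
homogenizing dispersal, else undominated — and reports percentage
fractions overall and per group.

**Co-occurrence networks.** Spearman correlations on relative abundances
(prevalence-filtered), edges at |ρ| ≥ S_t = 0.78 and p < 0.05, greedy
modularity, topology metrics (avgK, avgCC, GD, Q, power-law R², %
positive edges), Zi–Pi node roles (peripheral / connector / module hub /
network hub; non-peripherals are keystone taxa) and an optional
random-matrix-theory threshold scan.

**Supporting statistics.** Chao1, Shannon, rarefaction, Bray–Curtis,
PCoA, ANOSIM, Kruskal–Wallis, per-taxon Wilcoxon with
Benjamini–Hochberg FDR, VIF screening, Mantel / partial Mantel, and RDA
with exact hierarchical partitioning of per-variable contributions.

**Synthetic communities with known assembly regimes.** The generator
produces OTU tables, Yule phylogenies with conserved niche traits, and
seasonal environmental matrices under five regimes (neutral,
heterogeneous/homogeneous selection, dispersal limitation, homogenizing
dispersal), so every inference above has a ground-truth recovery test.

## Worked example

Simulate a two-season study (wet season *m* = 0.105, dry season
*m* = 0.026, shared regional pool), fit the neutral model per season and
partition the assembly processes:

```r
library(riverassembly)

ds <- simulate_dataset(n_per_group = 10, n_taxa = 400, depth = 5000,
                       m = c(WS = 0.105, DS = 0.026), seed = 7)
fits <- fit_ncm_by_group(ds$table)
print(fits$WS)
#> Sloan neutral community model fit
#>   m = 0.1137, N = 5000, d = 0.000139, R2 = 0.838 (374 taxa, 10 samples)
#>   partition: 92 above / 276 within / 6 below the 95% band
print(fits$DS)
#> Sloan neutral community model fit
#>   m = 0.02697, N = 5000, d = 0.000139, R2 = 0.723 (338 taxa, 10 samples)
#>   partition: 54 above / 266 within / 18 below the 95% band

bn <- bnti(ds$table, ds$tree, n_null = 199, seed = 8)
rc <- raup_crick_bray(ds$table, n_null = 199, seed = 9)
part <- classify_processes(bn, rc, groups = ds$table$groups)
print(part)
#> Assembly process partition (190 pairs, 0 undefined)
#>   overall: heterogeneous_selection 2.6%, homogeneous_selection 1.6%, dispersal_limitation 44.7%, homogenizing_dispersal 0.0%, undominated 51.1%
#>   WS: heterogeneous_selection 4.4%, homogeneous_selection 0.0%, dispersal_limitation 95.6%, homogenizing_dispersal 0.0%, undominated 0.0%
#>   DS: heterogeneous_selection 2.2%, homogeneous_selection 0.0%, dispersal_limitation 37.8%, homogenizing_dispersal 0.0%, undominated 60.0%
```

The fitted migration rates recover the generating values (0.114 vs
0.105; 0.027 vs 0.026), and the season simulated with restricted
immigration at this depth shows turnover partly inside the Raup–Crick
null envelope, while the pooled regional occupancy makes within-season
pairs of the high-immigration season read as dispersal-limited relative
to the two-season pool — the kind of pool-dependence the methods
vignette discusses.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes the synthetic study to
`results/data/`, and `02_diversity.R` … `07_report.R` read those files
and write diversity, NCM, assembly, network and environment-association
tables plus a consolidated Markdown/JSON report under `results/`.

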