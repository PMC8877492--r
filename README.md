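# haptonet

Post-denoising analysis of marine pico-eukaryote amplicon surveys, built
around the study design of Arctic pico-haptophyte 18S rRNA metabarcoding:
paired surface and subsurface-chlorophyll-maximum (SCM) samples across
stations, a ZOTU (zero-radius OTU) count table, sample metadata, and an
optional rooted phylogeny. It is aimed at microbial ecologists who want
the full downstream chain — diversity, ordination, driver attribution,
co-occurrence networks, and network robustness — as seeded, scriptable,
tested R functions rather than a sequence of GUI tools.

## What it computes

* **Alpha diversity** after seeded rarefaction to even depth: richness,
  Shannon entropy *H* = −Σ *p*ᵢ ln *p*ᵢ, and Faith's phylogenetic
  diversity (stem-inclusive minimal subtree length), with rank-sum
  habitat comparisons and Spearman correlations against covariates.
* **Beta diversity**: Bray–Curtis Σ|*x*−*y*| / Σ(*x*+*y*) and weighted
  UniFrac Σ_b *l*_b |*p*_A(b) − *p*_B(b)| (raw or normalized), principal
  coordinates analysis, and ANOSIM
  *R* = (r̄_between − r̄_within)/(n(n−1)/4) with permutation p-values —
  including exact exhaustive enumeration at small *n*.
* **Environmental drivers**: Mantel tests of community distance against
  z-scored covariate distances (and haversine geographic distance),
  LMG variance decomposition of the distance regression (each
  predictor's share of *R*² averaged over all predictor orderings), and
  a taxon-by-covariate Spearman screen with Benjamini–Hochberg control.
* **Co-occurrence network**: ZOTUs deleted only when relative abundance
  < 0.01% **and** prevalence < 25%; Spearman correlations on relative
  abundances; edges where BH-adjusted *q* < 0.01 and ρ ≥ 0.6; habitat
  enrichment classes; seeded Louvain modules; node metrics (degree,
  normalized betweenness, component-scaled closeness) and network
  metrics (density, diameter, clustering, path length).
* **Robustness**: natural connectivity
  λ̄ = ln[(1/N) Σᵢ exp(λᵢ)] over adjacency eigenvalues, tracked while
  nodes are removed by intact-graph degree or betweenness rank or at
  random, plus dominance comparison of attack curves.
* **Synthetic surveys**: a generator that plants habitat contrasts, a
  temperature driver, and latent correlation blocks with known ground
  truth, so every stage above is testable offline.

## Worked example

```r
library(haptonet)
cfg <- pipeline_config(seed = 1, n_permutations = 199,
                       attack = list(step = 1, max_fraction = 0.8,
                                     repetitions = 50))
bundle <- run_pipeline(cfg)
print(bundle)
```

```
Community analysis results bundle
  samples: 28 | ZOTUs: 300 (network stage: 300 after filter)
  rarefied to 38103 reads/sample
  ANOSIM (Bray-Curtis): R = 0.391, p = 0.005
  ANOSIM (weighted UniFrac): R = 0.187, p = 0.005
  top Mantel driver: temperature (R^2 = 0.291, p = 0.005)
  LMG: total R^2 = 0.416; largest share temperature (28.3%)
  network: 205 nodes, 2669 edges; modularity Q = 0.226
  enriched ZOTUs: 90 surface, 15 SCM
  pattern flags: surface_alpha_higher, habitat_anosim_significant, surface_subnetwork_denser, surface_more_robust
```

Reading the output: the habitats separate compositionally (ANOSIM R > 0
at p < 0.05 on both metrics); temperature — the planted driver — tops
the Mantel screen and takes the largest LMG share; far more ZOTUs are
surface-enriched than SCM-enriched; and the four pattern flags confirm
the planted structure was recovered end to end (higher surface alpha
diversity, habitat separation, a denser surface subnetwork, and a
surface attack curve that dominates the SCM curve).
`write_results_bundle(bundle, dir)` exports every stage as TSV/JSON plus
GraphML/GML networks. A thin CLI lives at `inst/cli/haptonet.R`
(`simulate` and `run` subcommands).

## Package layout

| Path | Contents |
| --- | --- |
| `R/synthetic.R` | survey designs, metadata/count/tree generators, ground truth |
| `R/io.R` | TSV/Newick/GraphML/GML/JSON readers and writers |
| `R/diversity.R` | rarefaction, alpha diversity, group comparisons |
| `R/beta.R` | Bray–Curtis, weighted UniFrac, PCoA, ANOSIM |
| `R/drivers.R` | environmental distances, Mantel, LMG, taxon screen |
| `R/network.R` | filtering, Spearman/BH, graph construction, modules, metrics |
| `R/robustness.R` | natural connectivity, attack curves, dominance |
| `R/pipeline.R` | configuration, orchestration, results bundle |
| `vignettes/haptonet-methods.Rmd` | model, conventions, design rationale |
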