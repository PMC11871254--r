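# MicroNetStab

Seasonal microbial co-occurrence networks and their stability.

`MicroNetStab` is an R package for ecologists analysing paired bacterial
and protist OTU tables from seasonal surveys (e.g. lake water sampled
over four seasons at several depths). It answers two linked questions:
how do the co-occurrence networks of a bacterial community differ across
seasons, and does adding the relations of bacterivorous protozoans (BP)
— the protists that graze on bacteria — change the stability of those
networks?

## What it computes

**Networks.** Pairwise Spearman correlations with t-approximation
p-values; signed networks thresholded at |ρ| > 0.6 and p < 0.05 (the
classical criterion; both configurable, strict inequalities);
single-kingdom subnetworks; "+BP" networks in which bacteria–BP edges
are added to the bacterial network (BP–BP edges excluded by default);
a census of cross-kingdom edges by protist feeding mode; topology
reports (degree, density, seeded Louvain modularity, clustering, giant
component).

**Stability — the four-index suite.**

- *Robustness*: fraction of taxa that keep at least one edge after
  random removal of a fraction f of nodes (default 0.5), mean ± sd over
  seeded trials.
- *Vulnerability*: max over nodes i of (E − E_i)/E, where
  E = (2/(N(N−1))) Σ_{u<v} 1/d(u,v) is global efficiency.
- *Cohesion*: taxa-shuffle null-corrected pairwise correlations →
  per-taxon positive/negative connectedness → abundance-weighted
  per-sample components C⁺, C⁻ and the negative:positive ratio
  |C⁻|/C⁺.
- *Natural connectivity*: λ̄ = ln((1/N) Σ exp(λ_i)) over adjacency
  eigenvalues, plus its decay slope (with fit R) under progressive
  random node removal.

Seasons and ±BP conditions are compared with a one-way ANOVA letter
display on the robustness replicates (pairwise Welch t + Holm).

**Community statistics.** Richness, Shannon diversity (nats),
Bray–Curtis dissimilarity, PCoA, ANOSIM and (partial) Mantel permutation
tests with explicit seeds, the add-one p-value rule and an exact
enumeration mode for small designs.

**Synthetic communities.** A seeded generator
(Gaussian copula → seasonal log-mean shifts → log-normal abundances →
multinomial reads) plants correlation blocks and bacterivore–bacterium
trophic couplings with known ground truth, emulating a 4 seasons ×
3 depths × 3 replicates design, so the whole pipeline is testable
without any sequencing data.

## Worked example

```r
library(MicroNetStab)

cfg <- simConfig(nBacteria = 40, nProtists = 12, nBacterivores = 5,
                 seqDepth = 20000,
                 modules = list(list(taxa = sprintf("B%03d", 1:5), rho = 0.85)),
                 trophicLinks = list(list(predator = "P001", prey = "B010",
                                          rho = 0.75)),
                 seed = 42)
g <- generateCommunity(cfg)
g$otu
#> OtuExperiment: 52 taxa x 36 samples (bacteria: 40, protist: 12)

otu  <- filterPrevalence(g$otu, minSamples = 12)   # present in 1/3 of samples
bact <- otu[kingdom(otu) == "bacteria", ]
bp   <- otu[!is.na(functionalGroup(otu)) &
              functionalGroup(otu) == "bacterivore", ]

net <- augmentWithBp(bact, bp)      # joint Spearman, bacteria + BP edges
net
#> SignedNetwork: 45 nodes, 11 edges (10 positive, 1 negative)

rb <- robustness(net, removalFraction = 0.5, trials = 100, seed = 1)
sprintf("robustness: %.3f +/- %.3f", rb$mean, rb$sd)
#> "robustness: 0.088 +/- 0.043"

naturalConnectivity(net)
#> [1] 0.354

dec <- naturalConnectivityDecay(net, trials = 10, seed = 1)
sprintf("decay slope: %.4f (R = %.3f)", dec$slope, dec$r)
#> "decay slope: -0.0097 (R = -0.993)"

co <- cohesion(bact, nullIters = 200, seed = 1)
sprintf("neg:pos cohesion ratio: %.3f +/- %.3f", co$ratioMean, co$ratioSd)
#> "neg:pos cohesion ratio: 1.017 +/- 0.233"

bc <- brayCurtis(bact)
anosim(bc, colData(bact)$season, nPerm = 999, seed = 1)
#> ANOSIM: statistic = 0.536008, p = 0.001 (999 permutations)
```

Reading the numbers: the sparse example network loses most taxa under
50% random removal (robustness 0.088 — only well-connected taxa
persist); the decay slope of natural connectivity is shallow and almost
perfectly linear (R = −0.993); the cohesion ratio near 1 says negative
and positive associations are balanced; and ANOSIM confirms the planted
seasonal structure (R = 0.54 at the permutation floor p = 0.001).

The full experiment — per-season bacteria-only and +BP networks,
topology, all four stability indices, the cross-kingdom census, the
ANOSIM/Mantel tests and the letter display, with every artifact written
as TSV plus an MD5 manifest — is one call:

```r
res <- runPipeline(pipelineConfig(mode = "synthetic", sim = cfg,
                                  outDir = "run1", seed = 1))
```

Configurations can also be read from YAML (`readPipelineConfig()`), and
`mode = "files"` consumes user TSV tables (taxa × samples counts,
sample metadata, a two-column feeding-mode map) instead of the
simulator.

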