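---
title: "Seasonal microbial co-occurrence networks and their stability"
author: "MicroNetStab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal microbial co-occurrence networks and their stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroNetStab)
```

## The analysis this package implements

Lake bacterial and protist communities are surveyed with amplicon
sequencing across seasons and depths, yielding taxa-by-samples OTU count
tables. A recurring question is whether biotic interactions — in
particular predation by bacterivorous protozoans (BP) — stabilise or
destabilise the bacterial community. The standard workflow is:

1. build a signed co-occurrence network from pairwise Spearman
   correlations, keeping pairs with $|\rho| > 0.6$ and $p < 0.05$;
2. derive per-season networks, a bacteria-only (single-kingdom) variant
   and a "+BP" variant in which bacterivore–bacterium relations are added
   to the bacterial network;
3. score each network with four stability indices — robustness,
   vulnerability, cohesion and natural connectivity — and compare seasons
   and ±BP conditions with a one-way ANOVA letter display;
4. support the comparison with community statistics: richness, Shannon
   diversity, Bray–Curtis dissimilarity, PCoA, ANOSIM across seasons and
   (partial) Mantel tests.

`MicroNetStab` implements this workflow as reusable, seeded functions
plus a one-call pipeline (`runPipeline()`), and pairs it with a
synthetic seasonal community generator so the entire analysis can be
validated against planted ground truth.

## Network construction

`spearmanMatrix()` computes $\rho$ as Pearson correlation of midranks
(average ranks on ties) and two-sided p-values from the
t-approximation $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of
freedom; $|\rho| = 1$ maps to $p = 0$. The t-approximation matches what
the common network tools do at $n = 9$–$36$ samples; an exact
permutation p-value is not attempted. Constant taxa have no defined rank
correlation and are rejected by name — `filterPrevalence()` exists to
remove them first.

`buildNetwork()` applies the thresholds as strict inequalities
($|\rho| > r_\min$ AND $p < p_\max$); the classical criterion is stated
with strict operators and ties at the boundary are vanishingly rare on
continuous statistics. Isolated nodes are retained, because node-removal
indices are defined over the full taxon set. Raw p-values are used by
default — the criterion in the literature this reproduces is an
uncorrected $p < 0.05$ — and a Benjamini–Hochberg option
(`bhCorrect = TRUE`) is available.

The "+BP" variant (`augmentWithBp()`) recomputes Spearman correlations
jointly on the concatenated bacteria + bacterivore table and keeps
bacteria–bacteria and bacteria–BP edges. Whether BP–BP edges belong in a
"+BP" network is ambiguous in the source literature; "adding BP
relationships *to the bacterial community*" reads most naturally as
cross-kingdom relations only, so BP–BP edges are excluded by default and
admitted with `includeBpBp = TRUE`. Because Spearman correlations are
pairwise, joint recomputation cannot change bacteria–bacteria edges —
a property the test suite asserts.

## The four stability indices

**Robustness** (`robustness()`): per trial, $\lfloor f N \rfloor$ nodes
are removed uniformly at random ($f = 0.5$ by default); a survivor
persists iff it keeps at least one edge among survivors; robustness is
persisting/$N$, reported as mean ± sd over trials (default 100). This is
the simplest Dunne-style random-removal rule: no secondary-extinction
cascade and no abundance weighting, so a complete graph attains exactly
$1 - f$ and an edgeless graph 0. The removal count uses the floor, so
for odd $N$ the attainable maximum is marginally above $1 - f$.

**Vulnerability** (`vulnerability()`): with global efficiency
$E = \frac{2}{N(N-1)} \sum_{u<v} 1/d(u,v)$ (unweighted shortest paths,
unreachable pairs contributing 0), vulnerability is
$\max_i (E - E_i)/E$ where $E_i$ removes node $i$. Counting unreachable
pairs as zero keeps $E$ monotone under edge addition and makes the index
well defined on disconnected networks.

**Natural connectivity** (`naturalConnectivity()`):
$\bar\lambda = \ln\left(\frac{1}{N}\sum_i e^{\lambda_i}\right)$ over the
eigenvalues of the unsigned, unweighted adjacency matrix, evaluated with
a log-sum-exp so large spectra do not overflow. Its decay under
progressive random removal (`naturalConnectivityDecay()`) is summarised
by the OLS slope of mean $\bar\lambda$ against the number removed over
removals $1..\lfloor 0.8N \rfloor$, together with the Pearson $R$ of
that fit — the slope-and-R presentation used for seasonal decay curves.

**Cohesion** (`cohesion()`): on relative abundances, observed pairwise
Pearson correlations are corrected by the taxa-shuffle null model (each
taxon's abundance vector permuted independently across samples,
`nullIters = 200` by default); each taxon's positive (negative)
connectedness is the mean of its positive (negative) corrected
correlations; per-sample cohesion is the abundance-weighted sum
$C^{\pm}_i = \sum_j \mathrm{ra}_{ij}\,\mathrm{conn}^{\pm}_j$, and the
negative:positive ratio $|C^-_i|/C^+_i$ is reported as mean ± sd over
samples. In the pipeline, cohesion is computed from the same per-season
samples that underlie that season's network; with 9 samples per season
the correlation estimates are noisy, which the small-$n$ caveat in the
output parameters records.

A property of this classical estimator worth knowing: because the
positive part of a zero-mean correlation has positive expectation, the
pair-level null correction leaves a baseline of order
$1/\sqrt{n_\text{samples}}$ in both components even on structureless
data (≈ 0.13 at $n = 36$), and compositional closure tilts the ratio
slightly above 1. The components are therefore comparative quantities,
not absolute zeros. For applications that need null-calibrated
components, `nullCorrection = "connectedness"` subtracts the
taxa-shuffle expectation of the connectedness itself, which centres both
components near 0 on structureless data — at the cost that per-sample
components are no longer sign-constrained and the ratio is frequently
undefined under the null. The default remains the classical pair-level
form.

**Letter display** (`compareStability()`): a one-way ANOVA across
conditions on the per-trial robustness replicates; if significant at
$\alpha = 0.05$, pairwise Welch t-tests with Holm correction define the
groups, and letters are assigned deterministically in descending-mean
order (conditions not significantly different share a letter).

## Community statistics

Shannon diversity uses natural logarithms (the convention of the vegan
ecosystem, which also provides the implementation). Bray–Curtis is
$d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, delegated to
`vegan::vegdist`. PCoA Gower-centres $-d^2/2$ and eigendecomposes;
axes with negative eigenvalues are dropped and reported rather than
corrected (no Lingoes/Cailliez by default), and asking for more axes
than there are positive eigenvalues truncates with a flag instead of
failing.

ANOSIM and the Mantel family are implemented in-package because their
permutation conventions are pinned down: midranks for tied distances,
the add-one rule $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_\text{perm})$ so $p = 0$ is impossible, Mantel one-sided (greater),
Pearson on the distance vectors by default (Spearman available — the
source literature does not say which it used), and an `exact = TRUE`
mode that enumerates all $n!$ permutations for small designs, used by
the test suite against brute-force enumeration oracles. Every
permutation test takes an explicit seed.

## The synthetic community generator

`simConfig()`/`generateCommunity()` emulate a seasonal lake survey:
4 seasons × 3 depths × 3 replicates = 36 samples by default. The
generative chain is

1. a latent Gaussian field per sample whose correlation matrix carries
   the planted structure — within-block correlations $\rho_\text{block}$
   and bacterivore–bacterium trophic couplings (positive by default,
   since grazers track their prey's abundance); positive definiteness is
   validated at construction;
2. per-taxon, per-season log-mean shifts
   $\sim N(0, \texttt{seasonEffectSd}^2)$, which create the seasonal
   PCoA clustering and ANOSIM signal without introducing cross-taxon
   correlation (each taxon's shift is independent);
3. exponentiation to log-normal abundances: baseline log-means
   $\sim N(0, \texttt{baselineSd}^2)$ give the heavy-tailed
   rank–abundance profile of real OTU tables, and the correlated latent
   field enters scaled by `dispersionSd`;
4. a multinomial draw of `seqDepth` reads per sample, so counts are
   compositional and column sums are exact.

Because every transformation after the latent field is monotone per
taxon, a planted latent $\rho$ survives as a rank correlation of nearly
the same magnitude (attenuated only by sequencing noise), which is
exactly the quantity the Spearman edge test targets.

Defaults: `nBacteria = 100`, `nProtists = 30`, `nBacterivores = 10`
(bacterivores and phototrophs dominate lake protist communities, so the
non-bacterivores are labelled phototrophs), `seqDepth = 20000`,
`seasonEffectSd = 0.8` (clear seasonal separation of the kind seen in
seasonal surveys without drowning within-season variation),
`dispersionSd = 1.0` and `baselineSd = 1.5` (log-normal overdispersion
typical of OTU data). Calibration experiments that measure recovery of
planted correlations (block recovery, trophic-link detection) are run
with `seasonEffectSd = 0`: the seasonal shift is an independent variance
component orthogonal to the planted structure, and leaving it in would
attenuate the very correlation whose recovery is being measured —
those experiments characterise the edge test, not the seasonal design.

What the generator does **not** emulate: mechanistic predator–prey
dynamics (no Lotka–Volterra feedback, couplings are correlational),
absolute abundances, season-specific correlation rewiring, taxonomic
structure, and read-level artefacts (chimeras, PCR bias). Passing tests
on synthetic data therefore validate the statistical machinery — they do
not certify that co-occurrence edges on real data are trophic
interactions, which remain putative.

## Numerical and design choices

- **Prevalence filter.** Spearman on near-constant zero rows is
  degenerate, and the source workflows are silent on rare-taxon
  filtering; the pipeline's declared convention is presence in ≥ 1/3 of
  the samples under analysis (≥ 3 of 9 for a seasonal network),
  configurable via `minPrevalenceFrac`.
- **Seeding.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state. The pipeline derives per-stage seeds
  with `childSeed()` (a 31-bit hash of the stage name combined with the
  master seed), so any stage can be re-run in isolation and the whole
  run is a pure function of (config, seed); `manifest.tsv` records MD5
  hashes of every artifact to make that checkable.
- **Community detection.** Modularity is reported for the partition
  found by seeded Louvain on the unsigned skeleton (the algorithm behind
  the usual GUI defaults is unstated in the source literature; Louvain
  is the standard choice and the seed makes it reproducible). The
  partition itself is attached to the `topology()` report.
- **Degenerate inputs.** All-zero samples are rejected by name rather
  than dropped; edgeless networks have robustness 0 and natural
  connectivity 0 (not errors); vulnerability requires a component of ≥ 3
  nodes; samples with zero positive cohesion are excluded from the ratio
  and counted; a partial-Mantel control collinear with `d2` returns 0
  when the numerator vanishes with the denominator and errors otherwise.
- **Problem sizes.** The shipped tests and the acceptance script scale
  the experiments to run quickly while keeping the statistics
  well-behaved: e.g. 60 bacteria + 20 protists at depth 20,000 for the
  pipeline run, 40 taxa × 36 samples × 5–10 seeds for edge-recovery
  calibration, 100–2000 robustness trials depending on the check. These
  sizes are the package's own validation choices; all of them are
  parameters the user can raise.

## Known limitations

- Spearman-threshold networks are not compositionality-aware; on strongly
  compositional data closure induces spurious negative correlations.
  SparCC/SPIEC-EASI-style inference is deliberately out of scope.
- Co-occurrence edges are statistical associations; calling a
  bacteria–bacterivore edge "trophic" is an interpretation supplied by
  the feeding-mode map, not by the network.
- Per-season networks rest on 9 samples; with the t-approximation the
  effective $|\rho|$ cutoff at $p < 0.05$ is then ≈ 0.67, i.e. stricter
  than the global 0.6 — a property of the classical criterion itself.
- The cohesion components carry the estimator baseline discussed above;
  compare them across conditions, not against zero, unless the
  connectedness-level correction is selected.
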