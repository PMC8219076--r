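---
title: "Methods: diversity and co-occurrence network analysis of OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and co-occurrence network analysis of OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miconet)
```

## The analytical model

`miconet` implements the downstream half of a 16S amplicon survey of an
aquaculture system: from an OTU count table, taxonomy and sample metadata to
diversity estimates, community comparisons and interaction networks. The
canonical design it serves has three habitats (water, sediment, animal
intestine) crossed with two breeding modes (pond monoculture MC, rice
co-culture RC) and three replicate fields, i.e. 18 samples, with per-sample
library sizes in the tens of thousands of reads.

The statistical backbone is deliberately conventional — these are the
methods a reviewer in this field expects — but every stochastic step is
seeded and every computational claim is backed by an oracle test (closed
form, exhaustive enumeration, or recovery of planted structure).

## The synthetic community generator

Real surveys give no ground truth, so the package carries a generator whose
output has the statistical structure the analysis assumes, with the truth
retained.

For a sample in habitat $h$, a latent Gaussian vector $z \in \mathbb{R}^T$
is drawn with block correlation: taxa in planted module $m$ share an
equicorrelation $\rho_w$ (default 0.9), implemented as
$z_i = \sqrt{\rho_w}\, g_m + \sqrt{1-\rho_w}\, \varepsilon_i$, which is
positive definite for any $\rho_w \in [0,1)$. Log-abundances are
$\mu_i(h) + \sigma z_i$, where $\mu_i(h)$ adds the habitat effect (default
3 natural-log units) to the signature taxa of $h$; exponentiation and
closure give relative abundances, and counts are a multinomial draw at a
depth sampled uniformly on 33,000–45,000 reads. Because $\exp$ is monotone,
the latent rank correlation survives into the abundances — Spearman-based
network recovery is therefore well-posed by construction, which is exactly
the property the co-correlation module needs to be testable.

Defaults: 3 habitats × 40 signature taxa + 120 shared taxa = 240 taxa; one
planted module per habitat (the habitat's signature set); mode effect 0.
The zero mode effect reflects the design this package mirrors, where the
breeding modes showed no significant community difference; it also gives the
permutation tests a true null to be calibrated against. When a nonzero mode
effect is requested it is applied to the first half of the shared taxa in
the second mode, so the effect is identifiable but does not interact with
the habitat signatures. An optional per-habitat $\sigma$ lets one impose an
evenness (hence Shannon) gradient across habitats.

What the generator does **not** emulate: sequencing error, chimeras,
OTU-clustering artifacts, taxon-specific PCR bias, overdispersion beyond the
log-normal, or realistic taxonomies (the SILVA-style strings are
placeholders at the two ranks the analysis uses). Passing recovery tests on
this generator therefore demonstrates the correctness of the analysis chain
under its own assumptions, not robustness to the full messiness of real
amplicon data.

## Parameter conventions, with reasons

* **Rarefaction** is a single draw without replacement (multivariate
  hypergeometric) to the smallest library — the dominant convention behind
  "normalised to the least sequence number". A numeric depth above any
  library size is an error naming the sample.
* **Shannon** uses the natural log (a `base` argument covers log2
  conventions). **Simpson** is reported as the unbiased dominance
  $D=\sum n_i(n_i-1)/(N(N-1))$ — *lower means more diverse*. This matches
  community software that reports sediment (rich, even) as the lowest value;
  it is documented prominently because both conventions circulate.
* **Chao1** uses the bias-corrected $+1$ denominator, defined even with no
  doubletons. **ACE** uses the standard rare/abundant cutoff of 10; when
  every rare read is a singleton the coverage term vanishes and the function
  falls back to Chao1, flagging the value rather than returning NaN.
* **ANOSIM** uses Clarke's statistic with midranks,
  $R=(\bar r_B-\bar r_W)/(n(n-1)/4)$, which attains $R=1$ under complete
  separation. The permutation p-value is the $+1$-smoothed estimator
  $(1+\#\{R^\pi \ge R\})/(n_\pi+1)$, floored at 0.001 for 999 permutations.
  `permutations = "exact"` enumerates all distinct label assignments instead
  (used when designs are small enough that the random estimator is mostly
  noise). **Adonis** is the one-factor PERMANOVA; no multi-factor formula
  interface is provided because the target design tests one factor at a
  time.
* **Stratified permutations.** Testing the mode contrast across all 18
  samples permutes mode labels *within habitats* (`strata`). Unrestricted
  permutation is badly conservative here: a random relabelling can align
  mode with the dominant habitat axis, inflating the permutation
  distribution, and the observed balanced design then almost never looks
  extreme. With strata the test is exact under within-habitat
  exchangeability and empirically calibrated (type-I rate ≈ 4–5% at
  $\alpha=0.05$ over 200 simulated null datasets). The within-habitat 3-vs-3
  contrasts have only 20 distinct assignments, so their p-values cannot fall
  below ≈ 0.05 at all — a resolution limit of the design, not a bug.
* **PCoA** reports all eigenvalues; axes with positive eigenvalues carry
  coordinates and the variance shares are taken over positive eigenvalues
  only, with no Lingoes/Cailliez correction (none is applied in the target
  workflow). Axis signs are fixed by making each axis's largest-magnitude
  loading positive, so ordinations are reproducible across platforms.
* **UPGMA** records merge heights as *half* the between-cluster average
  distance (the ultrametric convention, leaf-to-root = half the final
  average distance); ties are broken by the lexicographically smallest pair
  of cluster labels, making the tree deterministic on degenerate inputs.
* **"Others" binning** keys on the dataset-wide *mean* relative abundance
  (< 1% by default), not a per-sample rule, so one consistent taxon legend
  describes all samples. Whether the rule should be per-sample is genuinely
  ambiguous in the field; the threshold and rule are arguments.
* **Bipartite network**: genera need ≥ 5 total reads; an edge means ≥ 1
  read in ≥ 1 sample of a group. MC/RC groups collapse to habitats for the
  seven-way sharing classification (1 intestine-only, 2 intestine+water,
  3 all three, 4 intestine+sediment, 5 water+sediment, 6 water-only,
  7 sediment-only — the assignment of 6/7 is a fixed convention). Membership
  is presence-based; an abundance-weighted "most strongly associated" rule
  would be an alternative reading and is intentionally not the default.
* **Co-correlation network**: midrank Spearman (exact under ties) with the
  t-approximation $t=\rho\sqrt{(n-2)/(1-\rho^2)}$ for two-sided p-values
  ($p=0$ at $\rho=\pm1$; constant taxa are excluded, not guessed). Edges
  require $\rho \ge 0.75$ (inclusive) *and* $p<0.05$ on the raw p-value —
  no multiple-testing correction by default, because the thresholded-ρ
  convention this reproduces uses raw significance; a Benjamini–Hochberg
  flag exists. "ρ ≥ 0.75" is read as positive-only (co-occurrence);
  `mode = "absolute"` admits exclusion edges. Nodes enter the correlation
  step through a pre-filter (top 100 taxa by total abundance, present in
  ≥ 4 samples) — real surveys of ~1,200 genera need one to obtain a
  ~100-node network, though the exact published pre-filter is never stated,
  which is the main caveat for quantitative reproduction of any particular
  published network.
* **Topology**: local clustering is 0 for degree < 2 and the average is
  taken over all nodes; transitivity is 3·triangles/connected-triples;
  betweenness is Brandes, unnormalised (the scale on which published hub
  values in the hundreds live), endpoints excluded; diameter and mean path
  length are computed on the largest connected component, since finite
  values require ignoring disconnected pairs.
* **Louvain** is seeded; Q reported is the standard Newman–Girvan modularity
  of the returned partition at resolution 1.

## Seeds and determinism

One master seed drives the pipeline; each stage derives its own sub-seed
from the stage name (`stage_seed()`), so adding a stage never perturbs the
streams of the others. Every seeded function saves and restores the session
RNG state. Two runs with the same configuration are byte-identical,
including the Newick and GraphML exports.

## Numerical choices and degenerate inputs

Ties in ranks use midranks throughout (distances in ANOSIM, abundances in
Spearman, Kruskal–Wallis with tie correction). Zero-variance groups in t/
ANOVA follow an explicit contract (p = 1 for equal means, p = 0 otherwise)
instead of erroring mid-pipeline. An all-zero sample is an error naming the
sample everywhere it would silently poison a result (relative abundance,
Bray–Curtis). PERMANOVA with zero within-group variance reports R² = 1 and
an infinite pseudo-F sentinel. Percentages are printed to two decimals with
round-half-even.

## Problem sizes used in validation

The test suite validates estimators against brute-force formula evaluation
on 1,000 random profiles; graph metrics against hand-rolled BFS/enumeration
oracles on every connected graph with up to six vertices (via the graph
atlas) plus 100 random 20-node graphs; ANOSIM/Adonis against exhaustive
enumeration on 5- and 6-sample designs; null calibration on 200 simulated
datasets and signal detection on 100 (999 permutations each); and module
recovery over 20 generator seeds at 30 samples. These sizes give stable
Monte-Carlo margins while keeping a full run in the low minutes on one CPU.

## Known limitations

* Compositionality: Spearman on relative abundances is not a
  compositionality-aware association measure (SparCC/SPIEC-EASI are out of
  scope); the closure can induce spurious negative correlation, which the
  positive-only edge filter largely sidesteps but does not remove.
* No phylogeny: UniFrac distances, phylogenetic diversity and rarefaction
  curves are out of scope.
* The UPGMA three-branch habitat structure is recovered exactly in most but
  not all generator seeds at the default effect size; an occasional sample
  crosses branches, which is the expected behaviour of average linkage near
  the noise floor rather than an implementation artefact.
* The generator's defaults are chosen for testability of the analysis
  chain; no claim is made that effect sizes match any particular ecosystem.
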