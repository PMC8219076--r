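# miconet

Downstream analysis of 16S rRNA OTU count tables for multi-habitat
aquaculture surveys, and the validation machinery to trust it. The package
targets the common design in which microbial communities are sampled from an
animal's intestine and from its surrounding water and sediment, under two or
more management regimes (e.g. pond monoculture, MC, versus rice co-culture,
RC), with the question: *do habitats host distinct communities, does the
management regime matter, and which taxa bridge the habitats?*

It is aimed at microbial ecologists who already have an OTU (or ASV) table,
a taxonomy table and per-sample metadata, and want the standard analysis
chain as reproducible, seeded, tested functions rather than a point-and-click
pipeline.

## What it computes

Given a taxa × samples count table, the pipeline runs:

1. **Rarefaction** to the least sequence number (subsampling without
   replacement, hypergeometric).
2. **Alpha diversity** per sample: Good's coverage `1 − F₁/N`, bias-corrected
   Chao1 `S + F₁(F₁−1)/(2(F₂+1))`, ACE (rare/abundant cutoff 10), Shannon
   `H' = −Σ pᵢ ln pᵢ`, and Simpson dominance `D = Σ nᵢ(nᵢ−1)/(N(N−1))`
   (lower = more diverse); plus t / ANOVA / Kruskal–Wallis group tests with
   the usual star scheme.
3. **Beta diversity**: Bray–Curtis distances, principal coordinates analysis
   (Gower double-centring, negative eigenvalues reported but excluded from
   variance shares), a UPGMA dendrogram (Newick export), and seeded
   permutation tests — ANOSIM `R = (r̄_B − r̄_W)/(n(n−1)/4)` and one-factor
   PERMANOVA with pseudo-F and R², both with the +1-smoothed p-value over
   999 label permutations (optionally exact enumeration, optionally
   stratified).
4. **Composition summaries**: rank aggregation, `<1%`-mean "others" binning,
   per-taxon habitat read shares, top-N selection and a log10 heatmap matrix.
5. **Bipartite genus–environment network**: genera with ≥ 5 total reads
   linked to the sample groups they occur in, collapsed to habitats and
   classified into the seven environment-sharing clusters, with summary
   percentages.
6. **Spearman co-correlation network**: midrank Spearman ρ between genera
   (t-approximation p-values), edges kept at ρ ≥ 0.75 and p < 0.05, node
   metrics (degree, local clustering, Brandes betweenness), global topology
   (transitivity, diameter, mean path length), seeded Louvain modules with
   modularity Q, habitat labels per node, and betweenness-ranked hubs.

A **synthetic community generator** (`generate_community()`) produces data
with the statistical structure this analysis assumes — habitat-signature
taxa, shared taxa, planted latent correlation modules (a log-normal Gaussian
copula), uneven depths, and a null management-mode effect — while retaining
the ground truth, so every stage can be validated by recovery instead of by
eye.

## Worked example

```r
library(miconet)

sim <- generate_community(synth_config(seed = 42))
dim(sim$counts)            # 240 taxa x 18 samples
range(colSums(sim$counts)) # 33355 43800 reads

report <- run_pipeline(run_config(seed = 42, outdir = "run42"))
report$permutation_tests
#>                            group anosim_R anosim_p permutations adonis_F adonis_R2 adonis_p
#> 1 water vs sediment vs intestine    1.000    0.001          999   47.841     0.864    0.001
#> 2           MC-water vs RC-water    0.037    0.490          999    1.152     0.224    0.277
#> 3     MC-sediment vs RC-sediment   -0.148    0.790          999    0.626     0.135    0.498
#> 4   MC-intestine vs RC-intestine    0.037    0.290          999    1.152     0.224    0.290
```

The three habitats are perfectly separated (ANOSIM R = 1 at the permutation
floor p = 0.001) while the two breeding modes are indistinguishable — the
generator's null mode effect is correctly not "detected". The co-correlation
network recovers the three planted modules:

```r
g <- report$network_globals
sprintf("nodes %d  edges %d  Q %.3f  modules %d",
        g$n_nodes, g$n_edges, g$modularity,
        length(unique(report$network$partition)))
#> "nodes 100  edges 1623  Q 0.661  modules 3"

head(report$alpha[, c("sample_id", "observed", "coverage", "chao1", "shannon", "simpson")], 3)
#>   sample_id observed coverage chao1 shannon simpson
#> 1      MCw1      240   1.0000 240.0   4.462 0.01663
#> 2      MCw2      240   0.9999 240.2   4.242 0.02042
#> 3      MCw3      235   0.9998 235.8   3.989 0.02328
```

All stage outputs (rarefied table, alpha/beta tables, Newick tree,
permutation-test table, bipartite cluster summaries, network edge/node/global
TSVs and GraphML) are written under `outdir`; rerunning with the same master
seed reproduces them byte for byte.

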