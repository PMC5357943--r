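# switchnet

Switch-gene detection in gene co-expression networks.

`switchnet` is for computational biologists who have a genes × samples
expression matrix from two conditions (e.g. tumor and matched normal) and
want to find **switch genes**: genes that bridge expression modules while
being *anti-correlated* with their interaction partners — candidate
negative regulators of the processes they connect, with demonstrated
prognostic value in cancer transcriptomes.

## The method in brief

1. **Network.** Keep differentially expressed genes
   (|log2FC| ≥ 1 by default) and join two genes with an edge when the
   absolute Pearson correlation of their expression profiles passes a
   cutoff; the signed *r* stays on the edge.
2. **Communities.** Partition genes by k-means under the correlation
   distance *d* = 1 − *r*, so anti-correlated genes land in different
   communities.
3. **Cartography.** For each node compute the participation coefficient
   *P* = 1 − Σₛ(kₛ/k)², the clusterphobic coefficient
   *K*<sub>π</sub> = 1 − (k<sub>in</sub>/k)², the within-module degrees *z*
   (internal-degree statistics) and *z*<sub>g</sub> (total-degree
   statistics), and the APCC — the mean signed correlation of a node with
   its network neighbours. The (*K*<sub>π</sub>, *z*<sub>g</sub>) plane
   splits into regions R1–R7 (*heat cartography*); hubs (degree ≥ 5)
   classify as **party** (high APCC), **date** (low positive APCC) or
   **fight-club** (negative APCC).
4. **Switch genes** are the nodes in region R4 (*K*<sub>π</sub> > 0.8,
   *z*<sub>g</sub> < 2.5) with APCC < 0. The package quantifies their
   criticality by targeted-removal curves of the average shortest path,
   ranks them by Kaplan–Meier/log-rank separation of expression-defined
   patient cohorts, and compares switch sets across datasets by
   Hamming-distance clustering, with Fisher/BH over-representation
   analysis against user-supplied gene sets.

Synthetic generators with planted modules, switch nodes, paired
tumor/normal shifts and expression-driven survival make the whole pipeline
testable without any external download.

## Worked example

```r
library(switchnet)

sim  <- generate_modular_expression(n_modules = 4, genes_per_module = 50,
                                    n_samples = 100, n_switch = 10, seed = 7)
corr  <- pearson_matrix(sim$em)
net   <- build_graph(corr, cutoff = 0.6)
comm  <- cluster_expression(sim$em, k = 4, seed = 7)
carto <- cartography_table(net, comm)
table(carto$hub_class)
#> fight-club      party
#>         10        200

sw <- find_switch_genes(carto, net)
sw$genes
#>  [1] "SW01" "SW02" "SW03" "SW04" "SW05" "SW06" "SW07" "SW08" "SW09" "SW10"

carto[carto$switch, c("gene", "k", "k_in", "K_pi", "z_g", "APCC", "region")][1:3, ]
#>     gene  k k_in K_pi    z_g   APCC region
#> 201 SW01 81    0    1  -5.36 -0.644     R4
#> 202 SW02 97    1    1  -5.26 -0.625     R4
#> 203 SW03 84    0    1 -11.40 -0.603     R4
```

All ten planted switch genes are recovered with no false positives: each
has essentially no links inside its own community (*K*<sub>π</sub> ≈ 1),
sits far below its community's degree distribution (*z*<sub>g</sub> ≪ 2.5)
and is anti-correlated with its neighbours (APCC ≈ −0.6). The 200 module
genes classify as party hubs.

Downstream, `compare_strategies(net, carto)` contrasts the rise of the
average shortest path under targeted switch removal with count-matched
random removal, `rank_switch_genes_by_survival()` orders switch genes by
log-rank p-value, and `build_membership_matrix()` /
`hamming_distance_matrix()` / `cluster_datasets()` compare switch sets
across datasets. `run_pipeline(pipeline_config(...))` chains every stage
and writes TSV tables, figures-ready objects and a JSON report;
`inst/cli/switchnet` wraps it for shell use.

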