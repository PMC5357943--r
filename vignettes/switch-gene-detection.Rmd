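---
title: "Detecting switch genes in co-expression networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting switch genes in co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchnet)
```

## The problem

In a gene co-expression network, nodes are transcripts and an edge joins two
genes whose expression profiles are strongly correlated *or anti-correlated*
(`|r| >= cutoff`, with the signed Pearson `r` kept on the edge). Such
networks are modular: groups of co-regulated genes form communities. Most
hub-classification schemes describe hubs either by topology alone (the
classical cartography of participation coefficient and within-module degree)
or by co-expression alone (date vs party hubs, split on the average Pearson
correlation of a hub with its neighbours, APCC). This package implements a
scheme that combines the two and isolates a third hub class with no analogue
in protein-interaction networks: **fight-club hubs**, hubs whose APCC is
negative, and among them **switch genes** — genes that sit almost entirely
outside their own community, are not local hubs, and are anti-correlated
with their interaction partners. In a two-condition (e.g. tumor vs normal)
dataset these are candidate negative regulators of the processes they
connect to.

## Statistics

For node $i$ with total degree $k_i$, internal degree $k_{in,i}$ (links into
its own community $C_i$), and $k_{s,i}$ links into community $s$:

* participation coefficient
  $P_i = 1 - \sum_s \left( k_{s,i} / k_i \right)^2$. Its supremum over
  allocations into $N$ modules is $1 - 1/N$, so with few modules the
  high-$P$ region of the classical cartography is empty by construction
  ($P > 0.8$ is unreachable for $N < 6$, a fact the acceptance checks verify
  by exhaustive enumeration).
* clusterphobic coefficient
  $K_{\pi,i} = 1 - \left( k_{in,i}/k_i \right)^2$, the outward orientation
  of a node. Its bound (1) does not depend on the partition size, which is
  exactly why it can replace $P$ on the cartography's x-axis. Expanding the
  two definitions gives
  $P_i = K_{\pi,i} - \sum_{s \neq C_i} (k_{s,i}/k_i)^2$, hence
  $P \le K_\pi$ always, with both zero when a node's links are entirely
  internal.
* within-module degree $z_i$: z-score of $k_{in,i}$ against the
  *internal*-degree distribution of $C_i$; global within-module degree
  $z_{g,i}$: $k_{in,i}$ centred and scaled by the *total*-degree
  distribution of $C_i$. The sample standard deviation (denominator
  $n - 1$) is used in both; the convention matters only in small modules
  and is fixed here once.
* APCC: the arithmetic mean of the signed correlations on a node's retained
  edges. Neighbours are defined by the network, so only edges with
  $|r| \ge$ cutoff contribute.

The $(K_\pi, z_g)$ plane is split into seven regions; below the
$z_g = 2.5$ line the $K_\pi$ breaks are $0.05, 0.625, 0.8$ (regions R1–R4),
above it $0.3, 0.75$ (R5–R7). Only the R4 bound (0.8) is fixed by the
method's own account; the remaining breaks adopt the classical cartography
values, and all are configurable through `region_boundaries()`. Interval
edges are closed on the left region (`K_pi = 0.8` is still R3).

A **hub** is a node with degree at least 5 (`hub_min_degree`, configurable).
Hubs split by APCC: negative → fight-club; `[0, party_threshold)` → date;
above → party. The date/party cut (default 0.5) is a declared convention:
the two positive APCC modes are described qualitatively ("low" vs "high"),
not by a printed number, so reports should flag this threshold. A **switch
gene** is any node in region R4 with APCC < 0; on hubs this coincides with
"fight-club hub in R4".

## Community detection

Communities are found on the expression profiles, not on the thresholded
graph, using the correlation distance $d = 1 - r$ ($d \to 0$ for correlated,
$d \to 2$ for anti-correlated genes). This keeps anti-correlated genes in
*different* communities — essential, since a switch gene's defining feature
is that its (negative) edges leave its own community. The partition is a
k-means-style minimization of the total correlation distance to cluster
centroids (mean member profile, re-standardized), best of `restarts = 10`
random initializations, with ties in assignment broken toward the lowest
community index and emptied clusters re-seeded from the farthest points.
A seed is mandatory; given it, the run is deterministic. `choose_k()`
applies an elbow rule: the smallest k beyond which the relative quality
gain drops below `tol = 0.05` (falling back to the range maximum, with a
warning, when no elbow exists).

## Robustness

Network vulnerability is probed by deleting nodes and tracking the average
shortest path, computed over *connected pairs only*; disconnected pairs are
excluded from the mean rather than imputed, a convention recorded in the
output metadata (alternatives — largest-component-only or harmonic means —
change curve levels, not orderings). Targeted strategies remove category
members in descending degree order (ties by gene id, for determinism);
`compare_strategies()` pairs every targeted curve with a count-matched
random baseline — the same number of uniformly drawn nodes, averaged over
`n_random_reps = 20` replicates — which is the standard control in attack
tolerance analyses and keeps the comparison honest when categories are
small.

## Survival prioritization

For each switch gene, patients split on the quartiles of tumor-sample
expression: low cohort strictly below the 25th percentile, high strictly
above the 75th; ties with the quantiles are excluded. Cohorts are compared
with the Kaplan–Meier estimator and the unweighted log-rank test (standard
`survival` package machinery behind the package's interface), and genes are
ranked by increasing raw p-value; a Benjamini–Hochberg column is emitted
for reference but does not drive the ordering. Follow-up truncation (e.g.
at ten years) is available via `max_followup_days` and off by default.

## The synthetic generator

`generate_modular_expression()` emulates the structure the method assumes:
per-sample latent factors (one per module), member genes loading
$\sqrt{\text{intra\_corr}}$ on their module factor, and planted switch
genes loading $-\text{switch\_strength}$ on the unit-variance average of
`n_foreign = 2` foreign-module factors. Two design choices deserve note:

* **In-sample orthonormal factors.** The latent factors are centred and
  orthonormalized within the sample (QR against the intercept), so planted
  correlations are *exact*, not merely asymptotic: at zero noise a switch
  gene's correlation with members of its target modules is exactly
  $-1/\sqrt{n_\text{foreign}}$ and intra-module pairs sit at exactly 1.
  This is what makes closed-form oracle tests possible.
* **Unit-variance foreign aggregate.** The switch signal is
  $\sum f_t / \sqrt{n_\text{foreign}}$ rather than a plain mean; a plain
  mean would shrink the signal variance by $1/n_\text{foreign}$ and leave
  the planted switch-to-member correlation (≈0.59 at the default noise
  level) *below* the default network cutoff, making recovery a matter of
  sampling luck rather than design. With the unit-variance aggregate the
  planted correlation is ≈0.63 at the defaults and recovery is stable.

The default study conditions — 4 modules × 50 genes, 100 samples,
`intra_corr = 0.8`, 10 switches at `switch_strength = 0.8`,
`noise_sd = 0.3`, network cutoff 0.6, k = 4 — are the conditions under
which the test suite requires ≥ 9/10 planted switches recovered with ≤ 2
false positives, and under which switch-gene removal must raise the average
shortest path more than count-matched random removal at every fraction from
0.05 to 0.25. A baseline offset (default 10) keeps values non-negative, as
the input contract requires; Pearson correlation is affine-invariant, so it
changes nothing else. The generator does *not* emulate RNA-seq count noise
(negative binomial dispersion), batch effects, or correlated censoring —
passing tests demonstrate correctness of the machinery on the assumed
factor structure, not performance on raw sequencing data.

`generate_paired_tumor_normal()` scales selected genes by $2^{\text{log2fc}}$
in the tumor copies (multiplicative, so non-negativity is preserved);
`generate_survival()` draws exponential event times with rate
$\lambda_0 e^{\beta z}$ from standardized driver expression with
independent exponential censoring. At $\beta = 0$ the log-rank p is
uniform, which the suite checks as a type-I error rate of 0.05 ± 0.04 over
200 replicates.

## Differential selection

The two-condition step uses the mean-ratio criterion
$\log_2\!\big((\bar{x}_T + \varepsilon)/(\bar{x}_N + \varepsilon)\big)$
with pseudocount $\varepsilon = 0.05$ and default threshold
$|\text{log2FC}| \ge 1$, computed on unpaired condition means (robust to
unequal sample counts; pairing is kept for validation only). This is a
deliberately simple, explicit stand-in for a full count-model DE analysis,
which is out of scope; it is antisymmetric under condition swap and
configurable.

## Numerical and degenerate-input conventions

* Edge retention is inclusive (`|r| >= cutoff`); correlations are clipped
  to $[-1, 1]$ against floating-point drift.
* Zero-variance genes are a hard error at correlation time (filter first);
  missing values are rejected at read time, never imputed.
* Modules with zero degree spread (or singletons) give $z = z_g = 0$ with
  a warning instead of NaN propagation.
* Isolated nodes stay in the graph, flagged, but are dropped from the
  cartography table (degree 0 leaves $P$, $K_\pi$, APCC undefined) and
  reported via an attribute.
* The one-sided Fisher test is the hypergeometric upper tail
  $P(X \ge a)$, computed directly; BH adjustment and the `q <= 0.05` call
  follow.
* Hamming comparison of switch sets across datasets uses the union of
  observed genes as the row universe and normalizes by its size by default,
  so differently sized universes are comparable; dendrograms use average
  linkage (the linkage is not dictated by the method and is configurable).

## Problem sizes used by the test suite

Tests run the full planted-network conditions above (210 genes, 100
samples), 100 random graphs of 10–30 nodes for brute-force oracle
equivalence, a 10,000-permutation log-rank oracle on 40 patients, 200
survival replicates for calibration, and exhaustive hypergeometric
enumeration over all tables with universe size up to 50. These sizes were
chosen so every property is exercised at full strength while a complete
run stays comfortably interactive.

## Known limitations

* The k-means-style community search finds local optima; `restarts`
  mitigates but does not eliminate this, and the elbow rule for k is a
  heuristic (flat-quality data returns the range maximum with a warning).
* The date/party APCC threshold and the non-R4 region breaks are
  conventions, not fitted quantities; a mixture-model fit of the APCC
  distribution would be a natural plug-in.
* The average-shortest-path curves depend on the disconnected-pair
  convention in level (orderings are stable in our tests).
* Modularity-based community detection (Louvain/Leiden), partial-correlation
  networks and Cox-model prioritization are intentionally out of scope.
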