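---
title: "From drug response to a regulatory axis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From drug response to a regulatory axis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regaxis)
```

`regaxis` chains five analysis stages that are usually run as separate web
tools into one tested pipeline: response classification, differential
expression, network hub discovery, directed regulatory-network analysis, and
gene-set enrichment. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology left choices
open.

## 1. Response classification

The response substrate is a cell-line × drug matrix of LN_IC50 values
(log-normalized half-maximal inhibitory concentrations). Classification uses
the sign rule: LN_IC50 > 0 is drug-resistant, < 0 drug-sensitive. The rule is
stated with strict inequalities, so a value of exactly 0 — or a missing
entry — is left *unclassified* rather than assigned a side arbitrarily.

Differential analysis needs clearly separated groups, so `select_extremes()`
keeps only extreme responders, by default LN_IC50 < −1 (sensitive) or > +1
(resistant). A drug whose selected set contains only one class (or none)
permits no resistant-vs-sensitive contrast; such drugs are flagged
(`single-class` / `empty`) and excluded from the expression stage with a
logged reason. In pharmacogenomic screens this is common — a compound can be
uniformly effective or uniformly ineffective across a mutant background — and
dropping those drugs is the statistically honest choice, not a data loss.

Response matrices are clustered for heatmaps with **uncentered correlation**
(cosine similarity without mean-centering; for response profiles the raw
sign and magnitude carry meaning, so centering would discard information) and
**average linkage** (UPGMA) on the dissimilarity d = 1 − similarity. Missing
entries are handled pairwise: each similarity uses the complete pairs of the
two profiles. Agglomerative ties and left/right child order are not defined
by UPGMA itself; to make output deterministic, at every merge the subtree
containing the smallest original index goes left. The linkage is computed by
`stats::hclust(method = "average")`; the distance matrix and the leaf-order
rule are this package's.

## 2. Differential expression with double filtration

Expression input is a gene × sample matrix of log2 (RMA-style) values. Per
gene, `run_dge()` applies Welch's unequal-variance t-test between the
resistant and sensitive samples. The implementation is a vectorized row-wise
evaluation of the Welch formulas (means, variances, the Welch–Satterthwaite
degrees of freedom, and a two-sided p from the t distribution); the test
suite pins it against `stats::t.test(var.equal = FALSE)` to 1e-10.

A gene passes the **double filtration** iff p < `p_cut` (default 0.05) *and*
|log2FC| > `fc_cut` (default 2). Two reading choices are worth making
explicit:

- The fold-change filter is two-sided, |log2FC| > 2, because both up- and
  down-regulated genes are of interest (volcano plots show both tails).
- Because the data are already log2 scale, log2FC is the *difference of log2
  means* (resistant − sensitive), not a ratio of raw means. log2FC > 0 means
  higher expression in resistant samples.

Raw p-values are used for the pass flag by default, matching the common
MeV-style usage of this filter; `fdr = TRUE` adds a Benjamini–Hochberg column
for users who want the more rigorous criterion. Degenerate genes are handled
without NaN propagation: zero variance in both groups with equal means gives
t = 0, p = 1, log2FC = 0; zero variance with *unequal* means leaves the Welch
statistic undefined, so such genes carry p = NA and never pass (the
single-observation-per-value situation that produces this cannot arise under
continuous noise).

`cross_drug_intersection()` then counts, per gene, the number of drugs whose
DEG table marks it as passing, keeping genes recurrent in at least
`min_drugs` (default 3) drugs — recurrence across independent compounds is
the pipeline's main guard against drug-specific noise.

## 3. Co-expression and PPI networks

Published versions of this analysis derive co-expression edges from a
gene-interaction service and PPI edges from a curated database. Both are file
or matrix inputs here:

- `build_coexpression_network()` connects gene pairs whose absolute pairwise
  similarity across samples reaches `tau` (default 0.8), using uncentered
  correlation (or Pearson). This keeps the stage self-contained and
  reproducible; it does not attempt to reproduce any service's proprietary
  edge weighting.
- `import_edge_list()` reads SIF or TSV edge lists and keeps edges with
  confidence **strictly greater than 0.400** (the "medium confidence"
  convention, read literally as a strict inequality). Unscored edges are kept
  only when the filter is disabled (`min_confidence = NULL`), and duplicate
  undirected edges collapse keeping the maximum confidence — conservative
  retention.

Hubs are high-degree nodes. Published hub tables report per-network degree
cutoffs (30, 100, 30, 50, 10 across five drugs) without a generating rule, so
both selection rules are exposed: an absolute `min_degree` threshold, and a
`top_fraction` rule (default 0.2) that keeps the top 20% of nodes by degree,
including all ties at the cutoff. The lowest selected degree is always
recorded so results can be reported in the same form as those tables.

Communities come from greedy modularity maximization
(`igraph::cluster_fast_greedy`), the same objective family as the GLay
community clustering used in the original tool chain; this substitution is
deliberate and documented. The dendrogram is cut at the first modularity
maximum explicitly, which makes the partition deterministic (including for
degenerate cases such as a complete graph, which is one community). Per
cluster, PPI hubs are intersected with the co-expression hubs
(`intersect_hubs()`; empty intersections are reported as NA), and
`common_across_drugs()` counts per gene the drugs whose (cluster-unioned)
common-hub set contains it. The per-drug union over clusters is implied
rather than stated in the published tables; it is applied here and noted.

## 4. The directed regulatory network

The regulatory layer is a directed graph over three node classes — lncRNAs,
transcription factors, and coding (driver) genes — built from typed edge
tables by `regulatory_network()` / `merge_networks()` (parallel edges
collapse, provenance tags accumulate, class conflicts are errors).

Master-regulator ranking uses **out-degree** as the primary criterion —
sources are ranked by how many targets they regulate — with **betweenness
centrality** breaking ties, then node id for full determinism. Betweenness is
computed on unweighted directed shortest paths (the curated networks carry no
edge weights) with Brandes' algorithm and normalized by (n−1)(n−2), so values
lie in [0, 1] as in Cytoscape-style network analyzers. The test suite checks
it against brute-force enumeration of all shortest paths on hundreds of
random digraphs and against `igraph::betweenness`.

The axis around the nominated regulator is assembled by `build_axis_report()`:

- **Indirect regulation**: `two_hop_indirect_targets()` lists every
  (coding target, mediating TF) pair certified by an explicit 2-edge path
  regulator → TF → gene.
- **Feedback**: `find_mutual_edges()` reports reciprocal edge pairs (u → v
  and v → u). Longer cycles are not mutual interactions and are not reported.
- **Cis/trans**: a target on the regulator's chromosome is *cis*, otherwise
  *trans*. The call needs only chromosome co-location, mirroring how such
  calls are made from gene-location databases; distance thresholds within a
  chromosome would require a genomic-coordinate model that the inputs do not
  carry.
- **Interaction regions**: a predicted lncRNA binding site (an interval in
  1-based inclusive mRNA coordinates) is assigned to the 5′UTR, CDS or 3′UTR
  containing its midpoint, floor((start + end)/2). Published site tables
  assign one region per site without stating a rule for boundary-spanning
  sites; the midpoint rule decides those deterministically, and the overlap
  fraction of the site with each region is reported alongside so no
  information is lost.

One reconstruction is baked into the worked example
(`example_regulatory_edges()`): the published out-degree of 8 for MALAT1 is
recovered as its two stated coding targets plus six TF targets, of which only
EGR1 is named; the other five are placeholder nodes, and EGR1's out-degree of
4 includes its edge back to MALAT1 (the feedback loop). Placeholder TFs carry
no coding targets, so indirect regulation flows through EGR1 only, as stated.

## 5. Enrichment

`enrich()` performs over-representation analysis: per term, the upper-tail
hypergeometric probability P[X ≥ k] of seeing k query genes in a term of
size K given a query of size n from a universe of size N (equivalently the
one-sided Fisher exact p), with Benjamini–Hochberg correction across the
tested terms. Only over-representation is tested. The background universe
defaults to the union of all term genes because the original tool's
background is undocumented; a user-supplied universe overrides it. Query
genes outside the universe are dropped with a count, never silently retained,
which would inflate significance.

## 6. What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the pipeline was designed
around: 41 cell lines × 10 drugs; a bimodal LN_IC50 response with means ±2
and sd 0.5 (z ≈ 4 separation at the sign boundary); 1000 genes of which 50
are differentially expressed at effect 3 (log2) under Gaussian noise of sd
0.5 on a baseline of 7; and a 48 lncRNA / 38 TF / 5 coding-gene regulatory
network with one planted regulator of out-degree 8 against a background cap
of 3, plus one planted feedback loop. The original data sources publish no
distributional parameters, so the noise levels are fixtures chosen to be
realistic for RMA-scale microarray data (per-gene sd around 0.2–0.7 is
typical), not estimates; they were chosen once and are not tuned.

Planted structure is always emitted alongside the data (true labels, planted
gene list, planted regulator), so recovery is measurable. The generator is
Gaussian and independent across genes: it does *not* emulate gene–gene
correlation beyond planted blocks, heavy-tailed expression noise,
batch/tissue effects, or the sparsity pattern of real IC50 matrices. Passing
the recovery tests therefore demonstrates that the chain is implemented
correctly and calibrated under its stated assumptions — not that it would
achieve the same power on real screens.

Reproducibility: one integer seed drives everything. The generator functions
derive their substreams as `rng_seed + 0/1/2` (response, expression,
regulatory network) and the file-level `simulate_bundle()` uses `+3/+4` for
annotations and transcripts, so partial reruns are stable and identical
config + seed yields byte-identical files.

## 7. Numerical choices and limitations

- LN_IC50 exactly 0 is unclassified (strict inequalities); missing response
  entries are excluded pairwise from classification and clustering.
- Welch test edge cases are conventions, stated above, and tested.
- `top_fraction` hub selection uses `ceiling(f · n)` and includes ties at the
  cutoff, so it never silently under-selects.
- Betweenness on graphs with fewer than 3 nodes is 0 by definition.
- Test-suite problem sizes (10,000-gene null calibration, 50 regulatory
  networks, 40-node community graphs, 200 brute-force betweenness digraphs of
  ≤ 6 nodes) were chosen to give tight Monte-Carlo bounds while keeping the
  default suite fast on one CPU.
- Out of scope by design: dose–response curve fitting, array preprocessing
  (RMA), probe collapsing, limma-style variance moderation, live database
  queries, lncRNA–mRNA binding prediction (sites are inputs), and any claim
  about the biological validity of a nominated axis. The pipeline reproduces
  the inference chain; judging its biology requires bench work.
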