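---
title: "Inferring a compound's mechanism of action from transcriptome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a compound's mechanism of action from transcriptome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

## The problem

A compound applied to a cell line rarely acts through a single target.
Its transcriptional footprint — hundreds of genes moving up or down —
is scattered across the genome, but the proteins those genes encode are
not scattered: they cluster on the physical interaction network, because
co-regulated responses run through physically interacting signalling
machinery. `moanet` exploits this. It takes a treated-versus-control
expression matrix and a protein–protein interaction network (PPIN) and
asks: *which connected piece of the interactome did this compound hit,
and which signalling pathways and carcinogenesis processes does that
piece implicate?*

The pipeline has four stages:

1. **Differential expression and binarization.** Genes are flagged 1 if
   they pass a fold-change and an FDR cutoff, 0 otherwise; up-only and
   down-only indicator variants are kept alongside the combined one.
2. **Active subnetwork extraction.** A connected subgraph of the PPIN is
   grown to cover as many indicator-1 genes as possible while admitting
   at most *K* indicator-0 "exception" nodes — non-responsive proteins
   that glue responsive ones together.
3. **Pathway enrichment and the crosstalk network.** Subnetwork genes
   are tested for over-representation against GMT pathway collections;
   surviving terms are de-redundified and linked by Jaccard gene
   overlap into a pathway–pathway network, then clustered.
4. **Oncogenic projection.** Retained terms are matched against the ten
   canonical oncogenic signalling pathways (cell cycle, Hippo, Myc,
   Notch, NRF2, PI3K/Akt, RTK–RAS–MAPK, TGF-β, p53, Wnt/β-catenin) plus
   immune signalling, assigned an up/down direction from the directional
   subnetworks, and grouped into three carcinogenesis process
   categories: cell cycle/proliferation/apoptosis, metastasis/invasion,
   and angiogenesis.

## Models and procedures

### Moderated differential expression

For gene $g$ with pooled two-group variance $s_g^2$ on $d$ residual
degrees of freedom, the test statistic uses the empirical-Bayes
posterior variance

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with the prior $(d_0, s_0^2)$ estimated by method of moments on
$\log s_g^2$ (a scaled $\chi^2$ on the log scale has digamma/trigamma
moments; $d_0$ comes from a Newton inversion of the trigamma function).
The moderated $t = \Delta / \sqrt{\tilde{s}_g^2 (1/n_1 + 1/n_2)}$ is
referred to a $t$ distribution on $d + d_0$ degrees of freedom, and FDR
is Benjamini–Hochberg over all tested genes. When the prior cannot be
estimated (e.g. fewer than two genes with positive variance) the engine
falls back to the ordinary pooled-variance $t$; setting `d0 = 0`
reproduces that limit exactly, which the tests exploit. A gene constant
in both groups with equal means is reported as $t = 0$, $p = 1$, not an
error. The implementation is cross-checked against `limma::eBayes` in
the test suite (agreement to $10^{-10}$); `limma` is deliberately not
the engine so that the statistical chain is fully inspectable here.

Counts are transformed as $\log_2(x + 1)$ (pseudocount 1 for
zero-safety); linear microarray intensities as $\log_2 \max(x, 1)$ (the
floor guards background-subtracted negatives). Whether a GEO-style
matrix is already log-scale cannot be inferred reliably, so the scale
tag is explicit user input, with an all-integer matrix defaulting to
counts. RNA-seq genes must show non-zero counts in at least two samples
of one group; probe sets collapse to the probe with the largest mean
over *all* samples, ties to the lexicographically smallest probe id.

### The K-exception subnetwork problem

Given indicator values on the PPIN, the objective is a connected
induced subgraph maximizing the number of indicator-1 nodes subject to
at most $K$ indicator-0 members (default $K = 5$). Exception nodes
matter because hubs coordinating a response are often not themselves
differentially expressed; the budget keeps them from diluting the
solution. Interactome genes without expression measurements default to
indicator 0.

Two solvers share the contract and the tie-breaking rules (larger DE
count, then fewer exceptions, then lexicographically smallest node
list):

* **Greedy.** One candidate is seeded at every indicator-1 node;
  indicator-1 neighbours are always absorbed; an exception is added
  only while budget remains and only if it unlocks at least one new
  indicator-1 node, preferring the exception whose indicator-1 closure
  is largest. The result is locally maximal: no adjacent indicator-1
  node is left out.
* **Exact.** Every feasible solution lies inside a connected component
  of the subgraph induced by the indicator-1 nodes plus some exception
  set $E$, $|E| \le K$; enumerating all such $E$ and scoring component
  DE counts is therefore provably optimal. It is guarded to graphs of
  at most 20 nodes and exists as the oracle for the greedy solver —
  over 200 seeded random instances ($n \le 15$, edge probability 0.3,
  30% indicator-1, $K \in \{0,1,2\}$) the greedy attains the optimum in
  well over 80% of instances and never exceeds it.

### Centrality ranking

Hub genes of the extracted subnetwork are ranked by degree and by
shortest-path betweenness (unweighted geodesics, endpoints excluded,
fractional credit over equally short paths, raw unnormalized scores per
unordered pair). Because no single canonical combination of the two
metrics exists, the package uses the mean of the two descending ranks
(ties share mean ranks; final ties lexicographic) and also emits both
per-metric rankings so either reading can be reproduced. Betweenness
and degree come from igraph; the test suite re-derives betweenness by
naive enumeration of all geodesics on 50 seeded graphs and checks
agreement to $10^{-9}$.

### Enrichment and filtering

Over-representation uses the upper-tail hypergeometric probability
(one-sided Fisher test)

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

with the universe defaulting to all genes annotated anywhere in the
loaded collection (alternatives: interactome genes or measured genes).
BH adjustment is per source database by default, with a pooled option.
Retained terms must satisfy FDR < 0.05, carry at least one of the
keywords *signal*, *apoptosis*, *cell cycle* (case-insensitive
substring, internal whitespace collapsed, keyword set editable) and
have at least 3 overlap genes.

### The pathway crosstalk network

For two retained pathways the Jaccard index is computed on their
**enriched** gene sets — the subnetwork∩pathway overlaps, not the full
database gene sets — so the network reflects what the compound actually
hit. Two thresholds with deliberately different boundary conventions:

* redundancy: $J > 0.60$ (strict) marks term pairs as duplicates of one
  family; connected components of the redundancy graph collapse to one
  representative (smallest FDR, then largest overlap, then
  lexicographic) with a member→representative map emitted;
* crosstalk: $J \ge 0.25$ (inclusive, "at least 25%") inserts an edge
  between representatives.

Collapse runs before edge construction (prioritizing one family member
before drawing the map); the order is switchable. Clustering is greedy
modularity agglomeration (Clauset–Newman–Moore via igraph) on the
unweighted graph, a weighted option exists, and cluster labels are
relabelled by each cluster's lexicographically smallest member so runs
are deterministic. On community-structured graphs (two cliques joined
by a bridge) the greedy partition provably matches the exhaustive
maximum-modularity partition and the tests assert this; on arbitrary
graphs greedy agglomeration carries no optimality guarantee, so there
the tests assert only the bound against the exhaustive optimum.

### Canonical mapping

Matching enriched terms to canonical oncogenic pathways was a manual,
literature-driven step in typical practice. Here it is a curated,
editable TSV dictionary of case-insensitive substring synonyms, each
row carrying its own process category list (so VEGF/PDGF rows of the
RTK family map to angiogenesis while the rest of the family maps to
proliferation/apoptosis, and TGF-β reports both proliferation/apoptosis
and metastasis/invasion). Immune signalling forms an eleventh group,
categorized under proliferation/apoptosis with a tumour-
microenvironment note. A term is *up* if significant only in the
up-subnetwork enrichment, *down* if only in the down one, *both* or
*unresolved* otherwise. The tool never invents a functional call:
multi-category matches are all reported with their supporting overlap
genes, and unmatched terms are flagged for review rather than dropped.

## The synthetic data generator

Real inputs at publication scale (a genome-wide interactome, GEO series
matrices, multi-database GMTs) are external downloads, so the package
ships a generator whose defaults define the study conditions used by
the tests and the acceptance script:

* a 300-node preferential-attachment (scale-free) interactome,
  attachment 2 — scale-free degree structure is what makes exception
  hubs realistic;
* a planted connected 15-gene module with 3 exception members, placed
  so that the 12 differentially expressed members remain connected on
  their own (the recoverable core);
* log2 expression for 5 control and 5 treatment samples, gene baselines
  uniform in [4, 10], Gaussian noise $\sigma = 0.5$, treatment shift
  $\delta = 2$ log2 units on the DE members (all up by default). With
  these values the expected $|t| \approx \delta / (\sigma\sqrt{2/5})
  \approx 6.3$, so planted genes sit comfortably past the fold-change-2
  and FDR cutoffs — the cutoffs are the constraint being exercised, not
  the noise;
* a GMT collection containing the true pathway (the module), a
  redundant decoy, a mid-band crosstalk decoy, a decoy realizing the
  inclusive $J = 0.25$ boundary exactly, random filler terms and a
  known-negative term. Requested pairwise Jaccard values are realized
  *exactly* by set surgery: a decoy of size $b$ sharing $c$ genes with
  a size-$a$ term has $J = c/(a+b-c)$, so $c = J(a+b)/(1+J)$ must be an
  integer — infeasible requests error out with feasible sizes. Decoys
  draw their shared genes from the DE core so the Jaccard realized on
  enriched sets lands in the same redundancy/crosstalk band as the
  constructed one. All term names contain "signaling" so the collection
  survives the keyword filter, and the true term's default name carries
  an NRF2 synonym so the canonical mapping stage is exercised.

Every generator is a pure function of its seed. What the generator does
**not** emulate: probe-level microarray artifacts, RNA-seq
overdispersion (count-mode fixtures are exponentiated/rounded Gaussians),
batch effects, correlated background expression, and the identifier
chaos of real platforms. Passing tests therefore demonstrate that the
algorithms implement their contracts and recover signal under clean
conditions — not that any particular biological dataset will yield a
clean mechanism map.

## Numerical and design choices

* All tie-breaks are lexicographic and all outputs are written in
  sorted deterministic order; two runs with the same config and seed
  are byte-identical, and `run_from_manifest()` replays a run from its
  recorded configuration.
* FDR cutoff presets: 5×10⁻³ (default) and 1×10⁻² for noisier data;
  relaxing the preset can only grow the indicator sets.
* The trigamma inversion runs 50 Newton steps with closed-form guards
  at both extremes; degenerate variance patterns (all-zero variances)
  trigger the documented pooled-t fallback.
* The PCA screen (top 500 variance genes, group-centroid separation on
  PC1/PC2) is advisory only — it flags, never blocks, since an
  operationalized version of visual QC should not silently discard
  data.
* The whole network is retained rather than its largest connected
  component; disconnection is handled naturally by the solvers.
* Test and acceptance problem sizes — 200 oracle instances at
  $n \le 15$, exhaustive hypergeometric enumeration at $N \le 12$,
  exhaustive modularity at $\le 8$ nodes, a 300-node end-to-end fixture
  — were chosen as the largest sizes where the independent oracles are
  exhaustive and exact.

## Known limitations

* Identifier mapping beyond uppercasing is the user's responsibility;
  probe→gene and cross-species mapping must happen upstream.
* The interactome is undirected; signalling directionality is not
  modelled.
* Single-factor two-group designs only: no batch correction, paired
  designs, or RNA-seq library-size normalization.
* The dictionary-based canonical matching is surface-syntactic. A term
  whose name hides its pathway membership ("Nuclear receptor
  meta-pathway" for NRF2) is caught only if it collapses into a
  recognizable family member via gene-overlap redundancy, or if the
  user extends the dictionary.
* Greedy modularity clustering and the greedy subnetwork solver are
  heuristics; the shipped oracles quantify, but do not remove, their
  gap to the optimum.

## A minimal run

```{r example, eval = FALSE}
fx <- simulate_fixture(seed = 1)
bundle <- tempfile(); write_fixture_bundle(fx, bundle)
cfg <- pipeline_config(
  seed = 1, scale = "log2",
  paths = list(expression = file.path(bundle, "expression.tsv"),
               samples    = file.path(bundle, "samples.tsv"),
               network    = file.path(bundle, "network.tsv"),
               gmt        = file.path(bundle, "pathways.gmt"),
               gmt_db     = "synthetic"))
res <- run_pipeline(cfg, tempfile())
res$subnetworks$summary
res$assignments
```
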