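---
title: "Module proximity: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module proximity: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, what every tunable parameter means, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The model

The package ranks drugs against a disease by the proximity of two node
sets in a tissue-specific molecular network: the **disease module** `S`
(a network community over-represented in disease-associated genes) and the
**drug module** `T` (the drug target, its functionally related
perturbation-signature genes, and the shortest paths joining them). The
score adds a topological and a functional component:

* **network component** `1 − d_c/D ∈ [0, 1]`, where
  `d_c = (1/|T|) Σ_{t∈T} min_{s∈S} d(s, t)` is the closest distance — the
  mean hop distance from each drug-module node to its nearest
  disease-module node — and `D` is the diameter of the network's largest
  connected component (LCC). Distances are unweighted hop counts: edge
  weights in the inputs are confidence scores, not lengths, so they do
  not enter the metric.
* **semantic component** `sim_BMA(T, S) ∈ [0, 1]`, the Best-Match-Average
  of Wang-method GO similarities between the modules' genes, restricted
  to the biological-process namespace.

The total lies in `[0, 2]`. Both components matter: a drug can sit close
to a disease module for purely topological reasons (hubs), and the
semantic term asks whether its module is also *about* the same biology.

Significance is empirical. For each drug, 1000 random modules are built
that preserve the observed module's topological footprint — a random
target from the same degree bin, signature genes redrawn at the same hop
distances from that target, shortest-path assembly as for the real module
— and the drug is called significant when its score strictly exceeds the
95% quantile of the random scores. An add-one empirical p-value,
`(1 + #{null ≥ observed}) / (1 + n_random)`, is reported alongside the
binary call; the call itself uses the quantile rule so the two can be
inspected independently.

### Assumptions

* The undirected simple graph is an adequate arena: regulatory edges are
  directed in the source but direction is kept only as metadata, because
  both the distance metric and walktrap operate on undirected graphs.
* Hop distance is meaningful only within one connected component; all
  module operations are therefore confined to the LCC, which also makes
  `d_c ≤ D` a guaranteed invariant rather than a hope.
* GO biological-process annotation is informative for both drug signature
  genes and disease genes; genes without BP annotation are excluded from
  similarity matrices rather than scored 0, so sparse annotation does not
  masquerade as functional dissimilarity (each exclusion is logged).

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| SNP p-value threshold | strictly < 5e-8 | — | genome-wide significance; strict inequality, so p = 5e-8 is excluded |
| gene-region extension | 110,000 up / 40,000 down | bp | captures regulatory neighborhoods of transcripts; strand-aware, clipped at position 1; unknown strand gets the conservative 110 kb on both sides |
| regulatory edge weight | ≥ 0.4 | score in [0, 2] | retains high-evidence regulatory circuits without emptying the network |
| PPI confidence | ≥ 0.73 | score in [0, 1] | the source database's own high-confidence level |
| expression filter | RPKM ≥ 1 | RPKM | standard presence call; adipose runs may merge two depots by per-gene maximum |
| ORA / module alpha | 0.05 | — | conventional; module calls use the raw per-module p (no BH) by default, BH optional |
| minimum community size | 3 | nodes | communities of 1–2 nodes cannot be meaningfully tested |
| walk length | 4 | steps | the walktrap implementation's standard setting |
| Wang decay | is_a 0.8, part_of 0.6 | — | the similarity method's published factors; configurable |
| signature similarity cut | ≥ 0.5 | similarity | "medium-to-high" similarity to the target; inclusive boundary |
| signature size | ≤ 100 up + 100 down | genes | what signature databases export per perturbation |
| n_random | 1000 | draws | resolves p down to ~0.001 at tolerable cost; configurable |
| null quantile | 0.95 | — | strictly-greater rule against the nearest-rank (⌈qn⌉-th) order statistic |
| degree-bin occupancy | 100 | nodes | standard for degree-matched nulls at genome scale; auto-reduced to ⌊n/3⌋ with a message on networks smaller than 3 bins' worth, so small studies still get degree matching |
| association cut-off | ≥ 0.2 | score in [0, 1] | targets already linked to the disease are excluded from repurposing |

All thresholds are inclusive (`≥`) unless stated otherwise; the SNP filter
is the one strict inequality. The defaults are collected in
`run_config()` and every override is recorded in the run manifest.

## Numerical and determinism choices

* **Shortest-path tie-break.** Among equal-length shortest paths the
  lexicographically smallest node sequence is taken (greedy smallest-name
  forward walk over the distance matrix), so drug modules are
  reproducible across runs and platforms.
* **Walktrap determinism.** The agglomeration is deterministic given the
  vertex order; the package therefore name-sorts vertices when building
  the LCC.
* **Quantile estimator.** Nearest-rank on the sorted null (the 950th
  order statistic for n = 1000, q = 0.95) — no interpolation, so the
  strictly-greater rule is unambiguous even with tied scores.
* **Degenerate inputs.** Zero-margin 2×2 tables report p = 1 with an
  `NaN` odds ratio and a flag; empty distance shells during null sampling
  fall back to the nearest nonempty shell (ties toward the smaller
  distance), logged per draw; a degree bin holding only the original
  target samples the original target itself.
* **Sub-seeding.** One run seed fans out arithmetically to per-component
  seeds (all kept below 2³¹), so individual fixture files can be
  regenerated independently and bundles are byte-identical across
  regenerations.

## Open design points and the choices made

* **Set-level similarity aggregation.** Module-vs-module similarity is the
  BMA over gene-level BMA values (`method = "bma_genes"`). Pooling both
  modules' term sets into one term-level BMA is also implemented
  (`method = "pooled_terms"`); the gene-level default weights each gene
  once regardless of how many terms annotate it, which is the behavior we
  consider right for modules of unevenly annotated genes.
* **Network integration rule.** "Regulatory nodes and their first
  neighbors" is read as: a PPI edge is admitted iff at least one endpoint
  lies in the regulatory node set R or among R's first PPI neighbors.
  Second neighbors can enter as endpoints of admitted edges but do not
  themselves pull in further edges. The worked example in
  `integrate_network()`'s tests pins this down.
* **Scope of the enrichment filter.** Over-representation p-values are
  computed from the data-driven (GWAS-derived) genes only, but the
  keep-if-in-a-significant-set rule is applied to the full three-source
  union, so text-mining genes can be rescued by pathway membership
  (`filter.scope = "union"`; `"gwas_only"` restricts both).
* **Per-drug reference distributions.** Each drug's significance is
  judged against its own null (matched to its own target degree and
  distance profile) rather than a pooled null across drugs.
* **Isolated regulatory nodes** are dropped during integration (a node
  must touch ≥ 1 edge); the count of dropped nodes is reported in the
  build report.
* **ORA universe.** No default universe is guessed: it is the union of
  the supplied library genes unless the caller provides one explicitly.

## What the synthetic generator emulates — and what it does not

`generate_fixture_bundle()` produces every input the toolkit reads, with
planted ground truth: a stochastic-block-model network whose blocks are
communities (per-block transcription factors carry the regulatory edges;
all edges appear as high-confidence PPI, plus sub-threshold and
unexpressed-gene noise rows that the loaders must reject); a layered GO
hierarchy with one branch per block and per-gene annotations drawn from
the gene's own branch, making blocks semantically coherent; SNPs, gene
models and gene-set libraries arranged so the disease-gene machinery
recovers a list concentrated in block 1; and a positive-control drug
(target and signature in the disease block) against a negative control in
a distant block with a different annotation branch.

Profiles set the scale: `tiny` ≈ 32 nodes (fast wiring tests), `small`
≈ 200 nodes (the scale used by the acceptance checks: 1000-pair score
sweeps, 20-seed recovery runs, and the 200 × 1000-draw null calibration),
`medium` ≈ 1000 nodes. These sizes were chosen so the full property suite
runs in minutes on one core while leaving every statistical check
adequately powered.

The generator does **not** emulate: scale-free degree distributions or
the hub structure of real interactomes (blocks are Erdős–Rényi inside),
realistic GO depth (three layers, not sixteen), linkage disequilibrium or
population structure in the SNP table, correlated signatures across
related drugs, or the versioned idiosyncrasies of real resource schemas
beyond the columns the readers need. Passing tests therefore demonstrate
that the algorithms are implemented correctly and are calibrated under
their own assumptions — not that the biological conclusions drawn from
any particular real dataset would be reproduced. Headline counts from
real analyses (network sizes, numbers of significant drugs) depend on
versioned external resources and are out of scope here.

## Known limitations

* `d_c` is the only distance measure implemented; alternatives (shortest,
  centre, kernel) from the network-medicine literature are not offered.
* Information-content similarities (Resnik/Lin) are not implemented; only
  the Wang graph-based measure with is_a/part_of edges.
* The null preserves the distance multiset only when the random target's
  distance shells are populated; on very small or star-like networks the
  nearest-shell fallback can shift the null slightly (every fallback is
  logged).
* LD-based fine mapping, eQTL colocalization and epigenomic prioritization
  of causal variants are explicitly out of scope for the disease-gene
  stage, as is live retrieval from any external service.
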