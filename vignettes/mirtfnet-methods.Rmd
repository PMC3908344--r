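---
title: "Reverse-transcriptomics marker discovery with mirtfnet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-transcriptomics marker discovery with mirtfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtfnet)
```

## The problem and the approach

Lung cancer splits into two clinically distinct subtypes — non-small cell
(NSCLC) and small cell (SCLC) — and a large literature reports microRNAs
deregulated in one, the other, or both. miRNAs are hard to interpret
functionally on their own: no curated ontology annotates them directly.
The *reverse-transcriptomics* idea implemented here turns that around:
a miRNA inherits the functional annotation of its experimentally
validated target genes. Because miRNAs repress transcription factors
(TFs) and TFs in turn drive miRNA genes, target sets can be lifted into
composite miRNA–TF networks in which feed-back and feed-forward loops
are visible, and the differences between per-subtype networks nominate
TFs as subtype-specific diagnostic markers.

The pipeline runs in five stages, each an exported function family:

1. **Partition** (`partition_mirnas`): split a curated miRNA–disease
   association table into subtype-A-unique, subtype-B-unique and common
   miRNA sets, with up/down/differential tallies.
2. **Reverse annotation** (`annotate_mirna`, `filter_cohort_mirnas`):
   score each miRNA's validated target set for GO-term
   over-representation and retain miRNAs hitting cancer-relevant
   categories.
3. **Network construction** (`build_induced_network`,
   `apply_go_filters`, `overlay_regulation`): induce the PPI network
   over the retained cohort targets with one-hop neighbor expansion,
   reduce it by sequential GO category filters to the cell-cycle TF
   core, then overlay miRNA targeting and TF-to-miRNA regulation edges.
4. **Classification** (`classify_genes`, `containment_check`): compare
   the three cohort networks by set subtraction into six gene groups.
5. **Marker calling** (`key_nodes`, `shortest_path_members`,
   `enrichment_rank_genes`, `call_markers`): flag genes by three
   strategies — hub degree, shortest-path membership, disease-gene-set
   enrichment rank — and call the panel as their intersection over the
   subtype-discriminating groups.

## The enrichment model

The original workflow delegated target prioritization and functional
clustering to interactive web services. Those services are opaque and
version-dependent, so this package substitutes a single transparent
statistic: for a query set $q$ (a miRNA's targets, or a network's gene
set) and a term set $t$ inside a universe of $N$ genes, the p-value is
the upper-tail hypergeometric probability

$$P(X \ge k) \;=\; \sum_{x=k}^{\min(|t|,|q|)}
\frac{\binom{|t|}{x}\binom{N-|t|}{|q|-x}}{\binom{N}{|q|}},$$

with $k$ the observed overlap, Benjamini–Hochberg correction across all
tested terms, and dense 1-based ranking by ascending p. A miRNA is
*retained* when at least one whitelisted-category term is significant at
`alpha` after correction. Term sets are always intersected with the
universe before testing; an empty query yields an empty profile and an
empty universe is an error. The test suite checks the p-values against
an exhaustive `choose()`-based enumeration oracle to 12 significant
digits on all universes up to 25 genes.

"Top-ranked targets" had no printed cutoff in the original interactive workflow; the
package operationalizes it as *targets of retained miRNAs*, with the
retention whitelist and `alpha` both configurable. Defaults:
`whitelist = {transcription, cell_cycle, cell_organization_biogenesis}`
(the same three categories used as network filters) and `alpha = 0.05`.

## Network semantics

* **Neighbor expansion.** The printed node counts of the original
  interaction maps exceed their seed counts, implying the network
  browser added first-shell interaction partners. `build_induced_network`
  therefore includes seeds plus PPI neighbors to depth 1 (a config
  knob), and all PPI edges internal to that node set. Reproducing the
  2013 database-era counts is explicitly out of scope.
* **GO filters.** Filter semantics are node retention by annotation
  membership: a gene survives a step iff it is annotated to that
  category; miRNA nodes are exempt; dangling edges are dropped. Because
  each step is an intersection, the final node *set* is invariant to
  filter order (property-tested), while the intermediate trace is not.
  The two differently-named first filters of the original description
  ("Transcription" / "Transcription factor") are treated as the single
  category `transcription`, and "Cell cycle biogenesis" / "Cell
  Organization and Biogenesis" as the single category
  `cell_organization_biogenesis`.
* **Overlay.** A cohort miRNA joins the composite iff it targets a
  surviving gene (directed `targets` edge) or is regulated by one
  (directed `regulates` edge); genes are never removed. A feed-forward
  loop is a triple (TF $a$, miRNA $m$, TF $b$) with $a$ regulating $m$,
  $m$ targeting $b$, and an $a$–$b$ PPI edge.

## Classification: the six groups

With gene sets $A$ (NSCLC network), $B$ (SCLC network) and $C$ (common
network), groups 2–6 are literal set algebra: $A \cap B$,
$A \cap B \cap C$, $(A \cap C) \setminus B$, $A \setminus (B \cup C)$,
$C \setminus (A \cup B)$. Group 1 ("unique to SCLC") is defined as the
*full* SCLC gene set $B$ rather than $B \setminus (A \cup C)$. This is a
deliberate design choice: the published marker table lists all nine SCLC
genes under group 1 even though every one of them is shared (the SCLC
network is contained in the NSCLC network), and the group-1 = group-2 =
group-3 identity under containment only holds with this reading. It also
makes the six groups exactly cover $A \cup B \cup C$ — with the strict
difference, genes in $B \cap C \setminus A$ would belong to no group.
The trade-off is that group 1 may overlap groups 2–3 in general; it is
always disjoint from groups 4–6.

## Marker strategies and the panel

* **Key nodes**: genes ranked by total composite degree (all edge types,
  direction collapsed, parallel edges between a pair counted once).
  Default selection is the top quarter of genes (`top = 0.25`),
  boundary ties included, so the result is deterministic. No threshold
  was ever published; a quantile is scale-free-friendly and the
  knob is exposed.
* **Shortest paths**: unweighted breadth-first geodesics over the
  composite network with edge types collapsed (no edge weights exist in
  any input; the original tool's algorithm is unrecoverable). Endpoints
  default to the key-node set, since the two analyses were described as
  one coupled step. Endpoints count as members; unreachable pairs
  contribute nothing.
* **Enrichment rank**: each disease gene set (GMT) is tested against the
  network's gene set; a gene scores the minimum q-value over sets
  containing it; genes in no set are unranked and excluded.

The panel intersects the three flags over the subtype-discriminating
groups (`NSCLC_specific`, `general_specific` — the shared groups cannot
discriminate subtypes and are reported but not called). Whether the original
study intersected per cohort or across pooled candidates is unstated;
scoring is per cohort network here, with a `majority` policy flag as the
relaxation. The pipeline does not predict a marker's direction of
deregulation in patients — that came from microarray/qPCR follow-up — so
panels carry `expected_direction = "unknown"`.

## The synthetic world

`synthetic_config()` states one fixed world per the counts the original study
reports: 143 A-unique, 21 B-unique and 41 shared miRNAs; 4 planted
A-specific and 3 planted general-path markers (the panel sizes); a
9-gene TF core present in all three networks and a 6-gene block shared
by A and the common cohort (the scale of the published shared groups).
Where no value is stated, desk-scale choices were made once: a 600-gene
universe, 16 targets per miRNA (the reported common cohort averaged ~16
targets per miRNA), Erdős–Rényi background PPI at p = 0.008 (mean degree
≈ 5, typical of curated PPI subnets), GO annotation noise 2%.

Construction guarantees, not hopes, the planted structure: each miRNA
draws five targets from one small TF module (making its profile
strongly enriched, hence retained); filler pools are disjoint per
cohort and cc-block PPI edges only join blocks with identical cohort
membership, so one-hop expansion cannot leak a marker into a foreign
network; planted markers are wired with extra background PPI edges
until their raw degree exceeds the non-planted median, and with extra
TF-to-miRNA regulation edges until their composite degree out-ranks
every non-planted gene; each planted marker regulates a miRNA that
targets another member of its block, closing a feed-forward loop over
the intra-block PPI edge. Decoy TFs are annotated and targeted like
markers but never appear in regulation edges and are absent from the
disease gene sets, so each fails at least one criterion. Each table
draws from its own RNG stream derived from the master seed, so adding
one table never perturbs another.

What a green synthetic test establishes: that every stage implements
its contract and that the three-strategy intersection recovers exactly
the genes engineered to satisfy all criteria (recall and precision 1.0
over 20 seeds), degrading monotonically on average as target/PPI edges
are deleted. What it does not establish: performance on real curated
tables, where identifiers are inconsistent, annotation is incomplete
and biased, PPI networks are scale-free with study bias, and the
"truth" is unknown. The generator makes no attempt at realistic miRNA
nomenclature, expression values or sequence content.

## Numerical and interface choices

* Identifiers are opaque strings, normalized once (trim + uppercase) at
  load; no symbol authority is consulted, because reproducing the
  printed tables must not depend on one (the printed symbols include
  several non-standard forms, e.g. CMYC, PCAF, TWIST, HNRPD).
* GO is consumed as a flat gene-to-term table with a term-to-category
  mapping; no OBO graph, no ancestor propagation — the pipeline only
  ever uses three coarse categories.
* PPI edges are stored canonically (lexicographically smaller endpoint
  first) and deduplicated; self-loops are dropped.
* Within-cohort contradictory reports (a miRNA published both up and
  down in the same subtype) merge to direction `conflict` and count in
  neither tally; this is why per-direction tallies need not sum to the
  set size. Across cohorts, opposite directions classify a shared miRNA
  as `differential`.
* The run configuration is a flat `key: value` document parsed with
  `read.dcf` — the pre-installed stack has no YAML parser and the
  format needs nothing nested. CLI flags override config keys.
* All analysis stages are deterministic; the only randomness in the
  package is the synthetic generator, driven by one recorded master
  seed.

## Known limitations

* The published intermediate counts (e.g. 638 targets → 1791 nodes →
  170 → 26) depended on 2013 snapshots of miRWalk, miRTarBase, TransmiR,
  Osprey's interaction DB, etc., and are not reproducible from scratch;
  the package reproduces the downstream arithmetic from the printed
  memberships instead, and its own network stages are validated on
  synthetic data.
* The association fixture encodes the printed totals (184 NSCLC, 62
  SCLC, 41 shared), which force 21 SCLC-unique miRNAs although the
  original tallies report 22 (and direction tallies summing to 42 of 41
  shared miRNAs); the partition stage computes set arithmetic faithfully
  and the report exposes the counts rather than papering over them.
* Group 1 of the classification follows the published table's semantics
  (see above); users wanting the strict difference can compute
  `setdiff` from the same object.
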