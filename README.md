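# mirtfnet

Reverse-transcriptomics biomarker discovery for disease subtypes, built
around miRNA–transcription-factor regulatory networks. The package is
aimed at systems-biology analysts who start from *curated lists of
deregulated miRNAs* per disease subtype (here: non-small cell and small
cell lung cancer) and want to end with a small panel of candidate
transcription-factor markers, with every intermediate step scriptable,
deterministic, and testable.

## What it computes

miRNAs carry no direct functional annotation, so each miRNA inherits the
Gene Ontology annotation of its experimentally validated target genes
("reverse annotation"). For a target set *q* and GO term set *t* in a
universe of *N* genes, over-representation is scored by the upper-tail
hypergeometric probability

    P(X >= k) = sum_{x=k}^{min(|t|,|q|)} C(|t|,x) C(N-|t|, |q|-x) / C(N,|q|)

with Benjamini–Hochberg control across terms. Retained miRNAs (those
hitting cancer-relevant categories: transcription, cell cycle, cell
organization/biogenesis) pool their targets per cohort; the PPI network
induced over each pool (seeds + one-hop neighbors) is reduced by the
three GO category filters to a cell-cycle TF core and overlaid with
miRNA→TF targeting and TF→miRNA regulation edges, yielding composite
networks in which feed-forward loops (TF a → miRNA m → TF b, with a–b
interacting) are countable.

The three cohort networks A (NSCLC), B (SCLC), C (common) are compared
by set subtraction into six gene groups (A∩B, A∩B∩C, (A∩C)∖B, A∖(B∪C),
C∖(A∪B), and B itself), and markers are called on the
subtype-discriminating groups as the intersection of three strategies:

* **key nodes** — top-degree genes of the composite network (default top
  25%, ties included);
* **shortest paths** — genes on at least one unweighted geodesic between
  key-node pairs;
* **enrichment rank** — genes ranked by their best disease-gene-set
  q-value.

A synthetic-data module generates complete six-table input bundles with
planted markers that provably satisfy all criteria, so the whole
pipeline is validated end-to-end without any download.

## Worked example

Reconstructing the published lung-cancer comparison from the packaged
fixtures (the printed six-group marker table and miRNA totals):

```r
library(mirtfnet)

nets <- table1_networks()          # NSCLC: 27, SCLC: 9, common: 26 genes
cl <- classify_genes(nets$NSCLC, nets$SCLC, nets$common)
print(cl)
#>   unique_SCLC              9 genes
#>   common_SCLC_NSCLC        9 genes
#>   common_all               9 genes
#>   common_NSCLC_general    14 genes
#>   NSCLC_specific           4 genes
#>   general_specific         3 genes
containment_check(nets$SCLC, nets$NSCLC)$contained
#> [1] TRUE

partition_mirnas(lung_association_fixture())
#> <partition_result> NSCLC-unique: 143, SCLC-unique: 21, common: 41 (total 205)
```

The four NSCLC-specific genes (E2F6, TFDP1, SUV39H1, HNRPD) plus the
three general-path genes (RBL1, IRF1, HMGA1) are the seven-gene marker
panel; `call_markers` returns exactly these under the intersection
policy. The 143 NSCLC-unique miRNAs follow from the printed totals
184 − 41 by set arithmetic.

End-to-end on a synthetic bundle with planted markers:

```r
b <- generate_bundle(synthetic_config(seed = 1))
res <- run_pipeline(b$association, b$targets, b$annotations, b$ppi,
                    b$regulation, b$disease_sets)
print(res)
#> <pipeline_result>
#> <partition_result> NSCLC-unique: 143, SCLC-unique: 21, common: 41 (total 205)
#>   A       network: 22 genes, 143 miRNAs, 29 ffl
#>   B       network: 9 genes, 21 miRNAs, 3 ffl
#>   common  network: 21 genes, 41 miRNAs, 9 ffl
#>   panel: TFMA01, TFMA02, TFMA03, TFMA04, TFMG01, TFMG02, TFMG03
marker_recovery(res, b$truth)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

The panel is exactly the seven planted markers (TFMA* are the planted
NSCLC-specific TFs, TFMG* the planted general-path TFs).

A file-driven run uses a flat `key: value` config (see
`?read_run_config`) through `run_all(cfg)`, or the CLI at
`inst/cli/mirtfnet.R` with subcommands `simulate`, `partition`,
`annotate`, `build-net`, `compare`, `call-markers`, `run-all`.

## Scope notes

The literature mining that produced the original association tables, and
the 2013 database-era intermediate network sizes, are out of scope; see
`vignettes/mirtfnet-methods.Rmd` for the model, the parameter defaults
and every open design decision.
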