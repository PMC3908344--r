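# Per-cohort network construction: induced PPI network over pooled targets
# with one-hop neighbor expansion, sequential GO category filters, and the
# miRNA overlay that turns the TF-TF network into a composite miRNA-TF map.

#' Build the target-induced PPI network
#'
#' Nodes are the seed genes plus their PPI neighbors up to \code{depth}
#' hops (default one hop, mirroring interaction-browser expansion); edges
#' are all PPI edges with both endpoints in the node set. Seed genes are
#' retained even when isolated.
#'
#' @param seed_genes non-empty character vector of seed genes.
#' @param ppi data.frame of undirected edges (\code{gene_a}, \code{gene_b}).
#' @param cohort cohort tag for the resulting network.
#' @param depth neighbor expansion depth (non-negative integer).
#' @return a \code{\link{regulatory_network}} of gene nodes and
#'   \code{ppi} edges.
#' @export
build_induced_network <- function(seed_genes, ppi, cohort = "unspecified",
                                  depth = 1L) {
  seed_genes <- unique(normalize_id(seed_genes))
  if (length(seed_genes) == 0L) stop("seed_genes must be non-empty")
  ppi <- canonical_ppi(ppi)
  nodes <- seed_genes
  frontier <- seed_genes
  d <- 0L
  while (d < depth && length(frontier)) {
    nb <- c(ppi$gene_b[ppi$gene_a %in% frontier],
            ppi$gene_a[ppi$gene_b %in% frontier])
    frontier <- setdiff(unique(nb), nodes)
    nodes <- union(nodes, frontier)
    d <- d + 1L
  }
  keep <- ppi$gene_a %in% nodes & ppi$gene_b %in% nodes
  edges <- data.frame(from = ppi$gene_a[keep], to = ppi$gene_b[keep],
                      type = rep("ppi", sum(keep)), stringsAsFactors = FALSE)
  regulatory_network(
    data.frame(id = nodes, type = "gene", stringsAsFactors = FALSE),
    edges, cohort = cohort)
}

#' Apply sequential GO category filters to a network
#'
#' At each step only the gene nodes annotated to the current category are
#' retained (miRNA nodes are exempt); edges losing an endpoint are dropped.
#' The default sequence (transcription, then cell cycle, then cell
#' organization and biogenesis) leaves the cell-cycle-specific TF core.
#' Since each step is a set intersection, the final node set is invariant
#' under filter order, though the intermediate trace is not.
#'
#' @param net a \code{\link{regulatory_network}}.
#' @param annotations gene-GO annotation data.frame (see
#'   \code{\link{read_annotation_table}}).
#' @param filters non-empty ordered character vector of GO categories.
#' @return list with \code{network} (the filtered network) and
#'   \code{trace}, a data.frame of class \code{filter_trace} with columns
#'   \code{filter}, \code{nodes}, \code{edges} (counts after each step; the
#'   first row, labeled \code{"input"}, is the unfiltered state).
#' @export
apply_go_filters <- function(net, annotations,
                             filters = default_whitelist()) {
  stopifnot(inherits(net, "regulatory_network"))
  if (length(filters) == 0L) stop("filters must be non-empty")
  bad <- setdiff(filters, go_categories())
  if (length(bad)) stop("unknown GO filter category: ", paste(bad, collapse = ", "))
  trace <- data.frame(filter = "input", nodes = nrow(net$nodes),
                      edges = nrow(net$edges), stringsAsFactors = FALSE)
  cur <- net
  for (f in filters) {
    annotated <- unique(annotations$gene_id[annotations$go_category == f])
    keep_ids <- cur$nodes$id[cur$nodes$type == "mirna" |
                             cur$nodes$id %in% annotated]
    nodes <- cur$nodes[cur$nodes$id %in% keep_ids, , drop = FALSE]
    edges <- cur$edges[cur$edges$from %in% keep_ids &
                       cur$edges$to %in% keep_ids, , drop = FALSE]
    cur <- regulatory_network(nodes, edges, cohort = cur$cohort)
    trace <- rbind(trace, data.frame(filter = f, nodes = nrow(cur$nodes),
                                     edges = nrow(cur$edges),
                                     stringsAsFactors = FALSE))
  }
  class(trace) <- c("filter_trace", "data.frame")
  list(network = cur, trace = trace)
}

#' Overlay miRNA nodes onto a GO-filtered TF network
#'
#' Adds each cohort miRNA that either targets at least one gene node
#' (directed \code{targets} edge, miRNA to gene) or is regulated by at
#' least one gene node (directed \code{regulates} edge, gene to miRNA).
#' Gene nodes are never removed. Wherever both edge kinds meet, the
#' composite realizes TF-miRNA-TF (equivalently miRNA-TF-miRNA) paths.
#'
#' @param net the GO-filtered gene network.
#' @param regulation TF-to-miRNA edges (see
#'   \code{\link{read_regulation_table}}).
#' @param targets miRNA-to-gene edges (see \code{\link{read_target_table}}).
#' @param cohort_mirnas miRNAs eligible for this cohort's overlay.
#' @return the composite \code{\link{regulatory_network}}.
#' @export
overlay_regulation <- function(net, regulation, targets, cohort_mirnas) {
  stopifnot(inherits(net, "regulatory_network"))
  cohort_mirnas <- unique(normalize_id(cohort_mirnas))
  genes <- network_genes(net)
  clash <- intersect(cohort_mirnas, genes)
  if (length(clash)) {
    stop("gene/miRNA namespaces overlap: ", paste(clash, collapse = ", "))
  }
  tt <- targets[targets$validated & targets$mirna_id %in% cohort_mirnas &
                targets$gene_id %in% genes, , drop = FALSE]
  rr <- regulation[regulation$mirna_id %in% cohort_mirnas &
                   regulation$tf_id %in% genes, , drop = FALSE]
  used <- union(unique(tt$mirna_id), unique(rr$mirna_id))
  if (length(used) == 0L) return(net)
  nodes <- rbind(net$nodes,
                 data.frame(id = used, type = "mirna", stringsAsFactors = FALSE))
  edges <- rbind(net$edges,
                 data.frame(from = tt$mirna_id, to = tt$gene_id,
                            type = rep("targets", nrow(tt)),
                            stringsAsFactors = FALSE),
                 data.frame(from = rr$tf_id, to = rr$mirna_id,
                            type = rep("regulates", nrow(rr)),
                            stringsAsFactors = FALSE))
  regulatory_network(nodes, edges, cohort = net$cohort)
}

#' Count feed-forward loops in a composite network
#'
#' A feed-forward loop is a triple (TF a, miRNA m, TF b) such that a
#' regulates m (\code{regulates} edge), m targets b (\code{targets} edge),
#' and a and b interact (\code{ppi} edge), with a and b distinct. Each
#' role assignment is counted once.
#'
#' @param net a composite \code{\link{regulatory_network}}.
#' @return integer count of feed-forward loops.
#' @export
count_feedforward_loops <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  reg <- e[e$type == "regulates", , drop = FALSE]
  tar <- e[e$type == "targets", , drop = FALSE]
  ppi <- e[e$type == "ppi", , drop = FALSE]
  if (!nrow(reg) || !nrow(tar) || !nrow(ppi)) return(0L)
  ppi_key <- paste(ppi$from, ppi$to)  # canonical order already
  n <- 0L
  for (i in seq_len(nrow(reg))) {
    a <- reg$from[i]; m <- reg$to[i]
    bs <- tar$to[tar$from == m]
    bs <- bs[bs != a]
    if (!length(bs)) next
    key <- paste(pmin(a, bs), pmax(a, bs))
    n <- n + sum(key %in% ppi_key)
  }
  n
}
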