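# Differential network comparison and three-strategy marker calling:
# six-group gene classification by network subtraction, key-node (hub)
# detection, shortest-path membership, disease-set enrichment ranking, and
# the intersection panel.

#' Classify genes across three cohort networks
#'
#' Set algebra over the gene node sets of the two subtype networks A and B
#' and the common-event network C. Groups 4-6 are the literal differences
#' and intersections; groups 1-3 follow the reporting convention of the
#' underlying study: group 1 (\code{unique_SCLC}) is the full gene set of
#' the smaller subtype network, which coincides with groups 2 and 3
#' whenever that network is contained in both of the others (the observed
#' case), and is the only group covering genes B shares with C alone.
#'
#' @param net_A network of subtype A (NSCLC-like).
#' @param net_B network of subtype B (SCLC-like).
#' @param net_common network of the shared/common events.
#' @return object of class \code{gene_group_classification}: a list of six
#'   sorted gene sets \code{unique_SCLC} (= B), \code{common_SCLC_NSCLC}
#'   (A\eqn{\cap}B), \code{common_all} (A\eqn{\cap}B\eqn{\cap}C),
#'   \code{common_NSCLC_general} ((A\eqn{\cap}C)\eqn{\setminus}B),
#'   \code{NSCLC_specific} (A\eqn{\setminus}(B\eqn{\cup}C)),
#'   \code{general_specific} (C\eqn{\setminus}(A\eqn{\cup}B)).
#' @export
classify_genes <- function(net_A, net_B, net_common) {
  A <- network_genes(net_A)
  B <- network_genes(net_B)
  C <- network_genes(net_common)
  structure(list(
    unique_SCLC = sort(B),
    common_SCLC_NSCLC = sort(intersect(A, B)),
    common_all = sort(Reduce(intersect, list(A, B, C))),
    common_NSCLC_general = sort(setdiff(intersect(A, C), B)),
    NSCLC_specific = sort(setdiff(A, union(B, C))),
    general_specific = sort(setdiff(C, union(A, B)))
  ), class = "gene_group_classification")
}

#' @export
print.gene_group_classification <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("  %-22s %3d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Look up the classification group of genes
#'
#' Returns, per gene, the most specific group containing it, preferring the
#' marker-bearing groups (NSCLC_specific, general_specific) and falling
#' back through the shared groups.
#'
#' @param classification a \code{gene_group_classification}.
#' @param genes character vector of gene ids.
#' @return character vector of group names (NA when a gene is in no group).
#' @export
classification_group <- function(classification, genes) {
  order <- c("NSCLC_specific", "general_specific", "common_all",
             "common_NSCLC_general", "common_SCLC_NSCLC", "unique_SCLC")
  vapply(genes, function(g) {
    for (nm in order) if (g %in% classification[[nm]]) return(nm)
    NA_character_
  }, character(1))
}

#' Check gene-level containment of one network in another
#'
#' @param net_sub candidate sub-network.
#' @param net_super candidate super-network.
#' @return list with \code{contained} (logical) and \code{witness}, the
#'   genes of \code{net_sub} absent from \code{net_super} (empty when
#'   contained).
#' @export
containment_check <- function(net_sub, net_super) {
  witness <- setdiff(network_genes(net_sub), network_genes(net_super))
  list(contained = length(witness) == 0L, witness = sort(witness))
}

#' Key nodes: highest-degree genes of a network
#'
#' Genes are ranked by total degree over all edge types of the composite
#' network. \code{top} selects either the top \code{k} genes (integer
#' \eqn{\ge} 1) or the top fraction of genes (0 < top < 1, default the top
#' quarter); ties at the boundary degree are all included, so the result
#' is deterministic.
#'
#' @param net a \code{\link{regulatory_network}} with at least one gene.
#' @param top integer count or fraction in (0, 1).
#' @return sorted character vector of key-node genes.
#' @export
key_nodes <- function(net, top = 0.25) {
  genes <- network_genes(net)
  if (length(genes) == 0L) stop("network has no gene node")
  if (!is.numeric(top) || length(top) != 1L || top <= 0) {
    stop("config error: top must be a positive count or a fraction in (0,1)")
  }
  deg <- network_degree(net)[genes]
  k <- if (top < 1) max(1L, ceiling(top * length(genes))) else min(as.integer(top), length(genes))
  cutoff <- sort(deg, decreasing = TRUE)[k]
  sort(names(deg)[deg >= cutoff])
}

#' Genes on shortest paths between endpoint pairs
#'
#' A gene is a member iff it lies on at least one unweighted shortest path
#' (breadth-first distance over the composite network with edge types
#' collapsed) between some pair of endpoints. Endpoints are themselves
#' members; pairs in different components contribute nothing beyond the
#' endpoints. miRNA nodes traversed by a path are not reported.
#'
#' @param net a \code{\link{regulatory_network}}.
#' @param endpoints gene set with at least two members, all in the network.
#' @return sorted character vector of member genes.
#' @export
shortest_path_members <- function(net, endpoints) {
  genes <- network_genes(net)
  endpoints <- unique(normalize_id(endpoints))
  if (!all(endpoints %in% genes)) {
    stop("endpoints outside the network: ",
         paste(setdiff(endpoints, genes), collapse = ", "))
  }
  if (length(endpoints) < 2L) stop("at least two endpoints are required")
  g <- as_igraph(net)
  members <- endpoints
  for (i in seq_along(endpoints)) {
    others <- endpoints[-seq_len(i)]
    if (!length(others)) next
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = endpoints[i], to = others,
                                 mode = "all"))
    for (p in sp$vpaths) members <- union(members, names(p))
  }
  sort(intersect(members, genes))
}

#' Rank network genes by disease-set enrichment
#'
#' Each disease set is tested for over-representation in the network's gene
#' set by \code{\link{hypergeom_enrich}}; a gene is scored by the best
#' (minimum) q-value among the disease sets containing it. Genes belonging
#' to no disease set are unranked and excluded. The \code{top_n} best
#' scores are returned, ties at the boundary included.
#'
#' @param net a \code{\link{regulatory_network}}.
#' @param disease_sets named list of gene sets (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe gene universe for the enrichment test.
#' @param top_n number of genes to select (default 25).
#' @return list with \code{genes} (sorted selected genes) and
#'   \code{ranks}, a data.frame of columns \code{gene}, \code{score},
#'   \code{rank} (dense, 1-based) over all ranked genes.
#' @export
enrichment_rank_genes <- function(net, disease_sets, universe, top_n = 25L) {
  if (length(disease_sets) == 0L) stop("disease_sets must be non-empty")
  genes <- network_genes(net)
  universe <- unique(c(as.character(universe), genes))
  enr <- hypergeom_enrich(genes, disease_sets, universe)
  scored <- lapply(names(disease_sets), function(nm) {
    members <- intersect(normalize_id(disease_sets[[nm]]), genes)
    if (!length(members)) return(NULL)
    data.frame(gene = members, score = enr$q_value[enr$term == nm],
               stringsAsFactors = FALSE)
  })
  scored <- do.call(rbind, scored)
  if (is.null(scored) || nrow(scored) == 0L) {
    return(list(genes = character(),
                ranks = data.frame(gene = character(), score = numeric(),
                                   rank = integer(), stringsAsFactors = FALSE)))
  }
  best <- tapply(scored$score, scored$gene, min)
  ranks <- data.frame(gene = names(best), score = as.numeric(best),
                      stringsAsFactors = FALSE)
  ranks <- ranks[order(ranks$score, ranks$gene), , drop = FALSE]
  ranks$rank <- match(ranks$score, sort(unique(ranks$score)))  # dense ranks
  rownames(ranks) <- NULL
  # select the smallest set of whole rank classes covering top_n genes
  cum <- cumsum(as.integer(table(ranks$rank)))
  n_classes <- which(cum >= min(top_n, nrow(ranks)))[1]
  sel <- ranks$gene[ranks$rank <= sort(unique(ranks$rank))[n_classes]]
  list(genes = sort(sel), ranks = ranks)
}

#' Score genes of a cohort network under the three marker strategies
#'
#' Computes, for every gene of the network: total degree, key-node flag
#' (\code{\link{key_nodes}}), shortest-path membership
#' (\code{\link{shortest_path_members}} with the key nodes as endpoints,
#' the default coupling of the two analyses), and the disease-set
#' enrichment rank (\code{\link{enrichment_rank_genes}}; NA when the gene
#' is in no disease set or not selected).
#'
#' @param net a composite \code{\link{regulatory_network}}.
#' @param disease_sets named list of disease gene sets.
#' @param universe gene universe for the enrichment ranking.
#' @param top key-node selection count/fraction (see
#'   \code{\link{key_nodes}}).
#' @param top_n enrichment ranking depth (see
#'   \code{\link{enrichment_rank_genes}}).
#' @param endpoints optional endpoint override for the shortest-path
#'   strategy (default: the key-node set).
#' @return data.frame of class \code{strategy_scores}: columns \code{gene},
#'   \code{degree}, \code{is_key_node}, \code{on_shortest_path},
#'   \code{enrichment_rank}.
#' @export
strategy_scores <- function(net, disease_sets, universe, top = 0.25,
                            top_n = 25L, endpoints = NULL) {
  genes <- network_genes(net)
  deg <- network_degree(net)[genes]
  keys <- key_nodes(net, top = top)
  if (is.null(endpoints)) endpoints <- keys
  sp <- if (length(endpoints) >= 2L) {
    shortest_path_members(net, endpoints)
  } else endpoints
  er <- enrichment_rank_genes(net, disease_sets, universe, top_n = top_n)
  rk <- stats::setNames(er$ranks$rank, er$ranks$gene)
  out <- data.frame(
    gene = genes,
    degree = as.integer(deg),
    is_key_node = genes %in% keys,
    on_shortest_path = genes %in% sp,
    enrichment_rank = ifelse(genes %in% er$genes,
                             as.integer(rk[genes]), NA_integer_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("strategy_scores", "data.frame")
  out
}

#' Call the marker panel
#'
#' Combines per-gene strategy scores with the six-group classification.
#' Candidate markers are the genes of the subtype-discriminating groups
#' (by default \code{NSCLC_specific} and \code{general_specific}; the
#' shared groups cannot discriminate subtypes). Under the default
#' \code{intersection} policy a candidate enters the panel only when all
#' three strategies flag it (key node, on a shortest path, and
#' enrichment-ranked); under \code{majority}, when at least two do.
#'
#' @param scores a \code{strategy_scores} data.frame (rows from several
#'   cohort networks may be concatenated; a gene's best evidence is used).
#' @param classification a \code{gene_group_classification}.
#' @param policy \code{"intersection"} (default) or \code{"majority"}.
#' @param marker_groups classification groups eligible for the panel.
#' @return data.frame of class \code{marker_panel}: columns
#'   \code{gene_id}, \code{strategies} (comma-joined evidence),
#'   \code{degree}, \code{enrichment_rank}, \code{cohort_origin},
#'   \code{expected_direction} (always \code{"unknown"}: the pipeline does
#'   not predict regulation direction in patients).
#' @export
call_markers <- function(scores, classification,
                         policy = c("intersection", "majority"),
                         marker_groups = c("NSCLC_specific", "general_specific")) {
  policy <- match.arg(policy)
  stopifnot(inherits(classification, "gene_group_classification"))
  candidates <- sort(unique(unlist(classification[marker_groups],
                                   use.names = FALSE)))
  sc <- as.data.frame(scores)
  sc <- sc[sc$gene %in% candidates, , drop = FALSE]
  if (nrow(sc)) {
    # a gene scored in several networks keeps its best evidence per strategy
    agg <- lapply(split(sc, sc$gene), function(d) {
      data.frame(gene = d$gene[1],
                 degree = max(d$degree),
                 is_key_node = any(d$is_key_node),
                 on_shortest_path = any(d$on_shortest_path),
                 enrichment_rank = if (all(is.na(d$enrichment_rank))) NA_integer_
                                   else min(d$enrichment_rank, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    sc <- do.call(rbind, agg)
  }
  n_strat <- with(sc, is_key_node + on_shortest_path + !is.na(enrichment_rank))
  need <- if (policy == "intersection") 3L else 2L
  panel <- sc[n_strat >= need, , drop = FALSE]
  strategies <- vapply(seq_len(nrow(panel)), function(i) {
    paste(c("key_node", "shortest_path", "enrichment_rank")[
      c(panel$is_key_node[i], panel$on_shortest_path[i],
        !is.na(panel$enrichment_rank[i]))], collapse = ",")
  }, character(1))
  out <- data.frame(
    gene_id = panel$gene,
    strategies = strategies,
    degree = panel$degree,
    enrichment_rank = panel$enrichment_rank,
    cohort_origin = classification_group(classification, panel$gene),
    expected_direction = rep("unknown", nrow(panel)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_panel", "data.frame")
  out
}
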