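#' mirtfnet: miRNA-TF regulatory networks and subtype marker discovery
#'
#' Reverse-transcriptomics marker discovery: disease-subtype miRNA lists are
#' annotated through their validated targets, expanded into GO-filtered
#' miRNA-TF composite networks per cohort, compared by network subtraction,
#' and reduced to a marker panel by intersecting key-node, shortest-path and
#' enrichment-rank evidence.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Identifier normalization
# ---------------------------------------------------------------------------

#' Normalize gene and miRNA identifiers
#'
#' Identifiers are treated as opaque strings: a single pass of whitespace
#' stripping and upper-casing is applied at load time so that variant
#' capitalizations of the same printed symbol compare equal. No symbol
#' authority (HGNC, miRBase) is consulted.
#'
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @export
normalize_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' GO category labels recognized by the pipeline
#'
#' The three cancer-relevant coarse categories used as sequential network
#' filters, plus the catch-all \code{"other"}.
#'
#' @return character vector of category labels.
#' @export
go_categories <- function() {
  c("transcription", "cell_cycle", "cell_organization_biogenesis", "other")
}

#' Default cancer-GO whitelist
#'
#' The whitelist used to retain miRNAs (and, as sequential filters, network
#' nodes): transcription, cell cycle, and cell organization and biogenesis.
#'
#' @return character vector of category labels.
#' @export
default_whitelist <- function() {
  c("transcription", "cell_cycle", "cell_organization_biogenesis")
}

# ---------------------------------------------------------------------------
# regulatory_network S3 class
# ---------------------------------------------------------------------------

#' Construct a regulatory network
#'
#' A labeled graph over gene and miRNA nodes with three edge types:
#' undirected protein-protein interactions (\code{ppi}, stored canonically
#' with the lexicographically smaller endpoint first), directed
#' miRNA-to-gene targeting (\code{targets}), and directed gene-to-miRNA
#' regulation (\code{regulates}).
#'
#' @param nodes data.frame with columns \code{id}, \code{type}
#'   (\code{"gene"} or \code{"mirna"}).
#' @param edges data.frame with columns \code{from}, \code{to}, \code{type}
#'   (\code{"ppi"}, \code{"targets"} or \code{"regulates"}); may be empty.
#' @param cohort cohort tag, e.g. \code{"NSCLC"}, \code{"SCLC"},
#'   \code{"common"}.
#' @return object of class \code{regulatory_network}.
#' @export
regulatory_network <- function(nodes, edges = NULL, cohort = "unspecified") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_type <- setdiff(unique(nodes$type), c("gene", "mirna"))
  if (length(bad_type)) stop("unknown node type: ", paste(bad_type, collapse = ", "))
  bad_et <- setdiff(unique(edges$type), c("ppi", "targets", "regulates"))
  if (length(bad_et)) stop("unknown edge type: ", paste(bad_et, collapse = ", "))
  missing_ep <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing_ep)) {
    stop("edge endpoint not declared as node: ",
         paste(missing_ep, collapse = ", "))
  }
  # canonicalize undirected ppi edges and drop duplicates
  is_ppi <- edges$type == "ppi"
  if (any(is_ppi)) {
    a <- pmin(edges$from[is_ppi], edges$to[is_ppi])
    b <- pmax(edges$from[is_ppi], edges$to[is_ppi])
    edges$from[is_ppi] <- a
    edges$to[is_ppi] <- b
    edges <- edges[!(is_ppi & edges$from == edges$to), , drop = FALSE]
  }
  edges <- unique(edges)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(cohort = cohort, nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> cohort=%s: %d genes, %d miRNAs, %d edges\n",
              x$cohort, length(network_genes(x)),
              sum(x$nodes$type == "mirna"), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(x$edges$type)
    cat("  edges:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gene nodes of a network
#'
#' @param net a \code{regulatory_network}.
#' @return character vector of gene node ids (sorted).
#' @export
network_genes <- function(net) {
  sort(net$nodes$id[net$nodes$type == "gene"])
}

#' miRNA nodes of a network
#'
#' @param net a \code{regulatory_network}.
#' @return character vector of miRNA node ids (sorted).
#' @export
network_mirnas <- function(net) {
  sort(net$nodes$id[net$nodes$type == "mirna"])
}

#' Convert a regulatory network to an igraph object
#'
#' Edge directions and types are collapsed: the result is an undirected
#' simple graph suitable for degree and unweighted shortest-path analysis.
#' Parallel edges of different types between the same pair are merged.
#'
#' @param net a \code{regulatory_network}.
#' @return an \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$id,
                            type = net$nodes$type)
  if (nrow(net$edges)) {
    a <- pmin(net$edges$from, net$edges$to)
    b <- pmax(net$edges$from, net$edges$to)
    keep <- !duplicated(paste(a, b))
    g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
  }
  g
}

#' Node degree in the composite network
#'
#' Total degree over all edge types, with edge direction collapsed and
#' parallel edges of different types between the same node pair counted once.
#'
#' @param net a \code{regulatory_network}.
#' @return named integer vector over all nodes.
#' @export
network_degree <- function(net) {
  g <- as_igraph(net)
  d <- igraph::degree(g)
  stats::setNames(as.integer(d), igraph::V(g)$name)
}

#' Two networks are equal up to ordering
#'
#' @param a,b \code{regulatory_network} objects.
#' @return logical.
#' @export
network_identical <- function(a, b) {
  identical(a$nodes, b$nodes) && identical(a$edges, b$edges)
}
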