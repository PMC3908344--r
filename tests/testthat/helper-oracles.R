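# Independent brute-force oracles. These deliberately avoid the code paths
# they check: combinatorial enumeration instead of phyper/p.adjust, plain
# loops instead of igraph.

# upper-tail hypergeometric P(X >= k) by direct enumeration over choose()
oracle_hypergeom_upper <- function(k, term_size, universe_size, query_size) {
  xs <- k:min(term_size, query_size)
  if (k <= 0) return(1)
  if (!length(xs) || k > min(term_size, query_size)) return(0)
  sum(vapply(xs, function(x) {
    choose(term_size, x) * choose(universe_size - term_size, query_size - x)
  }, numeric(1))) / choose(universe_size, query_size)
}

# adjacency list from an undirected edge matrix (2-column character)
oracle_adj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# degree-sorted top-k gene selection with boundary ties, by counting
oracle_key_nodes <- function(net, k) {
  genes <- sort(net$nodes$id[net$nodes$type == "gene"])
  pairs <- unique(data.frame(a = pmin(net$edges$from, net$edges$to),
                             b = pmax(net$edges$from, net$edges$to)))
  deg <- vapply(genes, function(g) sum(pairs$a == g) + sum(pairs$b == g),
                numeric(1))
  cutoff <- sort(deg, decreasing = TRUE)[min(k, length(deg))]
  sort(genes[deg >= cutoff])
}

# all simple paths between two nodes by depth-first search
oracle_all_paths <- function(adj, from, to) {
  paths <- list()
  walk <- function(cur, seen) {
    if (cur == to) { paths[[length(paths) + 1]] <<- seen; return(invisible()) }
    for (nb in adj[[cur]]) {
      if (!(nb %in% seen)) walk(nb, c(seen, nb))
    }
  }
  walk(from, from)
  paths
}

# members of at least one shortest path between some endpoint pair
oracle_shortest_members <- function(net, endpoints) {
  nodes <- net$nodes$id
  pairs <- unique(data.frame(a = pmin(net$edges$from, net$edges$to),
                             b = pmax(net$edges$from, net$edges$to)))
  adj <- oracle_adj(nodes, as.matrix(pairs))
  members <- endpoints
  if (length(endpoints) >= 2) {
    cmb <- utils::combn(endpoints, 2)
    for (i in seq_len(ncol(cmb))) {
      ps <- oracle_all_paths(adj, cmb[1, i], cmb[2, i])
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1))
      for (p in ps[lens == min(lens)]) members <- union(members, p)
    }
  }
  genes <- net$nodes$id[net$nodes$type == "gene"]
  sort(intersect(members, genes))
}

# feed-forward loops by exhaustive triple enumeration
oracle_ffl <- function(net) {
  e <- net$edges
  reg <- e[e$type == "regulates", ]
  tar <- e[e$type == "targets", ]
  ppi <- e[e$type == "ppi", ]
  n <- 0L
  for (i in seq_len(nrow(reg))) for (j in seq_len(nrow(tar))) {
    if (reg$to[i] != tar$from[j]) next
    a <- reg$from[i]; b <- tar$to[j]
    if (a == b) next
    for (k in seq_len(nrow(ppi))) {
      if ((ppi$from[k] == a && ppi$to[k] == b) ||
          (ppi$from[k] == b && ppi$to[k] == a)) { n <- n + 1L; break }
    }
  }
  n
}

# random gene-only network (Erdos-Renyi ppi)
random_gene_network <- function(n, p = 0.25, cohort = "test") {
  genes <- sprintf("N%02d", seq_len(n))
  cmb <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(cmb)) < p
  edges <- if (any(keep)) {
    data.frame(from = cmb[1, keep], to = cmb[2, keep], type = "ppi",
               stringsAsFactors = FALSE)
  } else NULL
  regulatory_network(data.frame(id = genes, type = "gene",
                                stringsAsFactors = FALSE), edges, cohort)
}

# random composite network with miRNA nodes and all three edge types
random_composite_network <- function(n_genes = 8, n_mirna = 4, p = 0.3) {
  genes <- sprintf("N%02d", seq_len(n_genes))
  mirs <- sprintf("M%02d", seq_len(n_mirna))
  cmb <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(cmb)) < p
  edges <- list(if (any(keep)) data.frame(from = cmb[1, keep], to = cmb[2, keep],
                                          type = "ppi", stringsAsFactors = FALSE))
  for (m in mirs) {
    tg <- genes[stats::runif(n_genes) < p]
    rg <- genes[stats::runif(n_genes) < p / 2]
    if (length(tg)) edges <- c(edges, list(
      data.frame(from = m, to = tg, type = "targets", stringsAsFactors = FALSE)))
    if (length(rg)) edges <- c(edges, list(
      data.frame(from = rg, to = m, type = "regulates", stringsAsFactors = FALSE)))
  }
  regulatory_network(
    data.frame(id = c(genes, mirs),
               type = rep(c("gene", "mirna"), c(n_genes, n_mirna)),
               stringsAsFactors = FALSE),
    do.call(rbind, edges), "test")
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
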