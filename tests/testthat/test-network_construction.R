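ppi_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
}

test_that("induced network applies the one-hop rule", {
  ppi <- ppi_df("A", "B", "B", "C")
  n1 <- build_induced_network("A", ppi)
  expect_setequal(network_genes(n1), c("A", "B"))
  expect_equal(nrow(n1$edges), 1L)

  n2 <- build_induced_network(c("A", "C"), ppi)
  expect_setequal(network_genes(n2), c("A", "B", "C"))
  expect_equal(nrow(n2$edges), 2L)

  n3 <- build_induced_network("A", ppi_df(character(0)))
  expect_equal(network_genes(n3), "A")
  expect_equal(nrow(n3$edges), 0L)
  expect_error(build_induced_network(character(), ppi), "non-empty")
})

test_that("neighbor expansion matches brute force and is one-hop idempotent", {
  set.seed(7)
  for (i in 1:15) {
    genes <- sprintf("N%02d", 1:12)
    cmb <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(cmb)) < 0.2
    ppi <- data.frame(gene_a = cmb[1, keep], gene_b = cmb[2, keep])
    seeds <- sample(genes, sample(1:4, 1))
    net <- build_induced_network(seeds, ppi)
    # brute force: seeds plus any gene sharing an edge with a seed
    nb <- unique(c(seeds, ppi$gene_b[ppi$gene_a %in% seeds],
                   ppi$gene_a[ppi$gene_b %in% seeds]))
    expect_setequal(network_genes(net), nb)
    # re-running on the node set adds only second-hop neighbors
    net2 <- build_induced_network(network_genes(net), ppi)
    expect_true(all(network_genes(net) %in% network_genes(net2)))
    # depth-2 equals the two-pass expansion
    expect_setequal(network_genes(build_induced_network(seeds, ppi, depth = 2)),
                    network_genes(net2))
  }
})

test_that("GO filters retain annotated genes sequentially", {
  genes <- c("A", "B", "C", "D", "E", "F")
  net <- build_induced_network(genes, ppi_df("A", "B", "B", "C", "D", "E"))
  ann_all <- data.frame(gene_id = genes, go_term = "t",
                        go_category = "transcription")
  r <- apply_go_filters(net, ann_all, "transcription")
  expect_true(network_identical(r$network, net))
  expect_equal(r$trace$nodes, c(6L, 6L))

  r0 <- apply_go_filters(net, ann_all, "cell_cycle")
  expect_equal(length(network_genes(r0$network)), 0L)

  # hand-applied two-filter sequence on a toy net:
  # transcription: {A,B,C,D}; cell_cycle: {B,D,F} -> survivors {B,D}
  ann <- rbind(
    data.frame(gene_id = c("A", "B", "C", "D"), go_term = "t1",
               go_category = "transcription"),
    data.frame(gene_id = c("B", "D", "F"), go_term = "t2",
               go_category = "cell_cycle"))
  r2 <- apply_go_filters(net, ann, c("transcription", "cell_cycle"))
  expect_setequal(network_genes(r2$network), c("B", "D"))
  expect_error(apply_go_filters(net, ann, "mitochondrion"), "unknown")
})

test_that("filtering is monotone and its final set order-invariant", {
  set.seed(19)
  cats <- c("transcription", "cell_cycle", "cell_organization_biogenesis")
  for (i in 1:10) {
    net <- random_gene_network(sample(6:15, 1))
    genes <- network_genes(net)
    ann <- do.call(rbind, lapply(cats, function(cg) {
      g <- genes[stats::runif(length(genes)) < 0.6]
      if (!length(g)) return(NULL)
      data.frame(gene_id = g, go_term = paste0("t_", cg), go_category = cg,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ann)) next
    r <- apply_go_filters(net, ann, cats)
    expect_true(all(diff(r$trace$nodes) <= 0))
    expect_true(all(diff(r$trace$edges) <= 0))
    for (perm in list(cats[c(2, 1, 3)], cats[c(3, 2, 1)], cats[c(2, 3, 1)])) {
      expect_setequal(network_genes(apply_go_filters(net, ann, perm)$network),
                      network_genes(r$network))
    }
  }
})

test_that("miRNA overlay adds connected miRNAs and realizes TF-miRNA-TF paths", {
  net <- build_induced_network(c("T", "U"), ppi_df("T", "U"))
  targets <- data.frame(mirna_id = "M1", gene_id = "U", validated = TRUE)
  regulation <- data.frame(tf_id = "T", mirna_id = "M1", mode = "unknown")

  # rows not touching the network leave it unchanged
  far_t <- data.frame(mirna_id = "M9", gene_id = "X", validated = TRUE)
  far_r <- data.frame(tf_id = "Y", mirna_id = "M9", mode = "unknown")
  expect_true(network_identical(
    overlay_regulation(net, far_r, far_t, "M9"), net))

  comp <- overlay_regulation(net, regulation, targets, "M1")
  expect_setequal(network_mirnas(comp), "M1")
  # path T -> M1 -> U present as regulates + targets edges
  expect_true(any(comp$edges$type == "regulates" & comp$edges$from == "T" &
                  comp$edges$to == "M1"))
  expect_true(any(comp$edges$type == "targets" & comp$edges$from == "M1" &
                  comp$edges$to == "U"))
  # genes never removed
  expect_setequal(network_genes(comp), c("T", "U"))
  # miRNAs outside the cohort list are ignored
  expect_true(network_identical(
    overlay_regulation(net, regulation, targets, "M2"), net))
})

test_that("feed-forward loop counting matches exhaustive enumeration", {
  tri <- regulatory_network(
    data.frame(id = c("A", "B", "M"), type = c("gene", "gene", "mirna")),
    rbind(data.frame(from = "A", to = "M", type = "regulates"),
          data.frame(from = "M", to = "B", type = "targets"),
          data.frame(from = "A", to = "B", type = "ppi")))
  expect_equal(count_feedforward_loops(tri), 1L)
  no_ppi <- regulatory_network(tri$nodes, tri$edges[tri$edges$type != "ppi", ])
  expect_equal(count_feedforward_loops(no_ppi), 0L)

  set.seed(13)
  for (i in 1:12) {
    net <- random_composite_network(n_genes = sample(5:10, 1),
                                    n_mirna = sample(2:5, 1))
    expect_equal(count_feedforward_loops(net), oracle_ffl(net))
  }
})
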