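edgeless <- function(genes, cohort = "x") {
  regulatory_network(data.frame(id = genes, type = rep("gene", length(genes)),
                                stringsAsFactors = FALSE), cohort = cohort)
}

test_that("classification reproduces the published six groups", {
  nets <- table1_networks()
  cl <- classify_genes(nets$NSCLC, nets$SCLC, nets$common)
  expect_setequal(cl$NSCLC_specific, c("E2F6", "TFDP1", "SUV39H1", "HNRPD"))
  expect_setequal(cl$general_specific, c("RBL1", "IRF1", "HMGA1"))
  expect_equal(length(cl$common_SCLC_NSCLC), 9L)
  expect_equal(length(cl$common_NSCLC_general), 14L)
  # the published containment case: groups 1-3 coincide
  expect_equal(cl$unique_SCLC, cl$common_all)
})

test_that("classification degenerate cases", {
  a <- edgeless(c("A", "B", "C"))
  cl_same <- classify_genes(a, a, a)
  expect_setequal(cl_same$common_all, c("A", "B", "C"))
  expect_equal(length(cl_same$NSCLC_specific), 0L)
  expect_equal(length(cl_same$general_specific), 0L)
  expect_equal(length(cl_same$common_NSCLC_general), 0L)

  cl_dis <- classify_genes(edgeless(c("A1", "A2")), edgeless("B1"),
                           edgeless("C1"))
  expect_setequal(cl_dis$NSCLC_specific, c("A1", "A2"))
  expect_equal(cl_dis$unique_SCLC, "B1")
  expect_equal(cl_dis$general_specific, "C1")
  expect_equal(length(cl_dis$common_SCLC_NSCLC), 0L)
})

test_that("the six groups exactly reassemble the input networks", {
  set.seed(5)
  pool <- sprintf("G%02d", 1:20)
  for (i in 1:25) {
    A <- sample(pool, sample(1:15, 1))
    B <- sample(pool, sample(1:15, 1))
    C <- sample(pool, sample(1:15, 1))
    cl <- classify_genes(edgeless(A), edgeless(B), edgeless(C))
    # union of all groups covers exactly A | B | C
    expect_setequal(unique(unlist(cl)), union(A, union(B, C)))
    # per-network reassembly
    expect_setequal(union(cl$common_SCLC_NSCLC,
                          union(cl$common_NSCLC_general, cl$NSCLC_specific)),
                    A)
    expect_setequal(cl$unique_SCLC, B)
    # groups 4-6 are pairwise disjoint and disjoint from group 1
    expect_equal(length(intersect(cl$common_NSCLC_general, cl$NSCLC_specific)), 0L)
    expect_equal(length(intersect(cl$NSCLC_specific, cl$general_specific)), 0L)
    expect_equal(length(intersect(cl$unique_SCLC, cl$NSCLC_specific)), 0L)
    expect_equal(length(intersect(cl$unique_SCLC, cl$general_specific)), 0L)
  }
})

test_that("containment check reports witnesses", {
  nets <- table1_networks()
  expect_true(containment_check(nets$SCLC, nets$NSCLC)$contained)

  fake <- edgeless(c(network_genes(nets$SCLC), "NOTAGENE"))
  cc <- containment_check(fake, nets$NSCLC)
  expect_false(cc$contained)
  expect_equal(cc$witness, "NOTAGENE")
  expect_true(containment_check(edgeless(character()), nets$NSCLC)$contained)
})

test_that("key nodes follow degree with boundary ties", {
  star <- regulatory_network(
    data.frame(id = c("H", "L1", "L2", "L3"), type = "gene"),
    data.frame(from = "H", to = c("L1", "L2", "L3"), type = "ppi"))
  expect_equal(key_nodes(star, top = 1L), "H")

  ring <- regulatory_network(
    data.frame(id = c("A", "B", "C"), type = "gene"),
    data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"), type = "ppi"))
  expect_setequal(key_nodes(ring, top = 1L), c("A", "B", "C"))  # full tie class

  expect_error(key_nodes(star, top = 0), "config error")

  set.seed(31)
  for (i in 1:15) {
    net <- random_gene_network(sample(8:20, 1))
    k <- sample(1:5, 1)
    expect_equal(key_nodes(net, top = k), oracle_key_nodes(net, k))
  }
})

test_that("shortest-path membership matches exhaustive path enumeration", {
  path3 <- regulatory_network(
    data.frame(id = c("A", "B", "C"), type = "gene"),
    data.frame(from = c("A", "B"), to = c("B", "C"), type = "ppi"))
  expect_equal(shortest_path_members(path3, c("A", "C")), c("A", "B", "C"))

  two_comp <- regulatory_network(
    data.frame(id = c("A", "B", "C", "D"), type = "gene"),
    data.frame(from = c("A", "C"), to = c("B", "D"), type = "ppi"))
  expect_equal(shortest_path_members(two_comp, c("A", "C")), c("A", "C"))

  expect_error(shortest_path_members(path3, "A"), "two endpoints")
  expect_error(shortest_path_members(path3, c("A", "Z")), "outside")

  set.seed(17)
  for (i in 1:12) {
    net <- random_gene_network(sample(6:12, 1), p = 0.25)
    eps <- sample(network_genes(net), sample(2:4, 1))
    expect_equal(shortest_path_members(net, eps),
                 oracle_shortest_members(net, eps))
  }
})

test_that("enrichment ranking scores by best disease-set q-value", {
  net <- edgeless(c("A", "B", "C", "D"))
  uni <- c(network_genes(net), sprintf("U%02d", 1:16))
  # gene in no disease set is unranked and excluded
  ds <- list(d1 = c("A", "B"))
  er <- enrichment_rank_genes(net, ds, uni)
  expect_setequal(er$genes, c("A", "B"))
  expect_false("C" %in% er$ranks$gene)

  # single disease set equal to the network genes: all tie at rank 1
  er2 <- enrichment_rank_genes(net, list(all = network_genes(net)), uni)
  expect_equal(unique(er2$ranks$rank), 1L)
  expect_setequal(er2$genes, network_genes(net))

  expect_error(enrichment_rank_genes(net, list(), uni), "non-empty")
})

test_that("marker calling intersects the three strategies", {
  nets <- table1_networks()
  cl <- classify_genes(nets$NSCLC, nets$SCLC, nets$common)
  uni <- unique(c(network_genes(nets$NSCLC), network_genes(nets$common)))
  ds <- list(lung = uni)
  sc <- rbind(strategy_scores(nets$NSCLC, ds, uni, top = 1.0),
              strategy_scores(nets$common, ds, uni, top = 1.0))
  panel <- call_markers(sc, cl)
  expect_equal(nrow(panel), 7L)
  expect_setequal(panel$gene_id,
                  c("E2F6", "TFDP1", "SUV39H1", "HNRPD",
                    "RBL1", "IRF1", "HMGA1"))
  expect_setequal(unique(panel$cohort_origin),
                  c("NSCLC_specific", "general_specific"))

  # one strategy empty under the intersection policy empties the panel
  sc_no_rank <- sc
  sc_no_rank$enrichment_rank <- NA_integer_
  expect_equal(nrow(call_markers(sc_no_rank, cl)), 0L)

  # majority policy is at least as permissive as intersection
  p_major <- call_markers(sc_no_rank, cl, policy = "majority")
  expect_true(all(call_markers(sc_no_rank, cl)$gene_id %in% p_major$gene_id))
  expect_equal(nrow(p_major), 7L)  # two of three strategies still flagged
})
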