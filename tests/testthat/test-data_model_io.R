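test_that("association reader merges duplicates and derives conflicts", {
  f <- write_lines_tmp(c("mirna_id\tsubtype\tdirection\tsource",
                         "miR-a\tNSCLC\tup\ts1",
                         "miR-a\tSCLC\tdown\ts2",
                         "miR-b\tNSCLC\tup\ts3"))
  a <- read_association_table(f)
  expect_equal(length(unique(a$mirna_id)), 2L)
  # miR-a carries both subtypes with opposite directions: classified
  # differential downstream
  p <- partition_mirnas(a)
  expect_equal(p$common, "MIR-A")
  expect_equal(p$tallies$common$differential, 1L)

  # within-cohort conflicting reports merge to direction "conflict"
  f2 <- write_lines_tmp(c("mirna_id\tsubtype\tdirection\tsource",
                          "miR-c\tNSCLC\tup\ts1",
                          "miR-c\tNSCLC\tdown\ts2"))
  a2 <- read_association_table(f2)
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$direction, "conflict")
  expect_match(a2$source, "s1; s2")
})

test_that("association reader contracts: empty file, bad tokens", {
  f <- write_lines_tmp("mirna_id\tsubtype\tdirection\tsource")
  expect_equal(nrow(read_association_table(f)), 0L)

  f2 <- write_lines_tmp(c("mirna_id\tsubtype\tdirection\tsource",
                          "miR-a\tLUAD\tup\ts1"))
  expect_error(read_association_table(f2), "line 2.*LUAD")

  f3 <- write_lines_tmp(c("mirna_id\tsubtype\tdirection\tsource",
                          "miR-a\tNSCLC\tup\ts1",
                          "miR-b\tSCLC\tsideways\ts1"))
  expect_error(read_association_table(f3), "line 3.*sideways")

  f4 <- write_lines_tmp(c("mirna_id\tsubtype\tsource", "miR-a\tNSCLC\ts1"))
  expect_error(read_association_table(f4), "direction")
})

test_that("GMT reader de-duplicates, rejects malformed input", {
  f <- write_lines_tmp("s1\tdesc\tA\tB\tB")
  expect_equal(read_gmt(f), list(s1 = c("A", "B")))

  f2 <- write_lines_tmp(c("s1\tdesc\tA", "s1\tdesc\tB"))
  expect_error(read_gmt(f2), "line 2.*duplicate")

  f3 <- write_lines_tmp(c("s1\tdesc\tA", "bad\tline"))
  expect_error(read_gmt(f3), "line 2")
})

test_that("packaged marker-table fixture has the published group sizes", {
  g <- table1_gene_groups()
  expect_named(g, c("group1_unique_SCLC", "group2_common_SCLC_NSCLC",
                    "group3_common_all", "group4_common_NSCLC_general",
                    "group5_NSCLC_specific", "group6_general_specific"))
  expect_equal(unname(vapply(g, length, integer(1))), c(9L, 9L, 9L, 14L, 4L, 3L))
  # groups 1-3 are printed as the identical nine-gene set
  expect_setequal(g$group1_unique_SCLC, g$group3_common_all)
})

test_that("SIF writer canonicalizes ppi edges and handles empty nets", {
  net <- regulatory_network(
    data.frame(id = c("B", "A", "Z"), type = "gene"),
    data.frame(from = "B", to = "A", type = "ppi"))
  f <- tempfile()
  write_network_sif(net, f)
  lines <- readLines(f)
  expect_equal(lines, c("A\tppi\tB", "Z"))

  f2 <- tempfile()
  write_network_sif(regulatory_network(data.frame(id = character(),
                                                  type = character())), f2)
  expect_equal(file.size(f2), 0)
})

test_that("reader/writer pairs round-trip random small instances", {
  set.seed(42)
  for (i in 1:10) {
    net <- random_composite_network(n_genes = sample(3:8, 1),
                                    n_mirna = sample(0:3, 1))
    f <- tempfile()
    write_network_sif(net, f)
    back <- read_network_sif(f, cohort = "test")
    expect_true(network_identical(net, back))
  }
  # tabular round-trips
  b <- generate_bundle(synthetic_config(seed = 5))
  d <- tempfile()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_equal(sort(unique(r$association$mirna_id)),
               sort(unique(b$association$mirna_id)))
  expect_equal(r$targets[order(r$targets$mirna_id, r$targets$gene_id),
                         c("mirna_id", "gene_id")],
               b$targets[order(b$targets$mirna_id, b$targets$gene_id),
                         c("mirna_id", "gene_id")],
               ignore_attr = TRUE)
  expect_equal(r$ppi, b$ppi)
  expect_equal(r$regulation, b$regulation)
  expect_equal(r$disease_sets, b$disease_sets)
})

test_that("table readers normalize and validate", {
  f <- write_lines_tmp(c("mirna_id\tgene_id", "m1\t tp53 ", "m1\tTP53"))
  tt <- read_target_table(f)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$gene_id, "TP53")
  expect_true(tt$validated)

  f2 <- write_lines_tmp(c("gene_a\tgene_b", "B\tA", "A\tB", "A\tA"))
  ppi <- read_ppi_table(f2)
  expect_equal(ppi, data.frame(gene_a = "A", gene_b = "B"))

  f3 <- write_lines_tmp(c("gene_id\tgo_term", "g1\tGO:1", "g1\tGO:2"))
  ann <- read_annotation_table(f3, category_map = c("GO:1" = "cell_cycle"))
  expect_equal(ann$go_category, c("cell_cycle", "other"))

  f4 <- write_lines_tmp(c("tf_id\tmirna_id\tmode", "X\tX\tunknown"))
  expect_error(read_regulation_table(f4), "namespaces overlap")
})

test_that("regulatory_network enforces its invariants", {
  expect_error(regulatory_network(
    data.frame(id = c("A", "A"), type = "gene")), "duplicate")
  expect_error(regulatory_network(
    data.frame(id = "A", type = "gene"),
    data.frame(from = "A", to = "B", type = "ppi")), "endpoint")
  # ppi canonicalization merges the two orientations
  net <- regulatory_network(
    data.frame(id = c("A", "B"), type = "gene"),
    data.frame(from = c("B", "A"), to = c("A", "B"), type = "ppi"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "A")
})
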