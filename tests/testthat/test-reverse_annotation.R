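test_that("hypergeometric p-values match hand-derived cases", {
  uni <- sprintf("g%02d", 1:10)
  term <- list(t1 = uni[1:4])
  query <- c(uni[1:3], uni[9:10])  # overlap 3 of term size 4, query 5
  r <- hypergeom_enrich(query, term, uni)
  expect_equal(r$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(r$overlap, 3L)

  # query = universe: every overlap is the whole term, p = 1
  r2 <- hypergeom_enrich(uni, list(a = uni[1:4], b = uni[5:6]), uni)
  expect_equal(r2$overlap, r2$term_size)
  expect_equal(r2$p_value, c(1, 1))

  # zero overlap: upper tail includes X = 0, p = 1
  r3 <- hypergeom_enrich(uni[9:10], list(t = uni[1:4]), uni)
  expect_equal(r3$p_value, 1)

  expect_error(hypergeom_enrich("g", list(t = "g"), character()), "universe")
  expect_equal(nrow(hypergeom_enrich(character(), term, uni)), 0L)
})

test_that("p-values equal the enumeration oracle on all small universes", {
  set.seed(21)
  for (i in 1:60) {
    N <- sample(4:25, 1)
    uni <- sprintf("u%02d", seq_len(N))
    term_sets <- lapply(seq_len(sample(1:4, 1)), function(j)
      sample(uni, sample(1:N, 1)))
    names(term_sets) <- paste0("t", seq_along(term_sets))
    query <- sample(uni, sample(1:N, 1))
    r <- hypergeom_enrich(query, term_sets, uni)
    for (j in seq_len(nrow(r))) {
      expected <- oracle_hypergeom_upper(r$overlap[j], r$term_size[j],
                                         r$universe_size[j], r$query_size[j])
      expect_equal(r$p_value[j], expected, tolerance = 1e-12)
    }
    # BH q-values are monotone non-decreasing in p-rank
    expect_true(all(diff(r$q_value[order(r$p_value)]) >= -1e-15))
    # ranks dense and ordered
    expect_equal(r$rank, seq_len(nrow(r)))
  }
})

test_that("annotate_mirna assigns the shared term top rank", {
  uni <- sprintf("g%03d", 1:20)
  targets <- data.frame(mirna_id = "MIR-1", gene_id = uni[1:5],
                        validated = TRUE)
  ann <- rbind(
    data.frame(gene_id = uni[1:5], go_term = "GO:SHARED",
               go_category = "cell_cycle"),
    data.frame(gene_id = uni[c(1, 6:12)], go_term = "GO:BROAD",
               go_category = "other"))
  a <- annotate_mirna("MIR-1", targets, ann, uni)
  expect_equal(a$go_profile$term[1], "GO:SHARED")
  expect_equal(a$go_profile$rank[1], 1L)
  # oracle check of the top p-value at this reduced universe
  expect_equal(a$go_profile$p_value[1],
               oracle_hypergeom_upper(5, 5, 20, 5), tolerance = 1e-12)
  expect_true(a$retained)

  # a miRNA annotated only to "other" is not retained by default
  t2 <- data.frame(mirna_id = "MIR-2", gene_id = uni[6], validated = TRUE)
  a2 <- annotate_mirna("MIR-2", t2, ann, uni)
  expect_false(a2$retained)

  # identical target sets give identical profiles
  t3 <- rbind(targets, data.frame(mirna_id = "MIR-3", gene_id = uni[1:5],
                                  validated = TRUE))
  a3 <- annotate_mirna("MIR-3", t3, ann, uni)
  expect_equal(a$go_profile, a3$go_profile)

  expect_error(annotate_mirna("MIR-NONE", targets, ann, uni), "MIR-NONE")
})

test_that("filter_cohort_mirnas pools targets of retained miRNAs only", {
  uni <- sprintf("g%03d", 1:20)
  ann <- rbind(
    data.frame(gene_id = uni[1:5], go_term = "GO:CC", go_category = "cell_cycle"),
    data.frame(gene_id = uni[6:20], go_term = "GO:OTH", go_category = "other"))
  targets <- rbind(
    data.frame(mirna_id = "MIR-1", gene_id = uni[1:5], validated = TRUE),
    data.frame(mirna_id = "MIR-2", gene_id = uni[6:8], validated = TRUE))
  annotated <- annotate_mirnas(c("MIR-1", "MIR-2"), targets, ann, uni)
  fc <- filter_cohort_mirnas(annotated)
  expect_equal(fc$retained, "MIR-1", ignore_attr = TRUE)
  expect_equal(fc$pooled_targets, sort(uni[1:5]))

  # nothing retained -> empty pool; everything retained -> full union
  fc0 <- filter_cohort_mirnas(annotated, whitelist = "transcription")
  expect_equal(fc0$pooled_targets, character())
  fc1 <- filter_cohort_mirnas(annotated, whitelist = go_categories(), alpha = 1)
  expect_equal(fc1$pooled_targets, sort(uni[1:8]))
  expect_error(filter_cohort_mirnas(annotated, character()), "non-empty")
})

test_that("adding a term-less universe gene preserves term ordering", {
  set.seed(33)
  uni <- sprintf("u%02d", 1:15)
  term_sets <- list(t1 = uni[1:5], t2 = uni[3:10], t3 = uni[c(1, 11:14)])
  query <- uni[c(1:4, 11)]
  r1 <- hypergeom_enrich(query, term_sets, uni)
  r2 <- hypergeom_enrich(query, term_sets, c(uni, "EXTRA"))
  expect_equal(r1$term, r2$term)  # rank ordering among terms unchanged
})
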