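# Reverse annotation: GO terms are assigned to a miRNA from the annotation
# of its validated targets, scored by upper-tail hypergeometric enrichment
# with Benjamini-Hochberg control. This transparent statistic stands in for
# the web-service prioritization tools the original workflow relied on.

#' Upper-tail hypergeometric gene-set enrichment
#'
#' For each term set, tests whether the query over-represents the term in
#' the universe: the p-value is \eqn{P(X \ge k)} for a hypergeometric draw
#' of \code{query_size} genes from a universe containing \code{term_size}
#' term genes, where \code{k} is the observed overlap. Term sets are
#' intersected with the universe before testing; q-values are
#' Benjamini-Hochberg over all tested terms.
#'
#' @param query character vector, a gene set (must lie inside
#'   \code{universe}).
#' @param term_sets named list of character vectors (term -> genes).
#' @param universe character vector, the gene universe.
#' @param alpha significance level used to flag results (default 0.05).
#' @return data.frame of class \code{enrichment_result} with columns
#'   \code{term}, \code{overlap}, \code{term_size}, \code{query_size},
#'   \code{universe_size}, \code{p_value}, \code{q_value}, \code{rank},
#'   \code{significant}; rows ordered by rank (ascending p, ties broken by
#'   term id). Empty query gives zero rows.
#' @export
hypergeom_enrich <- function(query, term_sets, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query genes outside the universe: ", paste(outside, collapse = ", "))
  }
  empty <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), rank = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (length(query) == 0L || length(term_sets) == 0L) return(empty)

  N <- length(universe)
  n <- length(query)
  res <- lapply(names(term_sets), function(tm) {
    ts <- intersect(unique(as.character(term_sets[[tm]])), universe)
    m <- length(ts)
    k <- length(intersect(ts, query))
    # P(X >= k); phyper is P(X <= q), so use k - 1 on the upper tail
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = m, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$q_value <= alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Annotate one miRNA from its validated targets
#'
#' Collects the miRNA's validated target genes, builds term sets from the
#' flat gene-to-GO annotation table, and runs
#' \code{\link{hypergeom_enrich}} with the target set as query. The miRNA
#' is \code{retained} when at least one term from a whitelisted GO category
#' is significant at \code{alpha} after BH correction.
#'
#' @param mirna_id miRNA identifier.
#' @param target_table data.frame of miRNA-target edges (see
#'   \code{\link{read_target_table}}).
#' @param annotations data.frame of gene-GO annotations (see
#'   \code{\link{read_annotation_table}}).
#' @param universe gene universe for the test.
#' @param alpha BH significance level (default 0.05).
#' @param whitelist GO categories counting towards retention (default
#'   \code{\link{default_whitelist}}).
#' @return object of class \code{annotated_mirna}: list with
#'   \code{mirna_id}, \code{targets}, \code{go_profile} (an
#'   \code{enrichment_result} with an extra \code{go_category} column) and
#'   \code{retained}.
#' @export
annotate_mirna <- function(mirna_id, target_table, annotations, universe,
                           alpha = 0.05, whitelist = default_whitelist()) {
  mirna_id <- normalize_id(mirna_id)
  tt <- target_table[target_table$mirna_id == mirna_id & target_table$validated, ,
                     drop = FALSE]
  if (nrow(tt) == 0L) {
    stop("miRNA has no validated target in the table: ", mirna_id)
  }
  universe <- unique(as.character(universe))
  targets <- sort(intersect(unique(tt$gene_id), universe))
  term_sets <- split(annotations$gene_id, annotations$go_term)
  # only terms annotating at least one target can appear in the profile
  has_target <- vapply(term_sets, function(g) any(g %in% targets), logical(1))
  prof <- hypergeom_enrich(targets, term_sets[has_target], universe, alpha)
  term_cat <- annotations$go_category[!duplicated(annotations$go_term)]
  names(term_cat) <- annotations$go_term[!duplicated(annotations$go_term)]
  prof$go_category <- if (nrow(prof)) unname(term_cat[prof$term]) else character()
  retained <- any(prof$significant & prof$go_category %in% whitelist)
  structure(list(mirna_id = mirna_id, targets = targets, go_profile = prof,
                 retained = retained),
            class = "annotated_mirna")
}

#' @export
print.annotated_mirna <- function(x, ...) {
  cat(sprintf("<annotated_mirna> %s: %d targets, %d terms, retained=%s\n",
              x$mirna_id, length(x$targets), nrow(x$go_profile), x$retained))
  invisible(x)
}

#' Annotate a set of miRNAs
#'
#' Convenience wrapper running \code{\link{annotate_mirna}} over each miRNA
#' (skipping miRNAs with no validated target, which cannot be annotated).
#'
#' @param mirna_ids character vector of miRNA ids.
#' @inheritParams annotate_mirna
#' @return named list of \code{annotated_mirna} objects.
#' @export
annotate_mirnas <- function(mirna_ids, target_table, annotations, universe,
                            alpha = 0.05, whitelist = default_whitelist()) {
  mirna_ids <- normalize_id(mirna_ids)
  with_targets <- intersect(mirna_ids,
                            unique(target_table$mirna_id[target_table$validated]))
  out <- lapply(with_targets, annotate_mirna, target_table = target_table,
                annotations = annotations, universe = universe,
                alpha = alpha, whitelist = whitelist)
  stats::setNames(out, with_targets)
}

#' Retain whitelisted miRNAs and pool their targets
#'
#' Keeps the miRNAs whose GO profile contains at least one significant term
#' from a whitelisted category, and pools the target genes of the retained
#' miRNAs only; non-retained miRNAs and their targets are ignored.
#'
#' @param annotated list of \code{annotated_mirna} objects.
#' @param whitelist non-empty set of GO categories.
#' @param alpha significance level applied to the stored q-values.
#' @return list with \code{retained} (character vector of miRNA ids) and
#'   \code{pooled_targets} (sorted character vector).
#' @export
filter_cohort_mirnas <- function(annotated, whitelist = default_whitelist(),
                                 alpha = 0.05) {
  if (length(whitelist) == 0L) stop("whitelist must be non-empty")
  keep <- vapply(annotated, function(a) {
    prof <- a$go_profile
    any(prof$q_value <= alpha & prof$go_category %in% whitelist)
  }, logical(1))
  kept <- annotated[keep]
  pooled <- sort(unique(unlist(lapply(kept, `[[`, "targets"), use.names = FALSE)))
  list(retained = vapply(kept, `[[`, character(1), "mirna_id"),
       pooled_targets = if (is.null(pooled)) character() else pooled)
}
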