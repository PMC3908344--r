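# Packaged fixtures: the printed six-group marker table and an association
# table encoding the printed per-subtype miRNA totals. Both are small
# plain-text files under extdata with typed accessors here.

#' Path to a packaged fixture file
#'
#' @param file file name under the package's \code{extdata} directory.
#' @return absolute path.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mirtfnet", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' The published six-group marker gene sets
#'
#' Loads the packaged GMT of the six gene groups from the lung-cancer
#' marker table: groups 1-3 are the identical nine-gene set reported as
#' unique-to-SCLC / shared SCLC-NSCLC / shared by all three networks;
#' group 4 the fourteen genes shared by NSCLC and the general path; group
#' 5 the four NSCLC-specific genes; group 6 the three general-path-specific
#' genes.
#'
#' @return named list of six gene sets (sizes 9, 9, 9, 14, 4, 3).
#' @export
table1_gene_groups <- function() {
  read_gmt(fixture_path("table1_groups.gmt"))
}

#' Cohort networks reconstructed from the published gene groups
#'
#' Rebuilds the three final cohort gene sets from the six groups: the
#' NSCLC network is groups 2, 4 and 5 (27 genes), the SCLC network group 1
#' (9 genes), the common network groups 3, 4 and 6 (26 genes). The
#' published table records memberships, not edges, so the fixture networks
#' are edgeless; they are sufficient for the set-algebra comparison and
#' containment stages.
#'
#' @return named list of three \code{\link{regulatory_network}} objects:
#'   \code{NSCLC}, \code{SCLC}, \code{common}.
#' @export
table1_networks <- function() {
  g <- table1_gene_groups()
  mk <- function(genes, cohort) {
    regulatory_network(data.frame(id = sort(unique(genes)), type = "gene",
                                  stringsAsFactors = FALSE),
                       cohort = cohort)
  }
  list(
    NSCLC = mk(c(g$group2_common_SCLC_NSCLC, g$group4_common_NSCLC_general,
                 g$group5_NSCLC_specific), "NSCLC"),
    SCLC = mk(g$group1_unique_SCLC, "SCLC"),
    common = mk(c(g$group3_common_all, g$group4_common_NSCLC_general,
                  g$group6_general_specific), "common"))
}

#' The packaged lung-cancer miRNA association fixture
#'
#' An association table encoding the printed per-subtype totals: 184
#' NSCLC-associated and 62 SCLC-associated miRNAs, 41 of them shared, so
#' 143 NSCLC-unique and 21 SCLC-unique by set arithmetic. Direction labels
#' follow the printed tallies where they fit (89 up / 43 down NSCLC-unique
#' with 11 conflicting double-reports; 16 up / 5 down SCLC-unique; 13
#' concordant-up / 11 concordant-down / 17 differential shared).
#'
#' @return a \code{mirna_associations} data.frame.
#' @export
lung_association_fixture <- function() {
  read_association_table(fixture_path("lung_mirna_associations.tsv"))
}
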