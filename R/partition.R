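# Cohort partition of the miRNA association table: subtype-unique and
# shared miRNA sets with up/down/differential/conflict tallies.

#' Partition miRNAs into cohort-unique and common sets
#'
#' Splits the miRNA universe of an association table into the miRNAs unique
#' to each of two cohorts and those associated with both. For the common
#' set, a miRNA whose two per-cohort directions are opposite (up in one
#' subtype, down in the other) is tallied \code{differential}; one carrying
#' a within-cohort \code{conflict} direction is tallied \code{conflict} and
#' counted in neither the up nor the down tally.
#'
#' @param associations a \code{mirna_associations} data.frame (see
#'   \code{\link{read_association_table}}).
#' @param cohorts length-2 character vector naming cohort A and cohort B.
#' @return object of class \code{partition_result}: a list with elements
#'   \code{cohorts}, \code{unique_A}, \code{unique_B}, \code{common}
#'   (sorted id vectors) and \code{tallies} (named list of direction
#'   counts per set).
#' @export
partition_mirnas <- function(associations, cohorts = c("NSCLC", "SCLC")) {
  assoc <- as.data.frame(associations)
  if (nrow(assoc) == 0L) stop("record error: association table is empty")
  if (length(cohorts) != 2L) stop("exactly two cohorts are required")
  extra <- setdiff(unique(assoc$subtype), cohorts)
  if (length(extra)) stop("unknown cohort label(s): ", paste(extra, collapse = ", "))
  if (any(!nzchar(assoc$subtype))) stop("record error: association with empty subtype")

  in_a <- unique(assoc$mirna_id[assoc$subtype == cohorts[1]])
  in_b <- unique(assoc$mirna_id[assoc$subtype == cohorts[2]])
  common <- sort(intersect(in_a, in_b))
  unique_a <- sort(setdiff(in_a, common))
  unique_b <- sort(setdiff(in_b, common))

  dir_of <- function(ids, cohort) {
    m <- assoc[assoc$subtype == cohort, ]
    stats::setNames(m$direction, m$mirna_id)[ids]
  }
  tally_unique <- function(ids, cohort) {
    d <- dir_of(ids, cohort)
    list(count = length(ids),
         up = sum(d == "up"), down = sum(d == "down"),
         conflict = sum(d == "conflict"))
  }
  da <- dir_of(common, cohorts[1])
  db <- dir_of(common, cohorts[2])
  common_class <- ifelse(da == "conflict" | db == "conflict", "conflict",
                         ifelse(da == db, da, "differential"))
  tallies <- list(
    unique_A = tally_unique(unique_a, cohorts[1]),
    unique_B = tally_unique(unique_b, cohorts[2]),
    common = list(count = length(common),
                  up = sum(common_class == "up"),
                  down = sum(common_class == "down"),
                  differential = sum(common_class == "differential"),
                  conflict = sum(common_class == "conflict"))
  )
  structure(list(cohorts = cohorts, unique_A = unique_a, unique_B = unique_b,
                 common = common, tallies = tallies),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %s-unique: %d, %s-unique: %d, common: %d (total %d)\n",
              x$cohorts[1], length(x$unique_A), x$cohorts[2], length(x$unique_B),
              length(x$common),
              length(x$unique_A) + length(x$unique_B) + length(x$common)))
  invisible(x)
}

#' Machine-readable partition report
#'
#' Cross-checks the inclusion-exclusion identity (|unique A| + |unique B| +
#' |common| equals the number of distinct miRNAs) and returns a list that
#' serializes to JSON.
#'
#' @param result a \code{partition_result}.
#' @return list with per-set counts and direction tallies, the distinct
#'   miRNA total, and the cohort labels.
#' @export
partition_report <- function(result) {
  stopifnot(inherits(result, "partition_result"))
  total <- length(result$unique_A) + length(result$unique_B) + length(result$common)
  rep <- list(
    cohorts = result$cohorts,
    unique_A = c(list(cohort = result$cohorts[1]), result$tallies$unique_A),
    unique_B = c(list(cohort = result$cohorts[2]), result$tallies$unique_B),
    common = result$tallies$common,
    total = total
  )
  # internal consistency cross-check
  stopifnot(rep$unique_A$count == length(result$unique_A),
            rep$common$count == length(result$common))
  rep
}
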