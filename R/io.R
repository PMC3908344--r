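# Readers/writers for the flat formats the pipeline touches: TSV tables
# (header row required), GMT gene sets, SIF networks. All UTF-8, LF endings.

read_tsv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("format error in %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}

# ---------------------------------------------------------------------------
# miRNA-disease association table
# ---------------------------------------------------------------------------

#' Read a miRNA-disease association table
#'
#' Expects a TSV with header columns \code{mirna_id}, \code{subtype},
#' \code{direction}, \code{source}. One row records that a miRNA is
#' deregulated (\code{up} or \code{down}) in one disease subtype. Duplicate
#' (miRNA, subtype) rows are merged; if their directions disagree the merged
#' direction is \code{"conflict"} (reported up in one study, down in
#' another, within the same subtype) and such miRNAs are excluded from the
#' up/down tallies downstream.
#'
#' @param path TSV file path.
#' @param cohorts allowed subtype labels (default \code{c("NSCLC","SCLC")}).
#' @return data.frame of class \code{mirna_associations} with one row per
#'   (miRNA, subtype): columns \code{mirna_id}, \code{subtype},
#'   \code{direction} (\code{up}/\code{down}/\code{conflict}),
#'   \code{source}.
#' @export
read_association_table <- function(path, cohorts = c("NSCLC", "SCLC")) {
  df <- read_tsv_checked(path, c("mirna_id", "subtype", "direction", "source"))
  df$mirna_id <- normalize_id(df$mirna_id)
  df$subtype <- toupper(trimws(df$subtype))
  df$direction <- tolower(trimws(df$direction))
  lines <- seq_len(nrow(df)) + 1L  # +1 for the header row
  bad <- !(df$subtype %in% cohorts)
  if (any(bad)) {
    stop(sprintf("record error at line %d: unknown subtype '%s'",
                 lines[which(bad)[1]], df$subtype[which(bad)[1]]))
  }
  bad <- !(df$direction %in% c("up", "down"))
  if (any(bad)) {
    stop(sprintf("record error at line %d: unknown direction '%s'",
                 lines[which(bad)[1]], df$direction[which(bad)[1]]))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(mirna_id = character(), subtype = character(),
                      direction = character(), source = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mirna_associations", "data.frame")
    return(out)
  }
  key <- paste(df$mirna_id, df$subtype, sep = "\r")
  merged <- lapply(split(seq_len(nrow(df)), key), function(i) {
    dirs <- unique(df$direction[i])
    data.frame(mirna_id = df$mirna_id[i[1]], subtype = df$subtype[i[1]],
               direction = if (length(dirs) == 1L) dirs else "conflict",
               source = paste(unique(df$source[i]), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$mirna_id, out$subtype), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mirna_associations", "data.frame")
  out
}

#' Write a miRNA-disease association table
#'
#' @param assoc data.frame with columns \code{mirna_id}, \code{subtype},
#'   \code{direction}, \code{source}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_association_table <- function(assoc, path) {
  write_tsv(as.data.frame(assoc)[, c("mirna_id", "subtype", "direction", "source")], path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# miRNA -> target edges
# ---------------------------------------------------------------------------

#' Read a miRNA-to-target edge table
#'
#' TSV with header columns \code{mirna_id}, \code{gene_id} and an optional
#' \code{validated} column (\code{TRUE}/\code{FALSE}; missing column means
#' all edges are treated as validated). Duplicate (miRNA, gene) pairs are
#' collapsed, a pair counting as validated if any of its rows is.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{validated}.
#' @export
read_target_table <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "gene_id"), "validated")
  df$mirna_id <- normalize_id(df$mirna_id)
  df$gene_id <- normalize_id(df$gene_id)
  df$validated <- if ("validated" %in% names(df)) {
    toupper(trimws(df$validated)) %in% c("TRUE", "T", "1", "YES")
  } else TRUE
  if (nrow(df)) {
    key <- paste(df$mirna_id, df$gene_id, sep = "\r")
    val <- tapply(df$validated, key, any)
    df <- df[!duplicated(key), , drop = FALSE]
    df$validated <- as.logical(val[paste(df$mirna_id, df$gene_id, sep = "\r")])
    df <- df[order(df$mirna_id, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname read_target_table
#' @param targets data.frame as returned by \code{read_target_table}.
#' @export
write_target_table <- function(targets, path) {
  write_tsv(targets[, c("mirna_id", "gene_id", "validated")], path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PPI edges
# ---------------------------------------------------------------------------

#' Read a gene-gene interaction (PPI) edge table
#'
#' TSV with header columns \code{gene_a}, \code{gene_b}. Edges are
#' undirected: each pair is canonicalized (lexicographically smaller id
#' first), self-loops dropped, duplicates removed.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}.
#' @export
read_ppi_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b"))
  canonical_ppi(data.frame(gene_a = normalize_id(df$gene_a),
                           gene_b = normalize_id(df$gene_b),
                           stringsAsFactors = FALSE))
}

canonical_ppi <- function(ppi) {
  if (nrow(ppi) == 0L) return(ppi)
  a <- pmin(ppi$gene_a, ppi$gene_b)
  b <- pmax(ppi$gene_a, ppi$gene_b)
  keep <- a != b & !duplicated(paste(a, b))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_ppi_table
#' @param ppi data.frame with columns \code{gene_a}, \code{gene_b}.
#' @export
write_ppi_table <- function(ppi, path) {
  write_tsv(ppi[, c("gene_a", "gene_b")], path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene -> GO annotation
# ---------------------------------------------------------------------------

#' Read a flat gene-to-GO annotation table
#'
#' TSV with header columns \code{gene_id}, \code{go_term} and optionally
#' \code{go_category}. GO is consumed flat: no ontology graph, no ancestor
#' propagation. When \code{go_category} is absent it is derived from
#' \code{category_map}; unmapped terms fall into \code{"other"}.
#'
#' @param path TSV file path.
#' @param category_map optional named character vector mapping
#'   \code{go_term} to a category in \code{\link{go_categories}}.
#' @return data.frame with columns \code{gene_id}, \code{go_term},
#'   \code{go_category}; (gene, term) pairs unique.
#' @export
read_annotation_table <- function(path, category_map = NULL) {
  df <- read_tsv_checked(path, c("gene_id", "go_term"), "go_category")
  df$gene_id <- normalize_id(df$gene_id)
  df$go_term <- trimws(df$go_term)
  if (!("go_category" %in% names(df))) {
    df$go_category <- if (is.null(category_map)) "other" else {
      ifelse(df$go_term %in% names(category_map),
             unname(category_map[df$go_term]), "other")
    }
  }
  df$go_category <- tolower(trimws(df$go_category))
  bad <- setdiff(unique(df$go_category), go_categories())
  if (length(bad)) stop("unknown go_category: ", paste(bad, collapse = ", "))
  df <- df[!duplicated(paste(df$gene_id, df$go_term, sep = "\r")), , drop = FALSE]
  df <- df[order(df$gene_id, df$go_term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_annotation_table
#' @param annotations data.frame as returned by \code{read_annotation_table}.
#' @export
write_annotation_table <- function(annotations, path) {
  write_tsv(annotations[, c("gene_id", "go_term", "go_category")], path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TF -> miRNA regulation
# ---------------------------------------------------------------------------

#' Read a TF-to-miRNA regulation edge table
#'
#' TSV with header columns \code{tf_id}, \code{mirna_id} and optional
#' \code{mode} (\code{activates}, \code{represses} or \code{unknown};
#' default \code{unknown}). The TF and miRNA namespaces must be disjoint.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{tf_id}, \code{mirna_id},
#'   \code{mode}.
#' @export
read_regulation_table <- function(path) {
  df <- read_tsv_checked(path, c("tf_id", "mirna_id"), "mode")
  df$tf_id <- normalize_id(df$tf_id)
  df$mirna_id <- normalize_id(df$mirna_id)
  df$mode <- if ("mode" %in% names(df)) tolower(trimws(df$mode)) else "unknown"
  bad <- setdiff(unique(df$mode), c("activates", "represses", "unknown"))
  if (length(bad)) stop("unknown regulation mode: ", paste(bad, collapse = ", "))
  clash <- intersect(unique(df$tf_id), unique(df$mirna_id))
  if (length(clash)) {
    stop("tf/mirna namespaces overlap: ", paste(clash, collapse = ", "))
  }
  df <- df[!duplicated(paste(df$tf_id, df$mirna_id, sep = "\r")), , drop = FALSE]
  df <- df[order(df$tf_id, df$mirna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_regulation_table
#' @param regulation data.frame as returned by \code{read_regulation_table}.
#' @export
write_regulation_table <- function(regulation, path) {
  write_tsv(regulation[, c("tf_id", "mirna_id", "mode")], path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GMT gene sets
# ---------------------------------------------------------------------------

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name}, \code{description}, gene, gene, ... Set names must be
#' unique; genes are de-duplicated per set.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("format error in %s at line %d: expected >= 3 tab-separated fields",
                   path, i))
    }
    nm <- trimws(fields[1])
    if (nm %in% names(sets)) {
      stop(sprintf("format error in %s at line %d: duplicate set name '%s'",
                   path, i, nm))
    }
    genes <- unique(normalize_id(fields[-(1:2)]))
    sets[[nm]] <- genes[nzchar(genes)]
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# SIF networks
# ---------------------------------------------------------------------------

#' Write a regulatory network in SIF format
#'
#' One edge per line, \code{source<TAB>edge_type<TAB>target}; undirected
#' \code{ppi} edges are emitted once in canonical order (lexicographically
#' smaller id first). Isolated nodes are emitted as single-column lines.
#'
#' @param net a \code{\link{regulatory_network}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  lines <- if (nrow(e)) paste(e$from, e$type, e$to, sep = "\t") else character()
  isolated <- setdiff(net$nodes$id, unique(c(e$from, e$to)))
  lines <- c(lines, sort(isolated))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a regulatory network from SIF
#'
#' Inverse of \code{\link{write_network_sif}}. Node types are inferred from
#' edge semantics: \code{targets} edges run miRNA to gene, \code{regulates}
#' edges gene to miRNA, \code{ppi} endpoints are genes. Isolated
#' (single-column) nodes are taken to be genes, since only connected miRNAs
#' are ever placed in a composite network.
#'
#' @param path SIF file path.
#' @param cohort cohort tag for the resulting network.
#' @return a \code{\link{regulatory_network}}.
#' @export
read_network_sif <- function(path, cohort = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  from <- character(); to <- character(); type <- character()
  genes <- character(); mirnas <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1L) {
      genes <- c(genes, f[1])
    } else if (length(f) == 3L) {
      if (!(f[2] %in% c("ppi", "targets", "regulates"))) {
        stop(sprintf("format error in %s at line %d: unknown edge type '%s'",
                     path, i, f[2]))
      }
      from <- c(from, f[1]); type <- c(type, f[2]); to <- c(to, f[3])
      if (f[2] == "ppi") genes <- c(genes, f[1], f[3])
      if (f[2] == "targets") { mirnas <- c(mirnas, f[1]); genes <- c(genes, f[3]) }
      if (f[2] == "regulates") { genes <- c(genes, f[1]); mirnas <- c(mirnas, f[3]) }
    } else {
      stop(sprintf("format error in %s at line %d: expected 1 or 3 fields", path, i))
    }
  }
  mirnas <- unique(mirnas)
  genes <- setdiff(unique(genes), mirnas)
  nodes <- data.frame(id = c(genes, mirnas),
                      type = rep(c("gene", "mirna"),
                                 c(length(genes), length(mirnas))),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes,
                     data.frame(from = from, to = to, type = type,
                                stringsAsFactors = FALSE),
                     cohort = cohort)
}
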