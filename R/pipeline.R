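# End-to-end pipeline: partition -> reverse annotation -> per-cohort
# network construction -> classification -> three-strategy marker calling,
# with a consolidated machine-readable run report.

empty_network <- function(cohort) {
  regulatory_network(data.frame(id = character(), type = character(),
                                stringsAsFactors = FALSE),
                     cohort = cohort)
}

#' Run the full marker-discovery pipeline on in-memory tables
#'
#' Executes every analysis stage in order: miRNA partition, per-cohort
#' reverse annotation and retention, induced-network construction with
#' neighbor expansion, sequential GO filtering, miRNA overlay, six-group
#' gene classification by network subtraction, per-cohort strategy scoring
#' and marker calling. All stages are deterministic.
#'
#' @param association \code{mirna_associations} data.frame.
#' @param targets miRNA-target edge data.frame.
#' @param annotations gene-GO annotation data.frame.
#' @param ppi PPI edge data.frame.
#' @param regulation TF-miRNA regulation data.frame.
#' @param disease_sets optional named list of disease gene sets; when
#'   absent, a single set holding every network gene is used, which makes
#'   the enrichment-rank strategy non-restrictive.
#' @param cohorts length-2 cohort labels (A, B).
#' @param whitelist GO categories retaining miRNAs.
#' @param alpha BH significance level for retention.
#' @param filters ordered GO filter sequence for network reduction.
#' @param depth neighbor expansion depth.
#' @param top key-node count or fraction.
#' @param top_n enrichment ranking depth.
#' @param policy marker-calling policy.
#' @return list of class \code{pipeline_result} with elements
#'   \code{partition}, \code{networks} (composite networks per cohort),
#'   \code{traces}, \code{retained}, \code{ffl}, \code{classification},
#'   \code{containment}, \code{scores}, \code{panel}, \code{params}.
#' @export
run_pipeline <- function(association, targets, annotations, ppi, regulation,
                         disease_sets = NULL,
                         cohorts = c("NSCLC", "SCLC"),
                         whitelist = default_whitelist(), alpha = 0.05,
                         filters = default_whitelist(), depth = 1L,
                         top = 0.25, top_n = 25L,
                         policy = c("intersection", "majority")) {
  policy <- match.arg(policy)
  part <- partition_mirnas(association, cohorts)
  universe <- unique(c(annotations$gene_id, targets$gene_id,
                       ppi$gene_a, ppi$gene_b))
  mirna_sets <- list(A = part$unique_A, B = part$unique_B,
                     common = part$common)
  cohort_tags <- c(A = cohorts[1], B = cohorts[2], common = "common")

  networks <- list(); traces <- list(); retained <- list(); ffl <- list()
  for (k in names(mirna_sets)) {
    tag <- cohort_tags[[k]]
    ann <- annotate_mirnas(mirna_sets[[k]], targets, annotations, universe,
                           alpha = alpha, whitelist = whitelist)
    fc <- filter_cohort_mirnas(ann, whitelist, alpha)
    retained[[k]] <- fc$retained
    if (length(fc$pooled_targets) == 0L) {
      networks[[k]] <- empty_network(tag)
      traces[[k]] <- data.frame(filter = "input", nodes = 0L, edges = 0L,
                                stringsAsFactors = FALSE)
      ffl[[k]] <- 0L
      next
    }
    net0 <- build_induced_network(fc$pooled_targets, ppi, tag, depth)
    gf <- apply_go_filters(net0, annotations, filters)
    comp <- overlay_regulation(gf$network, regulation, targets, fc$retained)
    networks[[k]] <- comp
    traces[[k]] <- gf$trace
    ffl[[k]] <- count_feedforward_loops(comp)
  }

  classification <- classify_genes(networks$A, networks$B, networks$common)
  containment <- containment_check(networks$B, networks$A)

  if (is.null(disease_sets)) {
    disease_sets <- list(all_network_genes = sort(unique(unlist(
      lapply(networks, network_genes), use.names = FALSE))))
  }
  scores <- list()
  for (k in names(networks)) {
    if (length(network_genes(networks[[k]])) == 0L) next
    scores[[k]] <- strategy_scores(networks[[k]], disease_sets, universe,
                                   top = top, top_n = top_n)
  }
  all_scores <- do.call(rbind, scores)
  panel <- if (is.null(all_scores)) {
    call_markers(data.frame(gene = character(), degree = integer(),
                            is_key_node = logical(),
                            on_shortest_path = logical(),
                            enrichment_rank = integer(),
                            stringsAsFactors = FALSE), classification, policy)
  } else call_markers(all_scores, classification, policy)

  structure(list(partition = part, networks = networks, traces = traces,
                 retained = retained, ffl = ffl,
                 classification = classification, containment = containment,
                 scores = scores, panel = panel,
                 params = list(cohorts = cohorts, whitelist = whitelist,
                               alpha = alpha, filters = filters,
                               depth = depth, top = top, top_n = top_n,
                               policy = policy)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$partition)
  for (k in names(x$networks)) {
    cat(sprintf("  %-7s network: %d genes, %d miRNAs, %d ffl\n", k,
                length(network_genes(x$networks[[k]])),
                length(network_mirnas(x$networks[[k]])), x$ffl[[k]]))
  }
  cat(sprintf("  panel: %s\n", paste(x$panel$gene_id, collapse = ", ")))
  invisible(x)
}

#' Build the consolidated run report
#'
#' Collects every stage artifact of a pipeline result into a plain list
#' that serializes losslessly to JSON; no quantity is recomputed here.
#'
#' @param result a \code{pipeline_result}.
#' @param seed seed recorded for provenance (synthetic stages only; the
#'   analysis stages are deterministic).
#' @return report list.
#' @export
pipeline_report <- function(result, seed = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  cls_sizes <- lapply(unclass(result$classification), length)
  list(
    schema = "mirtfnet/report/v1",
    seed = seed,
    params = result$params,
    partition = partition_report(result$partition),
    cohorts = lapply(stats::setNames(names(result$networks),
                                     names(result$networks)), function(k) {
      list(cohort = result$networks[[k]]$cohort,
           retained_mirnas = length(result$retained[[k]]),
           genes = length(network_genes(result$networks[[k]])),
           mirnas = length(network_mirnas(result$networks[[k]])),
           edges = nrow(result$networks[[k]]$edges),
           feedforward_loops = result$ffl[[k]],
           filter_trace = result$traces[[k]])
    }),
    classification = list(sizes = cls_sizes,
                          groups = unclass(result$classification)),
    containment_B_in_A = result$containment,
    panel = result$panel)
}

#' Compare a called panel against a synthetic truth record
#'
#' @param result a \code{pipeline_result}.
#' @param truth truth record of a \code{\link{generate_bundle}} bundle.
#' @return list with \code{recall}, \code{precision}, \code{called},
#'   \code{planted}. Precision of an empty panel is 1 (no false calls).
#' @export
marker_recovery <- function(result, truth) {
  planted <- sort(c(truth$planted_markers_A, truth$planted_markers_general))
  called <- result$panel$gene_id
  hits <- length(intersect(called, planted))
  list(recall = if (length(planted)) hits / length(planted) else 1,
       precision = if (length(called)) hits / length(called) else 1,
       called = sort(called), planted = planted)
}

# ---------------------------------------------------------------------------
# Run configuration (flat key: value document, DCF dialect) and run_all
# ---------------------------------------------------------------------------

#' Read a run configuration file
#'
#' Flat, human-editable \code{key: value} document (Debian control format,
#' parsed with \code{read.dcf}). Recognized keys: the five input table
#' paths (\code{associations}, \code{targets}, \code{annotations},
#' \code{ppi}, \code{regulation}), optional \code{disease_sets} (GMT),
#' \code{out_dir}, \code{cohorts}, \code{whitelist} and \code{filters}
#' (comma-separated), \code{alpha}, \code{depth}, \code{top},
#' \code{top_n}, \code{policy}, \code{seed}.
#'
#' @param path config file path.
#' @return named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  cfg <- as.list(m[1, ])
  split_csv <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  defaults <- list(cohorts = c("NSCLC", "SCLC"),
                   whitelist = default_whitelist(),
                   filters = default_whitelist(),
                   alpha = 0.05, depth = 1L, top = 0.25, top_n = 25L,
                   policy = "intersection", seed = 1L,
                   disease_sets = NULL, out_dir = ".")
  out <- defaults
  for (nm in names(cfg)) {
    out[[nm]] <- switch(nm,
      cohorts = , whitelist = , filters = split_csv(cfg[[nm]]),
      alpha = , top = as.numeric(cfg[[nm]]),
      depth = , top_n = , seed = as.integer(cfg[[nm]]),
      cfg[[nm]])
  }
  required <- c("associations", "targets", "annotations", "ppi", "regulation")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("config error: missing key(s) ", paste(missing, collapse = ", "))
  }
  for (f in c(required, if (!is.null(out$disease_sets)) "disease_sets")) {
    if (!file.exists(out[[f]])) {
      stop("config error: ", f, " path does not exist: ", out[[f]])
    }
  }
  structure(out, class = "run_config")
}

#' Run the whole pipeline from a configuration
#'
#' Reads the input tables named by the configuration, executes all stages,
#' and writes \code{report.json}, one SIF file per composite cohort
#' network, and \code{classification.json} (the six-group comparison) into
#' the output directory.
#'
#' @param cfg a \code{run_config} (or path to a config file).
#' @return invisibly, the report list.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  association <- read_association_table(cfg$associations,
                                        cohorts = cfg$cohorts)
  targets <- read_target_table(cfg$targets)
  annotations <- read_annotation_table(cfg$annotations)
  ppi <- read_ppi_table(cfg$ppi)
  regulation <- read_regulation_table(cfg$regulation)
  disease_sets <- if (!is.null(cfg$disease_sets)) read_gmt(cfg$disease_sets)
  res <- run_pipeline(association, targets, annotations, ppi, regulation,
                      disease_sets, cohorts = cfg$cohorts,
                      whitelist = cfg$whitelist, alpha = cfg$alpha,
                      filters = cfg$filters, depth = cfg$depth,
                      top = cfg$top, top_n = cfg$top_n, policy = cfg$policy)
  report <- pipeline_report(res, seed = cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(list(sizes = lapply(unclass(res$classification), length),
                            groups = unclass(res$classification)),
                       file.path(cfg$out_dir, "classification.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (k in names(res$networks)) {
    write_network_sif(res$networks[[k]],
                      file.path(cfg$out_dir, paste0("network_", k, ".sif")))
  }
  invisible(report)
}
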