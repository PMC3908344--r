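# Synthetic input bundles with planted marker structure.
#
# The generator states a world shaped like the lung-cancer study the
# pipeline targets: two disease subtypes (A = NSCLC-like, B = SCLC-like)
# plus a shared/common cohort; a nine-gene TF core present in all three
# cohort networks; a block of TFs shared by A and the common cohort;
# planted subtype-specific marker TFs satisfying every marker criterion by
# construction (three-category GO annotation, targeting by >= 2 cohort
# miRNAs, hub degree, TF-miRNA regulation closing feed-forward loops); and
# decoy TFs each failing at least one criterion. Module-structured target
# draws make each miRNA's target set strongly enriched for a small GO term
# so the reverse-annotation step retains it.

stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483629)
}

#' Synthetic bundle configuration
#'
#' Defaults encode the study-scale world: 143 subtype-A-unique, 21
#' subtype-B-unique and 41 shared miRNAs; 4 planted A-specific and 3
#' planted general-path markers; a 9-gene core shared by all cohorts and 6
#' genes shared by A and the common cohort. The gene universe (600) and
#' targets per miRNA (16) are desk-scale stand-ins for database-era pools.
#'
#' @param n_mirna_A,n_mirna_B,n_common cohort-unique and shared miRNA
#'   counts.
#' @param targets_per_mirna validated targets drawn per miRNA (>= 6).
#' @param n_genes gene universe size.
#' @param n_tf number of TF genes (the first genes of the universe).
#' @param ppi_edge_prob background Erdos-Renyi PPI edge probability.
#' @param planted_markers_A,planted_markers_general planted marker counts.
#' @param core_shared,shared_AC,decoys_A,decoys_C sizes of the shared core,
#'   the A-and-common shared block, and the per-cohort decoy blocks.
#' @param go_noise_prob probability, per gene, of a spurious GO annotation.
#' @param seed master seed; every table derives its own stream from it.
#' @return validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_mirna_A = 143L, n_mirna_B = 21L, n_common = 41L,
                             targets_per_mirna = 16L, n_genes = 600L,
                             n_tf = 40L, ppi_edge_prob = 0.008,
                             planted_markers_A = 4L,
                             planted_markers_general = 3L,
                             core_shared = 9L, shared_AC = 6L,
                             decoys_A = 3L, decoys_C = 3L,
                             go_noise_prob = 0.02, seed = 1L) {
  cfg <- list(n_mirna_A = as.integer(n_mirna_A),
              n_mirna_B = as.integer(n_mirna_B),
              n_common = as.integer(n_common),
              targets_per_mirna = as.integer(targets_per_mirna),
              n_genes = as.integer(n_genes), n_tf = as.integer(n_tf),
              ppi_edge_prob = ppi_edge_prob,
              planted_markers_A = as.integer(planted_markers_A),
              planted_markers_general = as.integer(planted_markers_general),
              core_shared = as.integer(core_shared),
              shared_AC = as.integer(shared_AC),
              decoys_A = as.integer(decoys_A),
              decoys_C = as.integer(decoys_C),
              go_noise_prob = go_noise_prob, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_mirna_A", "n_mirna_B", "n_common", "targets_per_mirna",
              "n_genes", "n_tf", "planted_markers_A",
              "planted_markers_general", "core_shared", "shared_AC",
              "decoys_A", "decoys_C")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) stop("config error: ", f, " must be >= 0")
  }
  for (f in c("ppi_edge_prob", "go_noise_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("config error: ", f, " must be in [0,1]")
  }
  n_cc <- cfg$core_shared + cfg$shared_AC + cfg$planted_markers_A +
    cfg$decoys_A + cfg$planted_markers_general + cfg$decoys_C
  if (n_cc > cfg$n_tf) {
    stop("config error: planted/shared TF blocks (", n_cc,
         ") exceed n_tf (", cfg$n_tf, ")")
  }
  if (cfg$targets_per_mirna < 6L) {
    stop("config error: targets_per_mirna must be >= 6 ",
         "(5 module targets plus filler)")
  }
  # a non-empty target module needs >= 5 genes for the enrichment quota
  if (cfg$core_shared < 5L) {
    stop("config error: core_shared must be >= 5 (it anchors all cohorts)")
  }
  am <- cfg$planted_markers_A + cfg$decoys_A
  gm <- cfg$planted_markers_general + cfg$decoys_C
  for (blk in list(c("shared_AC", cfg$shared_AC),
                   c("planted_markers_A + decoys_A", am),
                   c("planted_markers_general + decoys_C", gm))) {
    sz <- as.integer(blk[2])
    if (sz > 0L && sz < 5L) {
      stop("config error: block ", blk[1],
           " must be 0 or >= 5 (enrichment quota)")
    }
  }
  if (am > 0L && cfg$n_mirna_A < 5L) {
    stop("config error: planted/decoy A markers need n_mirna_A >= 5")
  }
  if (gm > 0L && cfg$n_common < 5L) {
    stop("config error: planted/decoy general markers need n_common >= 5")
  }
  if (cfg$n_mirna_A + cfg$n_mirna_B + cfg$n_common < 1L) {
    stop("config error: at least one miRNA is required")
  }
  filler <- cfg$n_genes - cfg$n_tf
  bg_needed <- ceiling(cfg$n_genes * cfg$ppi_edge_prob) + 10L
  if (filler < 60L + bg_needed) {
    stop("config error: n_genes too small for the filler pools and the ",
         "hub-degree requirement at this ppi_edge_prob")
  }
  invisible(cfg)
}

# one regulates edge per planted gene, to a cohort miRNA that targets a
# different member of the planted block (feed-forward loop closure)
ffl_close <- function(block, targets, mirnas, module = block) {
  do.call(rbind, lapply(block, function(g) {
    m <- targets$mirna_id[targets$gene_id %in% setdiff(module, g) &
                          targets$mirna_id %in% mirnas]
    if (!length(m)) {
      stop("config error: no cohort miRNA targets the planted block of ", g)
    }
    data.frame(tf_id = g, mirna_id = draw(unique(m), 1L),
               stringsAsFactors = FALSE)
  }))
}

# deterministic sample of k elements from x under the current stream
draw <- function(x, k) {
  if (k <= 0L) return(x[0])
  if (length(x) == 1L) return(rep(x, min(k, 1L)))
  sample(x, min(k, length(x)))
}

#' Generate a synthetic input bundle
#'
#' Produces all six pipeline inputs (association, target, annotation, PPI
#' and regulation tables plus disease gene sets) and a truth record naming
#' the planted markers and block memberships. Identical seeds give
#' identical bundles.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return object of class \code{synthetic_bundle}: list with
#'   \code{association}, \code{targets}, \code{annotations}, \code{ppi},
#'   \code{regulation}, \code{disease_sets}, \code{truth}, \code{config}.
#' @export
generate_bundle <- function(cfg) {
  validate_synthetic_config(cfg)
  # --- identifier layout -------------------------------------------------
  mir_A <- sprintf("MIR-A%03d", seq_len(cfg$n_mirna_A))
  mir_B <- sprintf("MIR-B%03d", seq_len(cfg$n_mirna_B))
  mir_C <- sprintf("MIR-C%03d", seq_len(cfg$n_common))
  core <- sprintf("TFCORE%02d", seq_len(cfg$core_shared))
  ac <- sprintf("TFAC%02d", seq_len(cfg$shared_AC))
  pa <- sprintf("TFMA%02d", seq_len(cfg$planted_markers_A))
  da <- sprintf("TFDA%02d", seq_len(cfg$decoys_A))
  pg <- sprintf("TFMG%02d", seq_len(cfg$planted_markers_general))
  dc <- sprintf("TFDC%02d", seq_len(cfg$decoys_C))
  cc <- c(core, ac, pa, da, pg, dc)
  spare_tf <- sprintf("TFSP%02d", seq_len(cfg$n_tf - length(cc)))
  n_fill <- cfg$n_genes - cfg$n_tf
  fill <- sprintf("G%04d", seq_len(n_fill))
  # filler pools per cohort are disjoint so neighbor expansion cannot leak
  # a cc gene into the wrong cohort network
  n_bg <- max(ceiling(cfg$n_genes * cfg$ppi_edge_prob) + 10L,
              round(0.25 * n_fill))
  n_fb <- max(10L, round(0.10 * (n_fill - n_bg)))
  n_fc <- max(20L, round(0.30 * (n_fill - n_bg)))
  fill_b <- fill[seq_len(n_fb)]
  fill_c <- fill[n_fb + seq_len(n_fc)]
  fill_a <- fill[(n_fb + n_fc + 1):(n_fill - n_bg)]
  background <- fill[(n_fill - n_bg + 1):n_fill]
  universe <- c(cc, spare_tf, fill)

  # --- association table (stream 1) --------------------------------------
  set.seed(stream_seed(cfg$seed, 1L))
  dir_a <- sample(rep(c("up", "down"), c(round(0.62 * cfg$n_mirna_A),
                                         cfg$n_mirna_A - round(0.62 * cfg$n_mirna_A))))
  dir_b <- sample(rep(c("up", "down"), c(round(0.75 * cfg$n_mirna_B),
                                         cfg$n_mirna_B - round(0.75 * cfg$n_mirna_B))))
  # common miRNAs: roughly a third each concordant-up, concordant-down,
  # differential (opposite direction in the two subtypes)
  n_up <- round(0.32 * cfg$n_common)
  n_dn <- round(0.27 * cfg$n_common)
  n_diff <- cfg$n_common - n_up - n_dn
  kind <- sample(rep(c("up", "down", "diff"), c(n_up, n_dn, n_diff)))
  dir_c1 <- ifelse(kind == "diff", sample(c("up", "down"), cfg$n_common,
                                          replace = TRUE), kind)
  dir_c2 <- ifelse(kind == "diff", ifelse(dir_c1 == "up", "down", "up"), kind)
  assoc_rows <- function(ids, subtype, dirs) {
    if (!length(ids)) return(NULL)
    data.frame(mirna_id = ids, subtype = subtype, direction = dirs,
               source = "synthetic", stringsAsFactors = FALSE)
  }
  association <- rbind(assoc_rows(mir_A, "NSCLC", dir_a),
                       assoc_rows(mir_B, "SCLC", dir_b),
                       assoc_rows(mir_C, "NSCLC", dir_c1),
                       assoc_rows(mir_C, "SCLC", dir_c2))

  # --- target table (stream 2) -------------------------------------------
  # each miRNA draws 5 targets from one cc module (driving a small-term
  # enrichment signal) and fills up from its cohort's filler pool
  set.seed(stream_seed(cfg$seed, 2L))
  mk_targets <- function(mirnas, modules, pool) {
    modules <- Filter(length, modules)
    if (!length(mirnas) || !length(modules)) return(NULL)
    rows <- vector("list", length(mirnas))
    for (i in seq_along(mirnas)) {
      mod <- modules[[((i - 1L) %% length(modules)) + 1L]]
      gs <- c(draw(mod, 5L), draw(pool, cfg$targets_per_mirna - 5L))
      rows[[i]] <- data.frame(mirna_id = mirnas[i], gene_id = unique(gs),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  tg_a <- mk_targets(mir_A, list(core, ac, c(pa, da)), c(fill_a, spare_tf))
  tg_b <- mk_targets(mir_B, list(core), fill_b)
  tg_c <- mk_targets(mir_C, list(core, ac, c(pg, dc)), fill_c)
  targets <- rbind(tg_a, tg_b, tg_c)
  # coverage pass: every intended cc gene targeted by >= 2 miRNAs of each
  # cohort whose network it belongs to
  cover <- function(targets, genes, mirnas) {
    for (g in genes) {
      have <- unique(targets$mirna_id[targets$gene_id == g &
                                      targets$mirna_id %in% mirnas])
      need <- min(2L, length(mirnas)) - length(have)
      if (need > 0L) {
        add <- draw(setdiff(mirnas, have), need)
        targets <- rbind(targets,
                         data.frame(mirna_id = add, gene_id = g,
                                    stringsAsFactors = FALSE))
      }
    }
    targets
  }
  targets <- cover(targets, c(core, ac, pa, da), mir_A)
  targets <- cover(targets, core, mir_B)
  targets <- cover(targets, c(core, ac, pg, dc), mir_C)
  targets$validated <- TRUE
  targets <- targets[!duplicated(paste(targets$mirna_id, targets$gene_id)), ]
  targets <- targets[order(targets$mirna_id, targets$gene_id), ]
  rownames(targets) <- NULL

  # --- annotation table (stream 3) ---------------------------------------
  set.seed(stream_seed(cfg$seed, 3L))
  mod_of <- c(stats::setNames(rep("CORE", length(core)), core),
              stats::setNames(rep("AC", length(ac)), ac),
              stats::setNames(rep("AM", length(c(pa, da))), c(pa, da)),
              stats::setNames(rep("GM", length(c(pg, dc))), c(pg, dc)))
  cat_prefix <- c(transcription = "GO:TR", cell_cycle = "GO:CYC",
                  cell_organization_biogenesis = "GO:ORG")
  ann_cc <- do.call(rbind, lapply(names(cat_prefix), function(catg) {
    data.frame(gene_id = cc,
               go_term = paste0(cat_prefix[[catg]], ":", mod_of[cc]),
               go_category = catg, stringsAsFactors = FALSE)
  }))
  others <- c(spare_tf, fill)
  ann_other <- data.frame(
    gene_id = others,
    go_term = sprintf("GO:OTHER:%02d", sample.int(10L, length(others),
                                                  replace = TRUE)),
    go_category = "other", stringsAsFactors = FALSE)
  # spurious annotations: single-category noise (transcription-side or
  # "other" terms) so no gene can spuriously satisfy all three filters
  noisy <- universe[stats::runif(length(universe)) < cfg$go_noise_prob]
  ann_noise <- if (length(noisy)) {
    data.frame(gene_id = noisy,
               go_term = sample(c(paste0("GO:TR:", c("CORE", "AC", "AM", "GM")),
                                  sprintf("GO:OTHER:%02d", 1:10)),
                                length(noisy), replace = TRUE),
               go_category = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(ann_noise)) {
    ann_noise$go_category <- ifelse(startsWith(ann_noise$go_term, "GO:TR"),
                                    "transcription", "other")
  }
  annotations <- rbind(ann_cc, ann_other, ann_noise)
  annotations <- annotations[!duplicated(paste(annotations$gene_id,
                                               annotations$go_term)), ]
  annotations <- annotations[order(annotations$gene_id, annotations$go_term), ]
  rownames(annotations) <- NULL

  # --- ppi table (stream 4) ----------------------------------------------
  set.seed(stream_seed(cfg$seed, 4L))
  noncc <- c(spare_tf, fill)
  er <- igraph::as_edgelist(igraph::sample_gnp(length(noncc),
                                               cfg$ppi_edge_prob))
  ppi <- data.frame(gene_a = noncc[er[, 1]], gene_b = noncc[er[, 2]],
                    stringsAsFactors = FALSE)
  ring <- function(genes) {
    n <- length(genes)
    if (n < 2L) return(NULL)
    df <- data.frame(gene_a = genes, gene_b = genes[c(2:n, 1L)],
                     stringsAsFactors = FALSE)
    if (n == 2L) df[1, , drop = FALSE] else df
  }
  clique <- function(genes) {
    if (length(genes) < 2L) return(NULL)
    cmb <- utils::combn(genes, 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  }
  # cc-cc edges only within blocks whose cohort memberships agree, so
  # neighbor expansion never pulls a cc gene into a foreign cohort network
  attach_to <- function(leaves, hubs) {
    if (!length(leaves) || !length(hubs)) return(NULL)
    data.frame(gene_a = leaves, gene_b = rep_len(hubs, length(leaves)),
               stringsAsFactors = FALSE)
  }
  ppi <- rbind(ppi, ring(core), ring(ac), clique(pa), clique(pg),
               attach_to(da, pa), attach_to(dc, pg))
  ppi <- canonical_ppi(ppi)
  # planted raw-PPI hub condition: degree above the non-planted median
  planted <- c(pa, pg)
  deg <- table(factor(c(ppi$gene_a, ppi$gene_b), levels = universe))
  med <- stats::median(deg[setdiff(universe, planted)])
  for (g in planted) {
    need <- as.integer(med) + 3L - as.integer(deg[[g]])
    if (need > 0L) {
      nb <- draw(setdiff(background, c(ppi$gene_b[ppi$gene_a == g],
                                       ppi$gene_a[ppi$gene_b == g])), need)
      if (length(nb) < need) {
        stop("config error: background pool too small to satisfy the ",
             "planted hub-degree requirement")
      }
      ppi <- rbind(ppi, data.frame(gene_a = g, gene_b = nb,
                                   stringsAsFactors = FALSE))
    }
  }
  ppi <- canonical_ppi(ppi)

  # --- regulation table (stream 5), incl. composite hub boosting ---------
  set.seed(stream_seed(cfg$seed, 5L))
  baseline <- function(tf, mirnas) {
    m <- draw(mirnas, 2L)
    if (!length(m)) return(NULL)
    data.frame(tf_id = tf, mirna_id = m, stringsAsFactors = FALSE)
  }
  reg <- rbind(
    baseline(core[1], mir_A), baseline(core[2], mir_B), baseline(core[3], mir_C),
    # planted markers regulate miRNAs of their own cohort; the regulated
    # miRNA is chosen among those targeting another member of the planted
    # block, which closes a feed-forward loop over the intra-block ppi edge
    if (length(pa)) ffl_close(pa, targets, mir_A, c(pa, da)),
    if (length(pg)) ffl_close(pg, targets, mir_C, c(pg, dc)))
  # composite-degree boost: in each cohort's final composite network every
  # planted marker must out-rank every non-planted gene, so extra
  # regulates edges are wired until that holds (collapsed-pair degree)
  boost <- function(reg, net_genes, planted_genes, mirnas) {
    if (!length(planted_genes)) return(reg)
    pair_deg <- function(g) {
      ppi_n <- sum((ppi$gene_a == g & ppi$gene_b %in% net_genes) |
                   (ppi$gene_b == g & ppi$gene_a %in% net_genes))
      ms <- union(targets$mirna_id[targets$gene_id == g &
                                   targets$mirna_id %in% mirnas],
                  reg$mirna_id[reg$tf_id == g & reg$mirna_id %in% mirnas])
      ppi_n + length(ms)
    }
    degs <- vapply(net_genes, pair_deg, numeric(1))
    goal <- max(degs[setdiff(net_genes, planted_genes)]) + 1L
    for (g in planted_genes) {
      lack <- goal - degs[[g]]
      if (lack <= 0L) next
      used <- union(targets$mirna_id[targets$gene_id == g],
                    reg$mirna_id[reg$tf_id == g])
      add <- draw(setdiff(mirnas, used), lack)
      if (length(add) < lack) {
        stop("config error: not enough cohort miRNAs to boost planted ",
             "marker ", g, " to hub degree")
      }
      reg <- rbind(reg, data.frame(tf_id = g, mirna_id = add,
                                   stringsAsFactors = FALSE))
    }
    reg
  }
  reg <- boost(reg, c(core, ac, pa, da), pa, mir_A)
  reg <- boost(reg, c(core, ac, pg, dc), pg, mir_C)
  reg$mode <- sample(c("activates", "represses", "unknown"), nrow(reg),
                     replace = TRUE)
  reg <- reg[!duplicated(paste(reg$tf_id, reg$mirna_id)), ]
  reg <- reg[order(reg$tf_id, reg$mirna_id), ]
  rownames(reg) <- NULL

  # --- disease gene sets (stream 6) --------------------------------------
  set.seed(stream_seed(cfg$seed, 6L))
  disease_sets <- list(
    lung_core = sort(c(core, ac, pa, pg)),
    unrelated = sort(draw(background, min(20L, length(background)))))

  truth <- list(planted_markers_A = pa, planted_markers_general = pg,
                core_shared = core, shared_AC = ac,
                decoys_A = da, decoys_C = dc,
                mirna_unique_A = mir_A, mirna_unique_B = mir_B,
                mirna_common = mir_C)
  structure(list(association = association, targets = targets,
                 annotations = annotations, ppi = ppi, regulation = reg,
                 disease_sets = disease_sets, truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle> %d miRNAs, %d genes, %d target edges, ",
                     "%d ppi edges, %d regulation edges\n"),
              length(unique(x$association$mirna_id)), x$config$n_genes,
              nrow(x$targets), nrow(x$ppi), nrow(x$regulation)))
  invisible(x)
}

#' Randomly degrade a synthetic bundle
#'
#' Removes a fraction of the target and PPI edges uniformly at random,
#' leaving the truth record untouched; used to probe how marker recovery
#' decays with data loss.
#'
#' @param bundle a \code{synthetic_bundle}.
#' @param drop_frac fraction of edges to remove, in [0, 1).
#' @param seed RNG seed for the removal draw.
#' @return a degraded \code{synthetic_bundle}.
#' @export
degrade_bundle <- function(bundle, drop_frac, seed = 1L) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (drop_frac < 0 || drop_frac >= 1) {
    stop("drop_frac must satisfy 0 <= drop_frac < 1")
  }
  if (drop_frac == 0) return(bundle)
  set.seed(stream_seed(seed, 99L))
  drop_rows <- function(df, frac) {
    k <- floor(frac * nrow(df))
    if (k == 0L) return(df)
    out <- df[-draw(seq_len(nrow(df)), k), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  bundle$targets <- drop_rows(bundle$targets, drop_frac)
  bundle$ppi <- drop_rows(bundle$ppi, drop_frac)
  bundle
}

#' Write a synthetic bundle to a directory
#'
#' Emits the six flat inputs (\code{associations.tsv}, \code{targets.tsv},
#' \code{annotations.tsv}, \code{ppi.tsv}, \code{regulation.tsv},
#' \code{disease_sets.gmt}) plus \code{truth.json}.
#'
#' @param bundle a \code{synthetic_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_association_table(bundle$association, file.path(dir, "associations.tsv"))
  write_target_table(bundle$targets, file.path(dir, "targets.tsv"))
  write_annotation_table(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_ppi_table(bundle$ppi, file.path(dir, "ppi.tsv"))
  write_regulation_table(bundle$regulation, file.path(dir, "regulation.tsv"))
  write_gmt(bundle$disease_sets, file.path(dir, "disease_sets.gmt"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory written by \code{\link{write_bundle}}
#'
#' @param dir bundle directory.
#' @return list with the same table elements as a \code{synthetic_bundle}
#'   (truth present when \code{truth.json} exists).
#' @export
read_bundle <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  list(
    association = read_association_table(file.path(dir, "associations.tsv")),
    targets = read_target_table(file.path(dir, "targets.tsv")),
    annotations = read_annotation_table(file.path(dir, "annotations.tsv")),
    ppi = read_ppi_table(file.path(dir, "ppi.tsv")),
    regulation = read_regulation_table(file.path(dir, "regulation.tsv")),
    disease_sets = read_gmt(file.path(dir, "disease_sets.gmt")),
    truth = if (file.exists(truth_path)) {
      jsonlite::fromJSON(truth_path, simplifyVector = TRUE)
    } else NULL)
}
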