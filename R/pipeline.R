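#' Run the full analysis pipeline on a synthetic study
#'
#' End-to-end exercise of every stage on generated data with planted truth:
#' simulation, FPKM normalization, signature and PCA QC, percentile gene
#' filtering, the relative and centralized layers, group-contrast
#' differential expression on both layers, top-50 over-representation,
#' activity-stratified KS regulatory scores, guilt-by-association interferon
#' co-expression with its over-representation hand-off, k-means module
#' detection with size selection and marker annotation, ligand-receptor
#' occurrence with Fisher group tests, communication-gene enrichment, and
#' cytokine-activity group statistics on a synthetic signature projection.
#'
#' All interchange files are written under `out_dir`: `counts.tsv`,
#' `gene_lengths.tsv`, `samples.tsv`, `truth.json`, `sets.gmt`,
#' `lr_pairs.tsv`, `fpkm.tsv`, `relative.tsv`, `centralized.tsv`,
#' `samples_qc.tsv`, `deg_<contrast>.tsv`, `regscore.tsv`,
#' `gba_<condition>.tsv`, `gba_ora.tsv`, `clusters.tsv`,
#' `cluster_annotation.tsv`, `interactions.tsv`, `activity_stats.tsv`,
#' `pca_overview.tsv`, `provenance.jsonl`.
#'
#' @param out_dir output directory.
#' @param config a `SimulationConfig` (default study-sized).
#' @param n_perm permutation draws for the co-expression null (default
#'   10,000).
#' @param k number of gene modules for k-means (default 10).
#' @param gba_cell_types cell types to run guilt-by-association on (default
#'   all; restrict to bound runtime).
#' @param seed seed for the analysis-side randomness (permutations, k-means
#'   restarts); the simulation uses `config$seed`.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         n_perm = 10000, k = 10,
                         gba_cell_types = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "provenance.jsonl")
  logline <- function(step, ...) {
    rec <- c(list(step = step, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }

  ## simulate ------------------------------------------------------------
  sim <- simulate_dataset(config)
  catalog <- simulate_genesets(sim$truth, n_decoy_sets = 50,
                               seed = config$seed)
  lr <- simulate_lr_table(sim$truth, n_decoy_pairs = 20, seed = config$seed)
  write_dataset(sim, out_dir, catalog = catalog, lr = lr)
  logline("simulate", n_genes = config$n_genes,
          n_samples = ncol(sim$counts$values))

  ## preprocess ----------------------------------------------------------
  fp <- fpkm(sim$counts, sim$gene_lengths)
  st <- qc_signature_check(fp, marker_catalog(sim$truth), sim$samples)
  st <- pca_outlier_flag(fp, st)
  fp_f <- filter_genes(fp, lo_pct = 45, hi_pct = 99.5)
  rel <- relative_expression(fp_f, st, pseudocount = 0.1)
  # centralization is per sample, so one pass covers every culture
  # condition; the steady view is a column subset
  cen_all <- centralize(fp_f[, intersect(st$sample_id[qc_pass(st)],
                                         samples(fp_f))])
  steady_ids <- st$sample_id[st$condition == "steady" & qc_pass(st)]
  cen <- cen_all[, intersect(steady_ids, samples(cen_all))]
  universe <- genes(fp_f)
  write_expression_tsv(fp_f, file.path(out_dir, "fpkm.tsv"))
  write_expression_tsv(rel$matrix, file.path(out_dir, "relative.tsv"))
  write_expression_tsv(cen, file.path(out_dir, "centralized.tsv"))
  utils::write.table(as.data.frame(st), file.path(out_dir, "samples_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("preprocess", n_genes_kept = length(universe),
          n_flagged = sum(!qc_pass(st)))

  ## PCA overview --------------------------------------------------------
  all_ids <- intersect(st$sample_id[qc_pass(st)], samples(fp_f))
  pca <- pca_overview(fp_f[, all_ids], st)
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores),
               PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
               explained1 = pca$explained[1], explained2 = pca$explained[2]),
    file.path(out_dir, "pca_overview.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## differential expression + ORA --------------------------------------
  diseases <- setdiff(names(config$group_sizes), "HD")
  deg_results <- list(); ora_rows <- list()
  for (ct in config$cell_types) {
    for (g in diseases) {
      for (layer in c("relative", "centralized")) {
        m <- if (layer == "relative") rel$matrix else cen
        stab <- if (layer == "relative") rel$samples else st
        res <- try(deg_test(m, stab, "HD", g, ct,
                            condition = if (layer == "centralized") "steady"
                            else NULL),
                   silent = TRUE)
        if (inherits(res, "try-error")) next
        tag <- sprintf("HD-vs-%s_%s_%s", g, ct, layer)
        deg_results[[tag]] <- res
        utils::write.table(res, file.path(out_dir,
                                          paste0("deg_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        tops <- rank_by_fdr(res, 50)
        for (dir_ in c("up", "down")) {
          if (!length(tops[[dir_]])) next
          o <- suppressWarnings(ora(tops[[dir_]], catalog, universe))
          o$contrast <- tag; o$direction <- dir_
          ora_rows[[length(ora_rows) + 1L]] <- o
        }
      }
    }
  }
  if (length(ora_rows))
    utils::write.table(do.call(rbind, ora_rows),
                       file.path(out_dir, "ora_top50.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  logline("diffexpr", n_contrasts = length(deg_results))

  ## regulatory score across activity classes ----------------------------
  cat_ks <- filter_sets(catalog, universe, 3, 500)
  reg <- activity_profile(cen, st, cat_ks)
  if (!is.null(reg))
    utils::write.table(reg, file.path(out_dir, "regscore.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  logline("regscore", n_rows = if (is.null(reg)) 0L else nrow(reg))

  ## guilt-by-association co-expression ----------------------------------
  ifn <- intersect(ifn_genes_from_catalog(catalog), universe)
  st_gba <- if (is.null(gba_cell_types)) st else
    st[st$cell_type %in% gba_cell_types, ]
  # one pooled family over all cell type x group x culture condition strata
  conds <- gba_conditions(st_gba, condition = NULL)
  conds <- lapply(conds, intersect, samples(cen_all))
  conds <- conds[lengths(conds) >= 3]
  dists <- lapply(conds, function(ids) gba_distance(cen_all, ids, ifn))
  gba <- gba_permutation_test(dists, n_perm = n_perm, seed = seed)
  for (cond in names(gba$union)) {
    sub <- gba$table[gba$table$condition == cond & gba$table$significant, ]
    utils::write.table(sub, file.path(out_dir,
                                      paste0("gba_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gba_ora <- gba_to_ora(gba, catalog, universe)
  keep <- !vapply(gba_ora, is.null, logical(1))
  if (any(keep)) {
    go <- do.call(rbind, lapply(names(gba_ora)[keep], function(cond) {
      o <- gba_ora[[cond]]; o$condition <- cond; o
    }))
    utils::write.table(go, file.path(out_dir, "gba_ora.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  logline("gba", n_conditions = length(conds),
          union_sizes = lengths(gba$union))

  ## gene modules ---------------------------------------------------------
  cl <- kmeans_genes(cen, k = k, n_init = 50, seed = seed, samples_tab = st)
  cl <- select_clusters(cl, 500)
  utils::write.table(
    data.frame(gene = names(cl$assignment), cluster = cl$assignment,
               retained = cl$retained[cl$assignment]),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ann <- annotate_clusters(cl, catalog, universe)
  utils::write.table(ann, file.path(out_dir, "cluster_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("clustering", k = k, retained = sum(cl$retained))

  ## cell-cell communication ---------------------------------------------
  occ <- detect_interactions(rel$matrix, fp_f, st, lr)
  tests <- do.call(rbind, lapply(diseases, function(g) {
    t <- interaction_group_test(occ, "HD", g)
    t$contrast <- paste0("HD-vs-", g); t
  }))
  utils::write.table(tests, file.path(out_dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  comm_genes <- unique(c(lr$ligand, lr$receptor))
  enr_rows <- list()
  for (tag in names(deg_results)) {
    if (!grepl("_relative$", tag)) next
    res <- deg_results[[tag]]
    e <- comm_gene_enrichment(res$gene[res$significant &
                                         res$direction == "up"],
                              res$gene[res$significant &
                                         res$direction == "down"],
                              comm_genes, universe)
    e$contrast <- tag
    enr_rows[[length(enr_rows) + 1L]] <- e
  }
  if (length(enr_rows))
    utils::write.table(do.call(rbind, enr_rows),
                       file.path(out_dir, "comm_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # synthetic signature projection stands in for an external activity model
  target_sets <- catalog$sets[grepl("^(IFN|MODULE)", names(catalog$sets))]
  act <- signature_activity(rel$matrix, target_sets, layer = "stimulated")
  act_rows <- list()
  for (ct in config$cell_types) for (g in diseases) {
    a <- try(compare_activity(act, rel$samples, "HD", g, cell_type = ct),
             silent = TRUE)
    if (inherits(a, "try-error")) next
    a$cell_type <- ct; a$contrast <- paste0("HD-vs-", g)
    act_rows[[length(act_rows) + 1L]] <- a
  }
  if (length(act_rows))
    utils::write.table(do.call(rbind, act_rows),
                       file.path(out_dir, "activity_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  logline("cellcomm", n_pairs = nrow(unique(tests[c("ligand", "receptor")])))

  invisible(list(sim = sim, samples = st, fpkm = fp_f, relative = rel,
                 centralized = cen, deg = deg_results, regscore = reg,
                 gba = gba, clusters = cl, interactions = occ,
                 interaction_tests = tests, pca = pca))
}
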