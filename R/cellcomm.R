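#' Fixed vocabulary of ligand-receptor functional categories
#' @return character vector of the six category labels.
#' @export
lr_categories <- function() {
  c("Cytokines", "TGF", "TNF", "chemokines", "growth factor", "others")
}

#' Validate a ligand-receptor table
#'
#' @param df data.frame with columns `ligand`, `receptor`, `category`
#'   (from the [lr_categories()] vocabulary); (ligand, receptor) pairs
#'   unique.
#' @return the validated data.frame with class `LRTable` prepended.
#' @export
lr_table <- function(df) {
  required <- c("ligand", "receptor", "category")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("LR table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(df$ligand, df$receptor)))
    stop("duplicate (ligand, receptor) pair")
  if (!all(df$category %in% lr_categories()))
    stop("unknown category: ",
         paste(setdiff(df$category, lr_categories()), collapse = ", "))
  class(df) <- c("LRTable", class(df)[class(df) != "LRTable"])
  df
}

#' Donor-level ligand-receptor interaction detection
#'
#' CellPhoneDB-list style co-occurrence: for each donor with a complete set
#' of QC-passing samples (all cell types), each sender (T cells only: Th,
#' CTL), each receiver (all four populations) and each candidate pair, the
#' interaction is detected iff
#' (a) the ligand ranks within the top `ligand_top_fraction` of the
#'     *up-regulated* (positive relative-expression) genes of the sender's
#'     stimulated sample, and
#' (b) the receptor is expressed (FPKM > `receptor_min_fpkm`) in the
#'     receiver's stimulated sample.
#' Pairs whose ligand or receptor is absent from the matrix are skipped.
#'
#' @param relative `ExpressionMatrix` on the relative layer (columns
#'   `<donor>_<cell type>` as produced by [relative_expression()]).
#' @param fpkm_mat `ExpressionMatrix` on the fpkm layer (receptor expression
#'   is looked up in the receiver's aCD3 sample).
#' @param samples_tab a `SampleTable` (the original per-condition table).
#' @param lr an `LRTable`.
#' @param ligand_top_fraction top fraction of up-regulated genes (default
#'   0.10).
#' @param receptor_min_fpkm expression threshold for receptors (default 1).
#' @param senders sender cell types (default `c("Th", "CTL")`).
#' @return an `InteractionOccurrence`: list with `detections` (long
#'   data.frame: sender, receiver, ligand, receptor, category, donor, group,
#'   detected) and `fractions` (per pair x group detected fraction),
#'   plus `donors` (the complete-donor set used).
#' @export
detect_interactions <- function(relative, fpkm_mat, samples_tab, lr,
                                ligand_top_fraction = 0.10,
                                receptor_min_fpkm = 1,
                                senders = c("Th", "CTL")) {
  stopifnot(relative$layer == "relative", fpkm_mat$layer == "fpkm")
  cell_types <- unique(samples_tab$cell_type)
  # donors where all sorted populations passed QC in both layers
  ok <- samples_tab[qc_pass(samples_tab), ]
  acd3 <- ok[ok$condition == "aCD3" & ok$sample_id %in% samples(fpkm_mat), ]
  complete <- vapply(unique(acd3$donor_id), function(d) {
    all(cell_types %in% acd3$cell_type[acd3$donor_id == d]) &&
      all(paste(d, cell_types, sep = "_") %in% samples(relative))
  }, logical(1))
  donors <- unique(acd3$donor_id)[complete]
  if (!length(donors)) stop("no donor with a complete QC-passing sample set")
  donor_group <- ok$group[match(donors, ok$donor_id)]

  g_rel <- genes(relative); g_fp <- genes(fpkm_mat)
  usable <- lr$ligand %in% g_rel & lr$receptor %in% g_fp
  if (any(!usable))
    message(sum(!usable), " LR pair(s) skipped: gene absent from universe")
  lr <- lr[usable, , drop = FALSE]

  # per sender sample: the ligand-rank cutoff among up-regulated genes
  top_set <- function(v) {
    up <- v[v > 0]
    if (!length(up)) return(character())
    n_top <- max(1L, floor(ligand_top_fraction * length(up)))
    names(sort(up, decreasing = TRUE))[seq_len(n_top)]
  }

  rows <- list()
  for (di in seq_along(donors)) {
    d <- donors[di]
    tops <- lapply(stats::setNames(senders, senders), function(s)
      top_set(relative$values[, paste(d, s, sep = "_")]))
    for (recv in cell_types) {
      rs <- acd3$sample_id[acd3$donor_id == d & acd3$cell_type == recv]
      expressed <- g_fp[fpkm_mat$values[, rs] > receptor_min_fpkm]
      for (send in senders) {
        det <- lr$ligand %in% tops[[send]] & lr$receptor %in% expressed
        rows[[length(rows) + 1L]] <- data.frame(
          sender = send, receiver = recv, ligand = lr$ligand,
          receptor = lr$receptor, category = lr$category,
          donor = d, group = donor_group[di], detected = det,
          stringsAsFactors = FALSE)
      }
    }
  }
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  key <- paste(det$sender, det$receiver, det$ligand, det$receptor, det$group)
  frac <- stats::aggregate(detected ~ sender + receiver + ligand + receptor +
                             category + group, det, mean)
  names(frac)[names(frac) == "detected"] <- "fraction"
  structure(list(detections = det, fractions = frac, donors = donors),
            class = "InteractionOccurrence")
}

#' @export
print.InteractionOccurrence <- function(x, ...) {
  cat(sprintf("InteractionOccurrence: %d pairs x %d donors (%d groups)\n",
              nrow(unique(x$detections[c("sender", "receiver", "ligand",
                                         "receptor")])),
              length(x$donors), length(unique(x$detections$group))))
  invisible(x)
}

#' Group comparison of interaction occurrence
#'
#' Per (sender, receiver, ligand, receptor): a two-sided Fisher exact test of
#' the 2x2 detected/not x group table, BH-adjusted across pairs, with the
#' direction (up/down in `group_b`) from the detected-fraction difference.
#'
#' @param occ an `InteractionOccurrence`.
#' @param group_a,group_b donor groups to compare; either side may pool
#'   several groups (e.g. `group_b = c("pSS", "SLE")`, the study's
#'   disease-vs-healthy comparison). Convention: `group_a` = HD.
#' @param alternative `"two.sided"` (default) or a one-sided alternative
#'   passed to [stats::fisher.test()].
#' @return data.frame: sender, receiver, ligand, receptor, category,
#'   det_a/n_a, det_b/n_b, frac_a, frac_b, direction, p, q.
#' @export
interaction_group_test <- function(occ, group_a, group_b,
                                   alternative = "two.sided") {
  det <- occ$detections[occ$detections$group %in% c(group_a, group_b), ]
  if (!length(unique(det$donor[det$group %in% group_a])) ||
      !length(unique(det$donor[det$group %in% group_b])))
    stop("both groups need >= 1 donor")
  key <- paste(det$sender, det$receiver, det$ligand, det$receptor, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- det[key == k, ]
    a <- sub$detected[sub$group %in% group_a]
    b <- sub$detected[sub$group %in% group_b]
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2,
                  dimnames = list(c("det", "not"),
                                  c(paste(group_a, collapse = "+"),
                                    paste(group_b, collapse = "+"))))
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    data.frame(sub[1, c("sender", "receiver", "ligand", "receptor",
                        "category")],
               det_a = sum(a), n_a = length(a), det_b = sum(b),
               n_b = length(b), frac_a = mean(a), frac_b = mean(b),
               direction = ifelse(mean(b) >= mean(a), "up", "down"),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Enrichment of communication genes among regulated genes
#'
#' One-sided Fisher exact test of membership in the communication-gene set
#' (ligands, receptors and cytokine genes of the LR table, intersected with
#' the universe) against membership in the up- (resp. down-) regulated gene
#' list, over the expressed universe.
#'
#' @param up_genes,down_genes regulated gene lists (e.g. significant DEGs by
#'   direction).
#' @param comm_genes communication-related gene set.
#' @param universe expressed-gene universe.
#' @return data.frame with one row per direction: direction, n_regulated,
#'   n_comm, overlap, p (one-sided enrichment).
#' @export
comm_gene_enrichment <- function(up_genes, down_genes, comm_genes, universe) {
  universe <- unique(universe)
  comm <- intersect(unique(comm_genes), universe)
  one <- function(reg, label) {
    reg <- intersect(unique(reg), universe)
    k <- length(intersect(reg, comm))
    tab <- matrix(c(k, length(reg) - k,
                    length(comm) - k,
                    length(universe) - length(reg) - length(comm) + k), 2)
    p <- if (length(reg) == 0) 1 else
      stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(direction = label, n_regulated = length(reg),
               n_comm = length(comm), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }
  rbind(one(up_genes, "up"), one(down_genes, "down"))
}

#' Construct a cytokine-activity Z-score matrix container
#'
#' The pipeline consumes any cytokine x sample activity matrix (e.g. exported
#' from a hosted signature model); the layer tag decides the downstream test
#' family.
#'
#' @param values numeric matrix, cytokines x samples, finite.
#' @param layer `"steady"` or `"stimulated"`.
#' @return an `ActivityMatrix`.
#' @export
activity_matrix <- function(values, layer = c("steady", "stimulated")) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), all(is.finite(values)),
            !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, layer = layer), class = "ActivityMatrix")
}

#' Synthetic signature-projection activity scores
#'
#' A plain stand-in for a hosted cytokine-activity model, for synthetic
#' testing only (NOT a reimplementation of any published scoring model):
#' each cytokine's activity in a sample is the mean expression of its target
#' gene set, Z-scored across samples.
#'
#' @param matrix_ an `ExpressionMatrix` (relative or centralized layer).
#' @param target_sets named list: cytokine -> target gene ids.
#' @param layer layer tag for the resulting `ActivityMatrix`.
#' @return an `ActivityMatrix`.
#' @export
signature_activity <- function(matrix_, target_sets,
                               layer = c("steady", "stimulated")) {
  layer <- match.arg(layer)
  v <- t(vapply(target_sets, function(gs) {
    gs <- intersect(gs, genes(matrix_))
    colMeans(matrix_$values[gs, , drop = FALSE])
  }, numeric(ncol(matrix_$values))))
  v <- t(scale(t(v)))
  v[!is.finite(v)] <- 0
  activity_matrix(v, layer)
}

#' Group comparison of cytokine activities
#'
#' Per cytokine, a two-sided test between two donor groups' activity
#' Z-scores: Student's t-test on the stimulated layer, Wilcoxon rank-sum on
#' the steady layer (whose Z-score distributions are skewed), BH-adjusted
#' across cytokines.
#'
#' @param activity an `ActivityMatrix`.
#' @param samples_tab a `SampleTable` covering the activity columns.
#' @param group_a,group_b donor groups (>= 3 samples each).
#' @param cell_type optional cell-type restriction.
#' @return data.frame: cytokine, test, mean_diff (`group_b - group_a`), p, q.
#' @export
compare_activity <- function(activity, samples_tab, group_a, group_b,
                             cell_type = NULL) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  tab <- samples_tab[qc_pass(samples_tab) &
                       samples_tab$sample_id %in% colnames(activity$values), ]
  if (!is.null(cell_type)) tab <- tab[tab$cell_type == cell_type, ]
  sa <- tab$sample_id[tab$group == group_a]
  sb <- tab$sample_id[tab$group == group_b]
  if (length(sa) < 3 || length(sb) < 3)
    stop("underpowered comparison: need >= 3 samples per group")
  test <- if (activity$layer == "steady") "wilcoxon" else "t"
  res <- t(apply(activity$values, 1, function(v) {
    x <- v[sb]; y <- v[sa]
    p <- if (test == "t") stats::t.test(x, y)$p.value else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    c(mean(x) - mean(y), p)
  }))
  out <- data.frame(cytokine = rownames(activity$values), test = test,
                    mean_diff = res[, 1], p = res[, 2],
                    q = stats::p.adjust(res[, 2], method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
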