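#' Differential expression between donor groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between the two donor groups'
#' values within one cell type, on the layer appropriate to the design:
#' the centralized layer for steady-state contrasts, or the relative layer
#' after stimulation (where the stimulated-vs-control step is already encoded
#' per donor, making this the second step of the two-step contrast).
#' P-values are Benjamini-Hochberg adjusted across genes within the contrast;
#' significance is called at q <= 0.10, with a stricter q <= 0.01 "highly
#' significant" column exported alongside.
#'
#' The exact Wilcoxon null is used when both groups have <= 25 samples and
#' the gene has no cross-group ties; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param matrix_ `ExpressionMatrix` on the centralized or relative layer.
#' @param samples_tab a `SampleTable`; only QC-passing samples are used.
#' @param group_a,group_b donor groups to compare (direction is reported as
#'   up/down in `group_b`, the disease group by convention).
#' @param cell_type cell type defining the contrast stratum.
#' @param condition optional condition restriction (e.g. `"steady"`); by
#'   default all samples of the layer are eligible.
#' @return a `DEGTable` data.frame: gene, contrast, statistic, mean_diff
#'   (mean in `group_b` minus mean in `group_a`), direction, p, q,
#'   significant (q <= 0.1), highly_significant (q <= 0.01).
#' @export
deg_test <- function(matrix_, samples_tab, group_a, group_b, cell_type,
                     condition = NULL) {
  stopifnot(matrix_$layer %in% c("centralized", "relative"))
  tab <- samples_tab[qc_pass(samples_tab) &
                       samples_tab$sample_id %in% samples(matrix_) &
                       samples_tab$cell_type == cell_type, ]
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  sa <- tab$sample_id[tab$group == group_a]
  sb <- tab$sample_id[tab$group == group_b]
  if (length(sa) < 3 || length(sb) < 3)
    stop("underpowered contrast: need >= 3 samples per group, got ",
         length(sa), " vs ", length(sb))
  va <- matrix_$values[, sa, drop = FALSE]
  vb <- matrix_$values[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  exact_ok <- na <= 25 && nb <= 25

  res <- vapply(seq_len(nrow(va)), function(i) {
    x <- vb[i, ]; y <- va[i, ]
    w <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided",
      exact = exact_ok && !any(duplicated(c(x, y))), correct = TRUE))
    c(w$statistic, w$p.value)
  }, numeric(2))

  mean_diff <- rowMeans(vb) - rowMeans(va)
  p <- pmin(res[2, ], 1)
  p[!is.finite(p)] <- 1   # fully tied genes: no evidence either way
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = genes(matrix_),
    contrast = sprintf("%s-vs-%s|%s%s", group_a, group_b, cell_type,
                       if (is.null(condition)) "" else paste0("|", condition)),
    statistic = res[1, ],
    mean_diff = mean_diff,
    direction = ifelse(mean_diff >= 0, "up", "down"),
    p = p, q = q,
    significant = q <= 0.10,
    highly_significant = q <= 0.01,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEGTable", class(out))
  out
}

#' Top genes by false-discovery rate
#'
#' The rank-based hand-off to pathway over-representation: genes are sorted
#' by ascending q, with deterministic tie-breaking by raw p, then by
#' decreasing absolute mean difference, then lexicographic gene id, and the
#' `n_top` best up-regulated and down-regulated genes are returned.
#'
#' @param deg a `DEGTable`.
#' @param n_top list length per direction (study: 50).
#' @return list with `up` and `down` character vectors (each of length
#'   <= `n_top`).
#' @export
rank_by_fdr <- function(deg, n_top = 50) {
  ord <- order(deg$q, deg$p, -abs(deg$mean_diff), deg$gene)
  deg <- deg[ord, ]
  list(up = utils::head(deg$gene[deg$direction == "up"], n_top),
       down = utils::head(deg$gene[deg$direction == "down"], n_top))
}

#' PCA overview of an expression layer
#'
#' Per-gene centered principal component analysis across samples, for the
#' global structure view (condition/cell-type separation, stimulated
#' transcriptome shift) and the PC1-loading hand-off to over-representation.
#'
#' @param matrix_ an `ExpressionMatrix`.
#' @param samples_tab optional `SampleTable` used to annotate scores.
#' @param n_loading number of top-|loading| PC1 genes to export.
#' @return list with `scores` (sample x PC matrix), `explained` (fractions of
#'   variance), `pc1_genes` (top PC1-loading gene ids) and `meta` (aligned
#'   sample annotation, when supplied).
#' @export
pca_overview <- function(matrix_, samples_tab = NULL, n_loading = 100) {
  stopifnot(ncol(matrix_$values) >= 3)
  pc <- stats::prcomp(t(matrix_$values), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  load1 <- pc$rotation[, 1]
  pc1_genes <- names(sort(abs(load1), decreasing = TRUE))
  meta <- NULL
  if (!is.null(samples_tab))
    meta <- samples_tab[match(rownames(pc$x), samples_tab$sample_id), ]
  list(scores = pc$x, explained = expl,
       pc1_genes = utils::head(pc1_genes, n_loading), meta = meta)
}
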