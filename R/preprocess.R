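#' FPKM normalization
#'
#' Fragments Per Kilobase of transcript per Million mapped fragments:
#' `count / (length_kb * total_counts/1e6)`, per sample.
#'
#' @param counts `ExpressionMatrix` on the raw_counts layer.
#' @param gene_lengths named numeric vector of gene lengths in bp; every gene
#'   in `counts` must be present with a positive length.
#' @return `ExpressionMatrix` on the fpkm layer.
#' @export
fpkm <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "raw_counts")
    stop("fpkm() expects the raw_counts layer, got ", counts$layer)
  g <- genes(counts)
  if (!all(g %in% names(gene_lengths)))
    stop("annotation mismatch: missing gene length for ",
         paste(utils::head(setdiff(g, names(gene_lengths))), collapse = ", "))
  len <- gene_lengths[g]
  if (any(len <= 0)) stop("annotation mismatch: non-positive gene length")
  depth <- colSums(counts$values)
  if (any(depth <= 0))
    stop("QC failure: zero-depth sample ",
         paste(samples(counts)[depth <= 0], collapse = ", "))
  v <- counts$values / ((len / 1000) %o% (depth / 1e6))
  em_derive(counts, v, "fpkm", "fpkm")
}

#' Signature-based cell-type QC
#'
#' Simplified BioQC-style check: per sample, each cell-type marker set is
#' scored by a one-sided Wilcoxon rank-sum test of its member genes against
#' all other genes (enrichment = markers rank high). A sample is flagged
#' `signature_mismatch` when its own cell type's marker set is not the
#' top-enriched one, and `low_mapping` when a supplied uniquely-mapped-read
#' fraction falls below `min_mapped_fraction` (study threshold: 50%).
#'
#' @param fpkm `ExpressionMatrix` on the fpkm layer.
#' @param markers `GeneSetCatalog` with one set per declared cell type, named
#'   `MARKERS_<cell type>` (or exactly the cell-type names).
#' @param samples_tab a `SampleTable`.
#' @param min_mapped_fraction threshold on `mapped_fraction`.
#' @param mapped_fraction optional named numeric (per sample id) of
#'   uniquely-mapped read fractions; checked only when provided.
#' @return the `SampleTable` with QC flags added.
#' @export
qc_signature_check <- function(fpkm, markers, samples_tab,
                               min_mapped_fraction = 0.5,
                               mapped_fraction = NULL) {
  cts <- unique(samples_tab$cell_type)
  set_for <- function(ct) {
    nm <- if (paste0("MARKERS_", ct) %in% names(markers$sets))
      paste0("MARKERS_", ct) else ct
    if (!nm %in% names(markers$sets))
      stop("config error: no marker set for cell type ", ct)
    markers$sets[[nm]]
  }
  marker_sets <- lapply(stats::setNames(cts, cts), set_for)
  g <- genes(fpkm)
  bad <- character()
  for (i in seq_len(nrow(samples_tab))) {
    sid <- samples_tab$sample_id[i]
    if (!sid %in% samples(fpkm)) next
    v <- fpkm$values[, sid]
    r <- rank(v)
    # one-sided rank-sum enrichment: larger standardized U = stronger signal
    score <- vapply(marker_sets, function(ms) {
      inset <- g %in% ms
      m <- sum(inset); nn <- sum(!inset)
      if (m == 0 || nn == 0) return(-Inf)
      u <- sum(r[inset]) - m * (m + 1) / 2
      (u - m * nn / 2) / sqrt(m * nn * (m + nn + 1) / 12)
    }, numeric(1))
    if (names(which.max(score)) != samples_tab$cell_type[i])
      bad <- c(bad, sid)
  }
  out <- add_qc_flag(samples_tab, bad, "signature_mismatch")
  if (!is.null(mapped_fraction)) {
    low <- names(mapped_fraction)[mapped_fraction < min_mapped_fraction]
    out <- add_qc_flag(out, low, "low_mapping")
  }
  out
}

#' PCA outlier flagging
#'
#' Principal components are computed over all samples (per-gene centering);
#' a sample is flagged `pca_outlier` when its PC1 or PC2 coordinate lies more
#' than `k_sd` standard deviations from its stratum's (cell type x condition)
#' mean. Mean and SD are computed leaving the assessed sample out — a gross
#' outlier inflates the plain stratum SD enough to hide itself whenever the
#' stratum has fewer than `k_sd^2 + 1` samples. Strata with fewer than 3
#' samples are never flagged.
#'
#' @param matrix_ an `ExpressionMatrix` (any layer).
#' @param samples_tab a `SampleTable` covering the matrix columns.
#' @param k_sd flag threshold in SD units (default 4).
#' @return the `SampleTable` with `pca_outlier` flags added.
#' @export
pca_outlier_flag <- function(matrix_, samples_tab, k_sd = 4) {
  stopifnot(ncol(matrix_$values) >= 3)
  sid <- intersect(samples_tab$sample_id, samples(matrix_))
  x <- t(matrix_$values[, sid, drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)$x
  meta <- samples_tab[match(sid, samples_tab$sample_id), ]
  stratum <- paste(meta$cell_type, meta$condition)
  bad <- character()
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    if (length(rows) < 3) next
    for (j in seq_len(min(2, ncol(pc)))) {
      v <- pc[rows, j]
      for (i in seq_along(v)) {
        rest <- v[-i]
        dev <- abs(v[i] - mean(rest))
        sdv <- stats::sd(rest)
        hit <- if (sdv > 0) dev > k_sd * sdv else dev > 1e-8 && k_sd < Inf
        if (isTRUE(hit)) bad <- c(bad, sid[rows[i]])
      }
    }
  }
  add_qc_flag(samples_tab, unique(bad), "pca_outlier")
}

#' Percentile-based gene filtering
#'
#' Restricts the matrix to protein-coding genes whose total counts (summed
#' across samples) fall within the `[lo_pct, hi_pct]` percentile range of the
#' per-gene totals, with percentiles computed on the coding subset. The
#' percentile is linear interpolation of the empirical CDF (R quantile
#' type 4) with inclusive bounds at both ends, so for totals 1..100 the
#' 45-99.5 band retains totals 45..99. Genes in `keep_genes` (candidate
#' genomic markers) are retained regardless of the band.
#'
#' @param fpkm an `ExpressionMatrix` (typically fpkm; any layer whose row
#'   totals are meaningful).
#' @param coding_genes character vector of protein-coding gene ids; defaults
#'   to all genes.
#' @param lo_pct,hi_pct percentile bounds in [0, 100] (study: 45 and 99.5).
#' @param keep_genes optional gene ids forced into the output.
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(fpkm, coding_genes = NULL, lo_pct = 45,
                         hi_pct = 99.5, keep_genes = character()) {
  stopifnot(lo_pct >= 0, hi_pct <= 100, lo_pct < hi_pct)
  g <- genes(fpkm)
  if (is.null(coding_genes)) coding_genes <- g
  coding <- g[g %in% coding_genes]
  if (!length(coding)) stop("filter too strict: no coding genes present")
  totals <- rowSums(fpkm$values[coding, , drop = FALSE])
  qs <- stats::quantile(totals, c(lo_pct, hi_pct) / 100, type = 4,
                        names = FALSE)
  kept <- coding[totals >= qs[1] & totals <= qs[2]]
  kept <- union(kept, intersect(keep_genes, g))
  if (!length(kept)) stop("filter too strict: no genes retained")
  out <- fpkm[g[g %in% kept], ]
  out$provenance <- c(out$provenance,
                      sprintf("filter_genes[%g,%g]", lo_pct, hi_pct))
  out
}

#' Relative expression of stimulated samples
#'
#' The stimulation layer: each donor/cell-type aCD3 sample is normalized by
#' the same donor's PBS control, `log2((FPKM_aCD3 + pc)/(FPKM_PBS + pc))`.
#' Unpaired aCD3 samples are excluded (recorded in the provenance log).
#'
#' @param fpkm `ExpressionMatrix` on the fpkm layer.
#' @param samples_tab a `SampleTable`; only QC-passing samples are used.
#' @param pseudocount added to both numerator and denominator (default 0.1
#'   FPKM, guarding against zero controls).
#' @return list with `matrix` (`ExpressionMatrix`, relative layer; one column
#'   per donor x cell type, ids `<donor>_<cell type>`) and `samples` (a
#'   `SampleTable` for the derived columns, condition `"aCD3"`).
#' @export
relative_expression <- function(fpkm, samples_tab, pseudocount = 0.1) {
  stopifnot(fpkm$layer == "fpkm")
  ok <- samples_tab[qc_pass(samples_tab) &
                      samples_tab$sample_id %in% samples(fpkm), ]
  a <- ok[ok$condition == "aCD3", ]
  p <- ok[ok$condition == "PBS", ]
  key <- function(df) paste(df$donor_id, df$cell_type, sep = "_")
  pk <- stats::setNames(p$sample_id, key(p))
  paired <- key(a) %in% names(pk)
  dropped <- a$sample_id[!paired]
  a <- a[paired, , drop = FALSE]
  if (!nrow(a)) stop("unpaired samples: no aCD3 sample has a PBS partner")
  va <- fpkm$values[, a$sample_id, drop = FALSE]
  vp <- fpkm$values[, pk[key(a)], drop = FALSE]
  rel <- log2(va + pseudocount) - log2(vp + pseudocount)
  colnames(rel) <- key(a)
  st <- sample_table(data.frame(
    sample_id = key(a), donor_id = a$donor_id, group = a$group,
    cell_type = a$cell_type, condition = "aCD3",
    activity_score = a$activity_score, activity_class = a$activity_class,
    stringsAsFactors = FALSE))
  m <- em_derive(fpkm, rel, "relative",
                 sprintf("relative_expression(pc=%g, unpaired_dropped=%d)",
                         pseudocount, length(dropped)))
  list(matrix = m, samples = st, unpaired = dropped)
}

#' In-sample centralization
#'
#' The steady-state layer: per sample, `(x - median(x)) / sd(x)` (sample SD),
#' which reduces distributional skew when no within-donor negative control
#' exists. After the transform every sample has median 0.
#'
#' @param fpkm `ExpressionMatrix` on the fpkm layer.
#' @return `ExpressionMatrix` on the centralized layer.
#' @export
centralize <- function(fpkm) {
  stopifnot(fpkm$layer == "fpkm")
  med <- apply(fpkm$values, 2, stats::median)
  sdv <- apply(fpkm$values, 2, stats::sd)
  if (any(!is.finite(sdv) | sdv == 0))
    stop("degenerate sample: constant expression in ",
         paste(samples(fpkm)[!is.finite(sdv) | sdv == 0], collapse = ", "))
  v <- sweep(sweep(fpkm$values, 2, med, `-`), 2, sdv, `/`)
  em_derive(fpkm, v, "centralized", "centralize")
}
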