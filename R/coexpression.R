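#' Euclidean distance to interferon-response genes
#'
#' For one experimental condition (a stratum of samples), the Euclidean
#' distance between each interferon gene's centralized expression vector and
#' every other gene's, divided by the square root of the number of samples so
#' strata of unequal size are on one scale. Raw (unnormalized) distances are
#' recoverable by multiplying back.
#'
#' @param matrix_ `ExpressionMatrix` on the centralized layer.
#' @param sample_ids samples making up the condition (>= 3).
#' @param ifn_genes interferon-response gene ids (unexpressed ones are
#'   dropped).
#' @param centroid if `TRUE`, distances are computed to the mean profile of
#'   `ifn_genes` instead of per gene (single pseudo-gene `"<centroid>"`).
#' @return numeric matrix, rows = interferon genes, columns = all other
#'   genes; entry = normalized distance.
#' @export
gba_distance <- function(matrix_, sample_ids, ifn_genes, centroid = FALSE) {
  stopifnot(matrix_$layer %in% c("centralized", "relative"))
  sample_ids <- intersect(sample_ids, samples(matrix_))
  if (length(sample_ids) < 3) stop("condition needs >= 3 samples")
  present <- intersect(ifn_genes, genes(matrix_))
  if (!length(present)) stop("no interferon gene expressed")
  x <- matrix_$values[, sample_ids, drop = FALSE]
  if (centroid) {
    ref <- matrix(colMeans(x[present, , drop = FALSE]), nrow = 1,
                  dimnames = list("<centroid>", sample_ids))
  } else {
    ref <- x[present, , drop = FALSE]
  }
  others <- setdiff(rownames(x), present)
  y <- x[others, , drop = FALSE]
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b, vectorized over all pairs
  cross <- ref %*% t(y)
  d2 <- outer(rowSums(ref^2), rowSums(y^2), `+`) - 2 * cross
  d <- sqrt(pmax(d2, 0)) / sqrt(length(sample_ids))
  d
}

#' Permutation test for co-expression with interferon genes
#'
#' Guilt-by-association: a candidate gene is called co-expressed with a given
#' interferon gene, in a given condition, when its observed distance is
#' significantly lower than distances drawn from the pooled distance
#' distribution of all genes across all conditions (the stated comparator).
#' The null is `n_perm` draws with replacement from that pool per interferon
#' gene; `p = (1 + #draws <= d) / (1 + n_perm)` (finite-sample corrected),
#' BH-adjusted across candidates within (condition, interferon gene),
#' significant at q <= 0.10.
#'
#' @param distances named list of distance matrices (one per condition, from
#'   [gba_distance()]; identical row sets).
#' @param n_perm number of permutation draws (>= 100; study: 10,000).
#' @param seed integer seed for the draws.
#' @param scale_normalize divide each condition's distances (per interferon
#'   gene) by their median before pooling (default `TRUE`). Conditions can
#'   carry systematically different centralized scales — stimulation
#'   inflates the per-sample SD, compressing every distance in the stratum —
#'   and without a per-condition scale correction the compressed strata
#'   flood the pooled null's low tail.
#' @return a `GBAResult`: list with `table` (long data.frame: condition,
#'   ifn_gene, gene, distance (raw), norm_distance (the pooled quantity), p,
#'   q, significant) and `union` (named list, per condition the union of
#'   significant candidates over interferon genes).
#' @export
gba_permutation_test <- function(distances, n_perm = 10000, seed = 1,
                                 scale_normalize = TRUE) {
  if (n_perm < 100) stop("underpowered null: n_perm must be >= 100")
  stopifnot(length(distances) >= 1, !is.null(names(distances)))
  set.seed(seed)
  ifn <- rownames(distances[[1]])
  norm <- if (scale_normalize)
    lapply(distances, function(d) d / apply(d, 1, stats::median))
  else distances
  rows <- list()
  for (g in ifn) {
    pooled <- unlist(lapply(norm, function(d) d[g, ]), use.names = FALSE)
    draws <- sort(sample(pooled, n_perm, replace = TRUE))
    for (cond in names(distances)) {
      d <- norm[[cond]][g, ]
      cnt <- findInterval(d, draws)     # #draws <= d (draws sorted)
      p <- (1 + cnt) / (1 + n_perm)
      q <- stats::p.adjust(p, method = "BH")
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, ifn_gene = g, gene = names(d),
        distance = unname(distances[[cond]][g, ]),
        norm_distance = unname(d), p = unname(p), q = unname(q),
        significant = unname(q <= 0.10), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  un <- lapply(stats::setNames(names(distances), names(distances)),
               function(cond)
                 sort(unique(tab$gene[tab$condition == cond &
                                        tab$significant])))
  structure(list(table = tab, union = un, n_perm = n_perm),
            class = "GBAResult")
}

#' @export
print.GBAResult <- function(x, ...) {
  cat(sprintf("GBAResult: %d conditions, %d IFN genes, n_perm=%d\n",
              length(x$union), length(unique(x$table$ifn_gene)), x$n_perm))
  for (cond in names(x$union))
    cat(sprintf("  %s: %d significant candidates\n", cond,
                length(x$union[[cond]])))
  invisible(x)
}

#' Over-representation of the co-expressed union
#'
#' Per condition, the union of significant guilt-by-association candidates is
#' used as the query of a hypergeometric over-representation analysis.
#'
#' @param result a `GBAResult`.
#' @param catalog a `GeneSetCatalog`.
#' @param universe expressed-gene universe.
#' @param ... passed to [ora()] (size bounds).
#' @return named list of `ORAResult` per condition (`NULL` where the union is
#'   empty, recorded with a message).
#' @export
gba_to_ora <- function(result, catalog, universe, ...) {
  lapply(result$union, function(u) {
    u <- intersect(u, universe)
    if (!length(u)) {
      message("empty co-expression union; skipping over-representation")
      return(NULL)
    }
    ora(u, catalog, universe, ...)
  })
}

#' Experimental conditions for guilt-by-association
#'
#' Builds the sample groupings ("conditions") the permutation test contrasts
#' against the pooled distance distribution: cell type x donor group, split
#' further by culture condition when `condition = NULL` (the default
#' restricts to one culture condition). The pooled null is only calibrated
#' when conditions have comparable sample sizes — distances from very small
#' strata have a heavy low tail that would flood the pool — so
#' activity-class resolution is deliberately not offered here; activity
#' trajectories are the regulatory score's job. Condition names look like
#' `Th_SLE` or `Th_SLE_steady`.
#'
#' @param samples_tab a `SampleTable` (QC-passing samples only are used).
#' @param condition culture condition to restrict to (e.g. `"steady"`);
#'   `NULL` keeps all and adds the culture condition to the stratum key.
#' @param min_samples conditions with fewer samples are dropped.
#' @return named list of sample-id character vectors.
#' @export
gba_conditions <- function(samples_tab, condition = NULL, min_samples = 3) {
  tab <- samples_tab[qc_pass(samples_tab), ]
  if (!is.null(condition)) {
    tab <- tab[tab$condition == condition, ]
    key <- paste(tab$cell_type, tab$group, sep = "_")
  } else {
    key <- paste(tab$cell_type, tab$group, tab$condition, sep = "_")
  }
  out <- split(tab$sample_id, key)
  out[lengths(out) >= min_samples]
}

#' Select interferon gene sets from a catalog by name
#'
#' Mirrors the "selected IFN response gene-sets" step: all catalog entries
#' whose name matches `pattern` contribute their genes.
#'
#' @param catalog a `GeneSetCatalog`.
#' @param pattern regular expression (default `"IFN|INTERFERON"`,
#'   case-insensitive).
#' @return character vector of interferon-response gene ids.
#' @export
ifn_genes_from_catalog <- function(catalog, pattern = "IFN|INTERFERON") {
  hits <- grepl(pattern, names(catalog$sets), ignore.case = TRUE)
  sort(unique(unlist(catalog$sets[hits], use.names = FALSE)))
}
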