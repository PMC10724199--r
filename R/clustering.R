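#' Per-stratum mean feature matrix for gene clustering
#'
#' Genes are clustered on their mean expression per stratum (cell type x
#' donor group by default), matching the column blocks of the module
#' heatmaps.
#'
#' @param matrix_ an `ExpressionMatrix`.
#' @param samples_tab a `SampleTable`; only QC-passing samples are used.
#' @param by columns of the sample table defining a stratum.
#' @return numeric matrix, genes x strata.
#' @export
stratum_means <- function(matrix_, samples_tab,
                          by = c("cell_type", "group")) {
  tab <- samples_tab[qc_pass(samples_tab) &
                       samples_tab$sample_id %in% samples(matrix_), ]
  key <- do.call(paste, c(tab[by], sep = "|"))
  strata <- unique(key)
  out <- sapply(strata, function(s)
    rowMeans(matrix_$values[, tab$sample_id[key == s], drop = FALSE]))
  colnames(out) <- strata
  out
}

# k-means++ seeding: spread initial centers proportionally to squared
# distance from the nearest already-chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' k-means gene-module detection
#'
#' Best-of-`n_init` k-means (k-means++ seeding, Euclidean distance on
#' per-stratum mean profiles) by total within-cluster sum of squares;
#' deterministic given `seed`. Feature rows are standardized by default
#' (mean 0, SD 1 per gene, the usual heatmap convention), so modules are
#' defined by profile *shape* across strata rather than by absolute
#' expression level; constant-profile genes are left at zero. Cluster labels
#' are arbitrary — downstream reporting is by gene membership.
#'
#' @param matrix_ an `ExpressionMatrix`, or a precomputed gene x feature
#'   matrix (e.g. from [stratum_means()]).
#' @param k number of clusters (>= 2, <= number of genes).
#' @param n_init number of k-means++ restarts (default 50).
#' @param seed integer seed.
#' @param samples_tab required when `matrix_` is an `ExpressionMatrix`; used
#'   to build the per-stratum features.
#' @param by stratum definition, see [stratum_means()].
#' @param scale_rows standardize each gene's feature vector (default `TRUE`).
#' @return a `ClusterResult`: list with `assignment` (named integer),
#'   `sizes`, `centers`, `tot_withinss`, `retained` (set by
#'   [select_clusters()]; initialized all `TRUE`).
#' @export
kmeans_genes <- function(matrix_, k, n_init = 50, seed = 1,
                         samples_tab = NULL, by = c("cell_type", "group"),
                         scale_rows = TRUE) {
  feats <- if (inherits(matrix_, "ExpressionMatrix")) {
    if (is.null(samples_tab))
      stop("samples_tab is required to build per-stratum features")
    stratum_means(matrix_, samples_tab, by)
  } else matrix_
  if (k < 2) stop("invalid k: need k >= 2")
  if (k > nrow(feats)) stop("invalid k: more clusters than genes")
  if (scale_rows) {
    feats <- t(scale(t(feats)))
    feats[!is.finite(feats)] <- 0
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    cen <- kmeanspp_centers(feats, k)
    km <- suppressWarnings(stats::kmeans(feats, centers = cen,
                                         iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  assignment <- stats::setNames(best$cluster, rownames(feats))
  sizes <- as.integer(table(factor(assignment, levels = seq_len(k))))
  structure(list(assignment = assignment, sizes = sizes,
                 centers = best$centers, tot_withinss = best$tot.withinss,
                 retained = rep(TRUE, k), k = k),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k=%d, sizes %s, retained %d/%d\n",
              x$k, paste(x$sizes, collapse = "/"), sum(x$retained), x$k))
  invisible(x)
}

#' Cluster-size selection
#'
#' The study's heuristic: only clusters with fewer than `max_size` genes are
#' carried into pathway annotation (strictly less than; a 500-gene cluster is
#' dropped, a 499-gene cluster retained).
#'
#' @param result a `ClusterResult`.
#' @param max_size exclusive size ceiling (default 500).
#' @return the `ClusterResult` with its `retained` flags updated.
#' @export
select_clusters <- function(result, max_size = 500) {
  result$retained <- result$sizes < max_size
  if (!any(result$retained))
    warning("no cluster below ", max_size, " genes; retained set is empty")
  result
}

#' Marker-based cluster annotation
#'
#' Automated assist for labelling modules: each retained cluster is tested by
#' hypergeometric over-representation against a marker catalog; the top label
#' (smallest p) is reported with its q-value. Final biological labels remain
#' a manual call.
#'
#' @param result a `ClusterResult` (after [select_clusters()]).
#' @param markers a `GeneSetCatalog` of marker sets.
#' @param universe expressed-gene universe.
#' @param ... passed to [ora()].
#' @return data.frame: cluster, size, retained, top_label, p, q (`NA` label
#'   where no retained cluster or no catalog overlap).
#' @export
annotate_clusters <- function(result, markers, universe, ...) {
  out <- list()
  for (cl in seq_len(result$k)) {
    if (!result$retained[cl]) next
    members <- names(result$assignment)[result$assignment == cl]
    res <- suppressWarnings(ora(members, markers, universe, ...))
    best <- res[order(res$p, res$set), ][1, ]
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, size = result$sizes[cl], retained = TRUE,
      top_label = best$set, p = best$p, q = best$q,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = integer(), size = integer(),
                      retained = logical(), top_label = character(),
                      p = numeric(), q = numeric()))
  do.call(rbind, out)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovered gene modules against planted ones.
#'
#' @param a,b integer/character vectors of cluster labels, same length and
#'   names-aligned when named.
#' @return the adjusted Rand index in [-1, 1]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
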