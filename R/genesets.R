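#' GMT gene-set I/O
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member genes. `write_gmt` followed by `read_gmt` is the identity (line
#' order preserved).
#'
#' @param path file path.
#' @param catalog a `GeneSetCatalog`.
#' @return `read_gmt` returns a `GeneSetCatalog`; `write_gmt` returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("parse error in ", basename(path), " line ", i,
           ": expected >= 3 tab-separated fields")
    nm <- f[1]
    if (nm %in% names(sets))
      stop("parse error in ", basename(path), " line ", i,
           ": duplicate set name '", nm, "'")
    sets[[nm]] <- f[-(1:2)]
    desc[nm] <- f[2]
  }
  gene_set_catalog(sets, desc, provenance = basename(path))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, catalog$description[[nm]], catalog$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a catalog to an expressed universe and size bounds
#'
#' Sets are first intersected with the expressed-gene universe, then sets
#' with fewer than `min_size` or more than `max_size` in-universe members are
#' removed. The study uses 3-500 for the KS regulatory score and 3-300 for
#' over-representation (where undersized/oversized sets are instead retained
#' with p forced to 1; see [ora()]).
#'
#' @param catalog a `GeneSetCatalog`.
#' @param universe character vector of expressed gene ids.
#' @param min_size,max_size inclusive size bounds after universe reduction.
#' @return the filtered `GeneSetCatalog`.
#' @export
filter_sets <- function(catalog, universe, min_size = 3, max_size = 500) {
  stopifnot(min_size > 0, max_size >= min_size)
  red <- lapply(catalog$sets, function(g) intersect(g, universe))
  keep <- lengths(red) >= min_size & lengths(red) <= max_size
  gene_set_catalog(red[keep], catalog$description[names(red)[keep]],
                   provenance = catalog$provenance)
}

#' Hypergeometric over-representation analysis
#'
#' For each catalog set (reduced to the expressed universe), the upper-tail
#' hypergeometric probability of observing at least the seen overlap with the
#' query: population = universe, successes = in-universe set size, draws =
#' query size. Sets whose in-universe size is below `min_size` or above
#' `max_size` get p set to 1 exactly (the study's 3-300 rule, applied to the
#' pathway set, the query being fixed-size by construction). BH adjustment
#' runs across the sets within size bounds; forced sets carry q = 1.
#'
#' @param query character vector of query genes (genes outside the universe
#'   are dropped with a warning).
#' @param catalog a `GeneSetCatalog`.
#' @param universe expressed-gene universe.
#' @param min_size,max_size size bounds for the forced-p rule.
#' @return an `ORAResult` data.frame: set, set_size (in-universe), overlap,
#'   query_size, universe_size, p, q, forced.
#' @export
ora <- function(query, catalog, universe, min_size = 3, max_size = 300) {
  if (!length(universe)) stop("upstream failure: empty universe")
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  query <- unique(query)
  N <- length(universe); n <- length(query)
  red <- lapply(catalog$sets, function(g) intersect(unique(g), universe))
  K <- lengths(red)
  k <- vapply(red, function(g) length(intersect(g, query)), integer(1))
  forced <- K < min_size | K > max_size
  p <- ifelse(forced, 1,
              stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  q <- rep(1, length(p))
  q[!forced] <- stats::p.adjust(p[!forced], method = "BH")
  out <- data.frame(set = names(catalog$sets), set_size = unname(K),
                    overlap = unname(k), query_size = n, universe_size = N,
                    p = unname(p), q = unname(q), forced = unname(forced),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ORAResult", class(out))
  out
}

#' Disease-activity classification
#'
#' Maps a clinical disease-activity index (ESSDAI for pSS, SLEDAI for SLE)
#' to the three-level class used throughout the activity-stratified
#' analyses: Low for scores 1-3, Moderate for 4 up to (exclusive)
#' `high_cutoff`, High for `high_cutoff` and above. A score of 0 is classed
#' Low and flagged, the clinical definition starting at 1.
#'
#' @param score non-negative integer index value.
#' @param high_cutoff first score classed High (default 8, inclusive).
#' @return list with `score`, `class` (`"Low"|"Moderate"|"High"`) and
#'   `zero_score` flag.
#' @export
classify_activity <- function(score, high_cutoff = 8) {
  if (is.na(score) || score < 0) stop("activity score must be >= 0")
  cls <- if (score >= high_cutoff) "High" else if (score >= 4) "Moderate"
  else "Low"
  list(score = as.integer(score), class = cls, zero_score = score == 0)
}

#' Signed Kolmogorov-Smirnov regulatory score
#'
#' The gene-set activity measure: the maximal difference between the
#' empirical CDFs of the set's per-gene values and the background's (all
#' universe genes not in the set), signed positive when the set is
#' stochastically larger (its CDF lies below the background's at the
#' maximizing threshold). The one-sided p-value for the observed enrichment
#' direction uses the asymptotic bound `exp(-2 D^2 mn/(m+n))`.
#'
#' @param values named numeric vector: one scalar per gene (e.g. the
#'   stratum-mean centralized expression).
#' @param set_genes gene ids of the set (reduced to `names(values)`).
#' @param background optional background gene ids; default all other genes.
#' @return list with `D` (signed, |D| <= 1), `abs_D`, `p` (one-sided),
#'   `n_set`, `n_background`.
#' @export
ks_regscore <- function(values, set_genes, background = NULL) {
  if (length(unique(values)) < 2)
    stop("no variation: degenerate (constant) profile")
  g <- names(values)
  set_genes <- intersect(set_genes, g)
  if (is.null(background)) background <- setdiff(g, set_genes)
  background <- setdiff(intersect(background, g), set_genes)
  xs <- values[set_genes]; xb <- values[background]
  m <- length(xs); nb <- length(xb)
  if (m < 1 || nb < 1) stop("empty set or background after reduction")
  # signed max CDF difference over the pooled thresholds
  thr <- sort(unique(c(xs, xb)))
  Fs <- findInterval(thr, sort(xs)) / m
  Fb <- findInterval(thr, sort(xb)) / nb
  diffs <- Fb - Fs                       # >0 where the set sits higher
  i <- which.max(abs(diffs))
  D <- diffs[i]
  p <- exp(-2 * D^2 * m * nb / (m + nb))
  list(D = unname(D), abs_D = abs(unname(D)), p = min(1, p),
       n_set = m, n_background = nb)
}

#' Activity-stratified regulatory profile
#'
#' For every stratum (donor group x cell type x activity class, patients
#' only), per-gene values are the mean centralized expression across the
#' stratum's samples, and each catalog set is scored with the signed KS
#' regulatory score against the rest of the universe. Rows are ordered
#' Low -> Moderate -> High within each set/group/cell type so activity
#' trajectories (monotone rise vs bell shape) read off directly.
#'
#' @param matrix_ `ExpressionMatrix` on the centralized layer.
#' @param samples_tab a `SampleTable`; healthy donors (no activity score) are
#'   excluded from activity strata.
#' @param catalog a `GeneSetCatalog` (pre-filter with [filter_sets()], study
#'   bounds 3-500).
#' @param condition optional condition restriction (default `"steady"`).
#' @return a `RegScore` data.frame: set, group, cell_type, activity_class,
#'   n_samples, D, abs_D, p, q (BH within group x cell type).
#' @export
activity_profile <- function(matrix_, samples_tab, catalog,
                             condition = "steady") {
  stopifnot(matrix_$layer == "centralized")
  tab <- samples_tab[qc_pass(samples_tab) &
                       samples_tab$sample_id %in% samples(matrix_) &
                       !is.na(samples_tab$activity_class), ]
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  classes <- c("Low", "Moderate", "High")
  out <- list()
  for (grp in unique(tab$group)) for (ct in unique(tab$cell_type)) {
    for (cl in classes) {
      sel <- tab$group == grp & tab$cell_type == ct &
        tab$activity_class == cl
      if (!any(sel)) next
      prof <- rowMeans(matrix_$values[, tab$sample_id[sel], drop = FALSE])
      for (nm in names(catalog$sets)) {
        ks <- ks_regscore(prof, catalog$sets[[nm]])
        out[[length(out) + 1L]] <- data.frame(
          set = nm, group = grp, cell_type = ct, activity_class = cl,
          n_samples = sum(sel), D = ks$D, abs_D = ks$abs_D, p = ks$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (key in unique(paste(res$group, res$cell_type))) {
    i <- paste(res$group, res$cell_type) == key
    res$q[i] <- stats::p.adjust(res$p[i], method = "BH")
  }
  res$activity_class <- factor(res$activity_class, levels = classes)
  res <- res[order(res$set, res$group, res$cell_type, res$activity_class), ]
  rownames(res) <- NULL
  class(res) <- c("RegScore", class(res))
  res
}

#' Driver genes of an activity trajectory
#'
#' Within a gene set, each gene's sensitivity is the maximal absolute change
#' of its stratum-mean centered expression between consecutive activity
#' classes (Low->Moderate, Moderate->High); the top `top_fraction` of set
#' genes by sensitivity are returned.
#'
#' @param matrix_ `ExpressionMatrix` on the centralized layer.
#' @param samples_tab a `SampleTable` (patients with activity classes).
#' @param set_genes gene ids of the set of interest.
#' @param top_fraction fraction of set genes to return (default 0.10;
#'   at least one gene).
#' @param condition optional condition restriction (default `"steady"`).
#' @return character vector of driver gene ids, ordered by decreasing
#'   sensitivity; the `sensitivity` attribute carries the full named vector.
#' @export
driver_genes <- function(matrix_, samples_tab, set_genes,
                         top_fraction = 0.10, condition = "steady") {
  tab <- samples_tab[qc_pass(samples_tab) &
                       samples_tab$sample_id %in% samples(matrix_) &
                       !is.na(samples_tab$activity_class), ]
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  classes <- intersect(c("Low", "Moderate", "High"),
                       unique(tab$activity_class))
  if (length(classes) < 2)
    stop("need >= 2 populated activity classes")
  set_genes <- intersect(set_genes, genes(matrix_))
  means <- sapply(classes, function(cl)
    rowMeans(matrix_$values[set_genes,
                            tab$sample_id[tab$activity_class == cl],
                            drop = FALSE]))
  sens <- apply(abs(means[, -1, drop = FALSE] -
                      means[, -length(classes), drop = FALSE]), 1, max)
  n_top <- max(1L, ceiling(top_fraction * length(set_genes)))
  ord <- order(-sens, names(sens))
  out <- names(sens)[ord][seq_len(min(n_top, length(sens)))]
  attr(out, "sensitivity") <- sens[ord]
  out
}
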