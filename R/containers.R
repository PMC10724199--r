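#' Expression matrix with a layer tag
#'
#' The central container of the pipeline: a dense gene x sample numeric
#' matrix together with a `layer` tag recording which normalization stage the
#' values represent, and a provenance log of the transformations applied.
#' Raw counts and FPKM values must be non-negative; the relative
#' (log2 stimulated/control) and centralized ((x - median)/SD) layers are
#' real-valued.
#'
#' @param values numeric matrix with gene ids as rownames and sample ids as
#'   colnames; no duplicates, all values finite.
#' @param layer one of `"raw_counts"`, `"fpkm"`, `"relative"`, `"centralized"`.
#' @param provenance character vector of transformation records; grown by each
#'   layer transition.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values,
                              layer = c("raw_counts", "fpkm", "relative",
                                        "centralized"),
                              provenance = character()) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("non-finite expression values")
  if (layer %in% c("raw_counts", "fpkm") && any(values < 0))
    stop("raw_counts/fpkm layers must be non-negative")
  structure(list(values = values, layer = layer, provenance = provenance),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  if (length(x$provenance))
    cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Gene ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of gene ids.
#' @export
genes <- function(x) rownames(x$values)

#' Sample ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of sample ids.
#' @export
samples <- function(x) colnames(x$values)

# internal: derive a new matrix in a different layer, appending provenance
em_derive <- function(x, values, layer, step) {
  expression_matrix(values, layer,
                    provenance = c(x$provenance, step))
}

#' Subset an ExpressionMatrix
#'
#' @param x an `ExpressionMatrix`.
#' @param i gene selector (character, integer or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @return the subsetted `ExpressionMatrix` (layer and provenance preserved).
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  structure(list(values = v, layer = x$layer, provenance = x$provenance),
            class = "ExpressionMatrix")
}

#' Validate and normalize a sample metadata table
#'
#' The sample table describes each sequencing sample: its donor, donor group
#' (HD, pSS, SLE), sorted cell type (Th, CTL, NK, B), culture condition
#' (steady, aCD3, PBS), the donor's clinical disease-activity score
#' (ESSDAI/SLEDAI; `NA` for healthy donors) and derived activity class, plus
#' accumulated QC flags. Each (donor, cell type, condition) combination may
#' occur at most once.
#'
#' @param df data.frame with columns `sample_id`, `donor_id`, `group`,
#'   `cell_type`, `condition`; optional `activity_score`, `activity_class`,
#'   `qc_flags`.
#' @return the validated data.frame with class `SampleTable` prepended.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "donor_id", "group", "cell_type", "condition")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids")
  key <- paste(df$donor_id, df$cell_type, df$condition)
  if (anyDuplicated(key))
    stop("more than one sample for a (donor, cell type, condition)")
  if (!"activity_score" %in% names(df)) df$activity_score <- NA_integer_
  if (!"activity_class" %in% names(df)) df$activity_class <- NA_character_
  if (!"qc_flags" %in% names(df)) df$qc_flags <- ""
  class(df) <- c("SampleTable", class(df)[class(df) != "SampleTable"])
  df
}

#' Add a QC flag to selected samples
#'
#' @param st a `SampleTable`.
#' @param sample_ids samples to flag.
#' @param flag flag label, e.g. `"signature_mismatch"`.
#' @return the updated `SampleTable`.
#' @export
add_qc_flag <- function(st, sample_ids, flag) {
  idx <- st$sample_id %in% sample_ids
  st$qc_flags[idx] <- ifelse(st$qc_flags[idx] == "", flag,
                             paste(st$qc_flags[idx], flag, sep = ";"))
  st
}

#' Which samples pass QC (carry no flags)?
#' @param st a `SampleTable`.
#' @return logical vector aligned with the rows of `st`.
#' @export
qc_pass <- function(st) st$qc_flags == "" | is.na(st$qc_flags)

#' Construct a gene-set catalog
#'
#' Named gene lists with GMT semantics (name, description, member genes) and a
#' provenance string, as used for pathway over-representation and the KS
#' regulatory score.
#'
#' @param sets named list of character vectors (unique set names; non-empty
#'   gene ids).
#' @param description named character vector of set descriptions (recycled to
#'   `""` when absent).
#' @param provenance free-text origin of the catalog.
#' @return An object of class `GeneSetCatalog`.
#' @export
gene_set_catalog <- function(sets, description = NULL, provenance = "") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name")
  if (any(vapply(sets, function(g) any(!nzchar(g)), logical(1))))
    stop("empty gene id in a set")
  if (is.null(description)) {
    description <- rep("", length(sets))
    names(description) <- names(sets)
  }
  structure(list(sets = sets,
                 description = description[names(sets)],
                 provenance = provenance),
            class = "GeneSetCatalog")
}

#' @export
length.GeneSetCatalog <- function(x) length(x$sets)

#' @export
names.GeneSetCatalog <- function(x) names(x$sets)

#' @export
print.GeneSetCatalog <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("GeneSetCatalog: %d sets (sizes %s..%s)%s\n",
              length(x$sets),
              if (length(sizes)) min(sizes) else "-",
              if (length(sizes)) max(sizes) else "-",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Read / write an ExpressionMatrix as TSV
#'
#' Plain-text interchange used by the command-line entry points: rows are
#' genes, the first column is `gene_id`, remaining columns are sample ids.
#'
#' @param x an `ExpressionMatrix`.
#' @param path file path.
#' @param layer layer tag to attach on read.
#' @return `read_expression_tsv` returns an `ExpressionMatrix`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, layer = "raw_counts") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, layer, provenance = paste0("read:", basename(path)))
}
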