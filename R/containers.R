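# Domain containers.
#
# Light S3 wrappers around base matrices: an ExpressionMatrix is gene x
# sample with per-sample metadata (genotype, group, animal) and an explicit
# scale flag; a CountMatrix is cell x gene integer UMIs with per-cell
# metadata; a GeneSet is a named gene list with optional boolean labels.

#' Construct an ExpressionMatrix
#'
#' @param values gene x sample numeric matrix, non-negative, with unique
#'   rownames (gene ids) and colnames (sample ids).  Units are either linear
#'   expression or log2(expression + 1), recorded in `scale`.
#' @param sample_meta data.frame with columns `sample_id`, `genotype`
#'   (one of KO, HE, WT), `group` (tissue or cell-type label), `animal`.
#'   Every sample in `values` must have a row.
#' @param scale "linear" or "log2".
#' @return object of class `expression_matrix` with elements `values`,
#'   `sample_meta` (ordered as the columns), `scale`.
#' @export
expression_matrix <- function(values, sample_meta, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite (no NaN/NA)")
  if (any(values < 0)) stop("expression values must be non-negative")
  sample_meta <- as.data.frame(sample_meta)
  need <- c("sample_id", "genotype", "group", "animal")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) stop("sample_meta missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(absent))
    stop("samples without metadata: ", paste(absent, collapse = ", "))
  bad <- setdiff(unique(sample_meta$genotype), c("KO", "HE", "WT"))
  if (length(bad)) stop("genotype must be KO, HE or WT; got: ", paste(bad, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("genotypes:", paste(names(table(x$sample_meta$genotype)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a CountMatrix
#'
#' @param counts cell x gene matrix of non-negative integers (UMIs); dense
#'   matrix or Matrix sparse matrix, with unique cell rownames and gene
#'   colnames.
#' @param cell_meta data.frame with columns `cell_id`, `cell_type`,
#'   `genotype`, `animal`; every cell must have a row.
#' @return object of class `count_matrix` with elements `counts`,
#'   `cell_meta` (ordered as the rows).
#' @export
count_matrix <- function(counts, cell_meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts need cell rownames and gene colnames")
  if (anyDuplicated(rownames(counts))) stop("cell ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("gene ids must be unique")
  vals <- if (inherits(counts, "Matrix")) counts@x else as.vector(counts)
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("counts must be non-negative integers")
  cell_meta <- as.data.frame(cell_meta)
  need <- c("cell_id", "cell_type", "genotype", "animal")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stop("cell_meta missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(rownames(counts), cell_meta$cell_id)
  if (length(absent))
    stop("cells without metadata: ", paste(utils::head(absent, 5), collapse = ", "))
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  print(table(x$cell_meta$cell_type, x$cell_meta$genotype))
  invisible(x)
}

#' Construct a GeneSet
#'
#' @param name set name.
#' @param genes character vector of gene ids (must be unique).
#' @param labels optional named logical vector keyed by member genes, e.g.
#'   a `tonic_sensitive` flag.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, labels = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("genes must be unique within a set")
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !all(names(labels) %in% genes))
      stop("labels must be named by member genes only")
    labels <- stats::setNames(as.logical(labels), names(labels))
  }
  structure(list(name = name, genes = genes, labels = labels), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$labels)) "" else sprintf(" (%d labeled)", length(x$labels))))
  invisible(x)
}

# Accept an expression_matrix or a plain gene x sample matrix.
.as_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}
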