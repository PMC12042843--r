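# Readers and writers for the on-disk formats.
#
# Single-cell counts travel as a MatrixMarket triplet directory
# (matrix.mtx + features.tsv + barcodes.tsv) following the gene-expression
# convention of features-as-rows on disk and cells-as-rows in memory.
# Bulk matrices and all tabular outputs are TSV with a header row; gene
# sets are GMT.  Gene identifiers are opaque case-sensitive strings.

#' Read a single-cell count matrix from a MatrixMarket triplet directory
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param meta_path TSV with columns `cell_id` (or `barcode`), `cell_type`,
#'   `genotype`, `animal`, keyed by barcode.
#' @return a [count_matrix] with cells as rows regardless of on-disk
#'   orientation (orientation inferred from the barcode count; the
#'   features-as-rows convention wins for square matrices).
#' @export
read_count_matrix <- function(dir, meta_path) {
  mtx_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path))
    if (!file.exists(p)) stop("format error: missing file ", p)
  mtx_lines <- readLines(mtx_path)
  body <- mtx_lines[!startsWith(mtx_lines, "%") & nzchar(trimws(mtx_lines))]
  declared <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
  if (length(declared) >= 3 && length(body) - 1L != declared[3])
    stop(sprintf("format error in %s: header declares %d entries but file contains %d",
                 mtx_path, declared[3], length(body) - 1L))
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("format error in ", mtx_path, ": ",
                                         conditionMessage(e)))
  features <- read.delim(feat_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(bc_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # disk convention: features as rows
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # already cells x genes
  } else {
    bad <- if (nrow(m) != length(features) && nrow(m) != length(barcodes))
      feat_path else bc_path
    stop(sprintf("format error: matrix is %d x %d but features=%d, barcodes=%d (check %s)",
                 nrow(m), ncol(m), length(features), length(barcodes), bad))
  }
  dimnames(m) <- list(barcodes, features)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if ("barcode" %in% names(meta) && !"cell_id" %in% names(meta))
    names(meta)[names(meta) == "barcode"] <- "cell_id"
  missing_bc <- setdiff(barcodes, meta$cell_id)
  if (length(missing_bc))
    stop("metadata error: barcodes absent from meta: ",
         paste(utils::head(missing_bc, 10), collapse = ", "))
  count_matrix(m, meta)
}

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' @param cm a [count_matrix].
#' @param dir output directory (created if needed).
#' @param meta_path optional path for the cell metadata TSV (default
#'   `meta.tsv` inside `dir`).
#' @return invisibly, `dir`.
#' @export
write_count_matrix <- function(cm, dir, meta_path = file.path(dir, "meta.tsv")) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(cm$counts, sparse = TRUE)),
                               "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(cm$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(cm$counts), file.path(dir, "barcodes.tsv"))
  write.table(cm$cell_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bulk expression matrix from TSV
#'
#' @param path gene x sample TSV; first column gene id, header row of sample
#'   ids.  Lines starting with `#` are ignored.
#' @param meta_path sample metadata TSV (`sample_id`, `genotype`, `group`,
#'   `animal`).
#' @param scale "linear" or "log2".
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(path, meta_path, scale = c("linear", "log2")) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  meta <- read.delim(meta_path, comment.char = "#", stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = match.arg(scale))
}

#' Write a bulk expression matrix to TSV
#'
#' @param expr an [expression_matrix].
#' @param path output TSV path for values.
#' @param meta_path output TSV path for sample metadata.
#' @param header optional character vector of `#`-prefixed header lines.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path, meta_path, header = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' description field is discarded and duplicate genes within a line are
#' deduplicated with a warning.
#'
#' @param path GMT path.
#' @return list of [gene_set] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("format error: GMT line %d has %d fields (need name, description, >=1 gene)",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s' (line %d): duplicate genes deduplicated",
                      fields[1], i))
      at_log("read_gmt", "set '%s': %d duplicate genes removed", fields[1],
             sum(duplicated(genes)), level = "warn")
      genes <- unique(genes)
    }
    out[[i]] <- gene_set(fields[1], genes)
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog map
#'
#' @param path TSV with columns `rat_gene` and `mouse_gene` (other columns
#'   kept as provenance).
#' @return data.frame.
#' @export
read_ortholog_map <- function(path) {
  map <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rat_gene", "mouse_gene")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("ortholog map missing columns: ", paste(miss, collapse = ", "))
  map
}

# Write a stage output table with a provenance header.
write_stage_table <- function(tab, path, stage, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# airetonic stage=%s seed=%d config=%s", stage, seed, hash), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
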