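# Tonic-sensitivity classification and the per-cell-type "IFN score".
#
# Tonic-sensitive ISGs are the interferon-stimulated genes whose baseline
# expression depends on constitutive receptor signaling, operationalized
# as downregulated in an unstimulated receptor-knockout reference
# contrast.  The IFN score standardizes each tonic gene's expression in a
# knockout sample against the control-group mean and SD and sums the z
# values per cell type; negative scores indicate blunted tonic interferon
# signaling.

#' Classify ISGs as tonic-sensitive from a baseline reference contrast
#'
#' @param reference_de DE table of an unstimulated receptor-knockout vs
#'   wild-type contrast (columns gene, lfc, fdr); must cover at least half
#'   of the ISG universe.
#' @param isg_universe a [gene_set] of interferon-stimulated genes.
#' @param lfc_cut,fdr_cut downregulation thresholds (defaults -1, 0.05).
#' @return data.frame with gene, `tonic_sensitive` (logical; NA for
#'   unclassified), `ref_lfc`, `ref_fdr`, `status` in
#'   {tonic_sensitive, tonic_insensitive, unclassified}.
#' @export
classify_tonic <- function(reference_de, isg_universe, lfc_cut = -1, fdr_cut = 0.05) {
  idx <- match(isg_universe$genes, reference_de$gene)
  coverage <- mean(!is.na(idx))
  if (coverage < 0.5)
    stop(sprintf("reference covers only %.0f%% of the ISG universe (need >= 50%%)",
                 100 * coverage))
  lfc <- reference_de$lfc[idx]
  fdr <- reference_de$fdr[idx]
  tonic <- lfc < lfc_cut & fdr < fdr_cut
  status <- ifelse(is.na(idx), "unclassified",
                   ifelse(tonic, "tonic_sensitive", "tonic_insensitive"))
  at_log("classify_tonic", "%d ISGs: %d tonic-sensitive, %d insensitive, %d unclassified",
         length(status), sum(status == "tonic_sensitive"),
         sum(status == "tonic_insensitive"), sum(status == "unclassified"))
  data.frame(gene = isg_universe$genes, tonic_sensitive = tonic,
             ref_lfc = lfc, ref_fdr = fdr, status = status,
             stringsAsFactors = FALSE)
}

#' IFN score for one cell type
#'
#' For each tonic-sensitive gene g, z_g = (x_KO,g - mean_ctrl,g) /
#' sd_ctrl,g, using the control-sample mean and SD (n-1 denominator);
#' the score of a KO sample is the sum of its z values.  Genes with zero
#' control SD are dropped with a warning.
#'
#' @param expr gene x sample numeric matrix on a log scale (e.g. per-animal
#'   means of log-normalized values) for one cell type.
#' @param tonic tonic label table from [classify_tonic] (or any data.frame
#'   with gene + tonic_sensitive columns).
#' @param control_ids,ko_ids column ids of control and knockout samples;
#'   at least 2 controls are required.
#' @return data.frame with `sample`, `score`, `n_genes`; per-gene z values
#'   attached as attribute `z`.
#' @export
ifn_score <- function(expr, tonic, control_ids, ko_ids) {
  mat <- .as_values(expr)
  if (length(control_ids) < 2) stop("need at least 2 control samples to estimate SD")
  if (!all(c(control_ids, ko_ids) %in% colnames(mat)))
    stop("unknown sample ids")
  genes <- tonic$gene[!is.na(tonic$tonic_sensitive) & tonic$tonic_sensitive]
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0) stop("no tonic-sensitive genes present in the matrix")
  ctrl <- mat[genes, control_ids, drop = FALSE]
  mu <- rowMeans(ctrl)
  sdv <- apply(ctrl, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping %d tonic gene(s) with zero control SD", sum(sdv == 0)))
    genes <- genes[sdv > 0]
    if (length(genes) == 0) stop("no tonic-sensitive genes left after SD filter")
    mu <- mu[sdv > 0]
    sdv <- sdv[sdv > 0]
  }
  z <- (mat[genes, ko_ids, drop = FALSE] - mu) / sdv
  out <- data.frame(sample = ko_ids, score = unname(colSums(z)),
                    n_genes = length(genes), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "z") <- z
  out
}

# Per-(animal, cell type) means of log-normalized single-cell expression:
# the per-animal aggregation that feeds the IFN score (animal-level
# averaging avoids pseudoreplication across cells).
animal_celltype_means <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "count_matrix"))
  logn <- log_normalize(cm, scale_factor)
  out <- list()
  for (ct in unique(cm$cell_meta$cell_type)) {
    sel <- cm$cell_meta$cell_type == ct
    sub <- logn[sel, , drop = FALSE]
    animal <- cm$cell_meta$animal[sel]
    means <- rowsum(sub, group = animal) / as.vector(table(animal)[sort(unique(animal))])
    geno <- tapply(cm$cell_meta$genotype[sel], animal, function(g) unique(g)[1])
    out[[ct]] <- list(values = t(means), genotype = geno[rownames(means)])
  }
  out
}

#' IFN score table across cell types
#'
#' Aggregates single-cell counts to per-animal, per-cell-type means of
#' log-normalized expression, then applies [ifn_score] within each cell
#' type using the control animals as the standardization group.
#'
#' @param cm a [count_matrix] with genotype and animal metadata.
#' @param tonic tonic label table from [classify_tonic].
#' @param control_genotypes genotypes treated as controls (default HE, WT).
#' @return data.frame with `animal`, `cell_type`, `score`, `n_genes`.
#' @export
ifn_score_table <- function(cm, tonic, control_genotypes = c("HE", "WT")) {
  agg <- animal_celltype_means(cm)
  rows <- lapply(names(agg), function(ct) {
    vals <- agg[[ct]]$values
    geno <- agg[[ct]]$genotype
    ctrl <- names(geno)[geno %in% control_genotypes]
    ko <- names(geno)[!geno %in% control_genotypes]
    if (length(ko) == 0) return(NULL)
    sc <- ifn_score(vals, tonic, ctrl, ko)
    data.frame(animal = sc$sample, cell_type = ct, score = sc$score,
               n_genes = sc$n_genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  at_log("ifn_score", "%d (animal, cell type) scores, mean %.2f",
         nrow(out), mean(out$score))
  out
}
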