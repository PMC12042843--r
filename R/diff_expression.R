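# Bulk and pseudobulk two-group differential expression.
#
# Per-gene Welch two-sample t on log2-scale values with Benjamini-Hochberg
# adjustment; Aire-dependent genes are the genes downregulated in the
# knockout (signed LFC below the cut at the chosen FDR).  Single-cell
# counts are first summed to (animal, cell type) pseudobulk replicates.

#' Sum single-cell counts into pseudobulk strata
#'
#' @param cm a [count_matrix].
#' @param by grouping columns of the cell metadata (default animal and
#'   cell_type).
#' @param min_cells strata with fewer cells are dropped with a warning
#'   (default 10).
#' @param scale_factor library-size normalization constant for the log2
#'   values (default 1e4).
#' @return object of class `pseudobulk`: list with `counts` (stratum x gene
#'   integer sums), `log2cpm` (log2(1 + scale_factor * count/stratum
#'   total)), and `meta` (stratum, animal/cell_type columns, genotype,
#'   n_cells).
#' @export
pseudobulk <- function(cm, by = c("animal", "cell_type"), min_cells = 10,
                       scale_factor = 1e4) {
  stopifnot(inherits(cm, "count_matrix"))
  if (nrow(cm$counts) == 0) stop("empty CountMatrix")
  miss <- setdiff(by, names(cm$cell_meta))
  if (length(miss)) stop("unknown grouping columns: ", paste(miss, collapse = ", "))
  key <- interaction(cm$cell_meta[by], drop = TRUE, sep = ":")
  sums <- rowsum(as.matrix(cm$counts), group = key)
  n_cells <- as.integer(table(key)[rownames(sums)])
  keep <- n_cells >= min_cells
  if (any(!keep)) {
    warning(sprintf("dropping %d strata with fewer than %d cells: %s",
                    sum(!keep), min_cells,
                    paste(rownames(sums)[!keep], collapse = ", ")))
    at_log("pseudobulk", "dropped %d/%d strata below min_cells=%d",
           sum(!keep), length(keep), min_cells, level = "warn")
  }
  if (!any(keep)) stop("all strata below min_cells")
  sums <- sums[keep, , drop = FALSE]
  n_cells <- n_cells[keep]
  meta <- do.call(rbind, strsplit(rownames(sums), ":", fixed = TRUE))
  meta <- stats::setNames(as.data.frame(meta, stringsAsFactors = FALSE), by)
  meta$stratum <- rownames(sums)
  # carry genotype through when it is constant within a stratum
  geno <- tapply(cm$cell_meta$genotype, key, function(g) {
    u <- unique(g); if (length(u) == 1L) u else NA_character_
  })
  meta$genotype <- as.character(geno[rownames(sums)])
  meta$n_cells <- n_cells
  totals <- rowSums(sums)
  log2cpm <- log2(1 + scale_factor * sums / totals)
  at_log("pseudobulk", "%d strata x %d genes (min_cells=%d)",
         nrow(sums), ncol(sums), min_cells)
  structure(list(counts = sums, log2cpm = log2cpm, meta = meta),
            class = "pseudobulk")
}

# Vectorized per-row Welch two-sample t test.
welch_t_rows <- function(mat, idx1, idx2) {
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("need at least 2 replicates per group")
  s1 <- .row_mean_var(mat, idx1)
  s2 <- .row_mean_var(mat, idx2)
  lfc <- s1$mean - s2$mean
  se2 <- s1$var / s1$n + s2$var / s2$n
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((s1$var / s1$n)^2 / (s1$n - 1) + (s2$var / s2$n)^2 / (s2$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  flat <- se2 == 0
  # both groups constant: equal means -> t = 0, p = 1; unequal -> infinite t
  tstat[flat] <- ifelse(lfc[flat] == 0, 0, sign(lfc[flat]) * Inf)
  p[flat] <- ifelse(lfc[flat] == 0, 1, 0)
  data.frame(lfc = lfc, t = tstat, p = p)
}

#' Two-group differential expression (Welch t + BH)
#'
#' @param expr an [expression_matrix] on log2 scale, a `pseudobulk` object
#'   (its log2 values are used), or a plain log2-scale gene x sample
#'   matrix.
#' @param group_ids sample/stratum ids of the test group (KO).
#' @param ref_ids sample/stratum ids of the control group.
#' @param adjust multiple-testing adjustment across genes ("BH").
#' @return a DE table: data.frame with `gene`, `lfc` (mean KO minus mean
#'   control on log2 scale), `t`, `p`, `fdr`; attribute `adjust_method`.
#' @export
de_test <- function(expr, group_ids, ref_ids, adjust = c("BH")) {
  adjust <- match.arg(adjust)
  mat <- if (inherits(expr, "pseudobulk")) t(expr$log2cpm) else .as_values(expr)
  if (inherits(expr, "expression_matrix") && expr$scale != "log2")
    stop("de_test expects log2-scale input")
  idx1 <- match(group_ids, colnames(mat))
  idx2 <- match(ref_ids, colnames(mat))
  if (anyNA(idx1) || anyNA(idx2)) stop("unknown sample ids in contrast")
  res <- welch_t_rows(mat, idx1, idx2)
  res$fdr <- stats::p.adjust(res$p, method = adjust)
  out <- data.frame(gene = rownames(mat), res, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "adjust_method") <- adjust
  at_log("de_test", "%d genes tested, %d vs %d replicates, %d at FDR<0.05",
         nrow(out), length(idx1), length(idx2), sum(out$fdr < 0.05))
  out
}

#' Define Aire-dependent genes from a KO-vs-control DE table
#'
#' Aire-dependent genes are those downregulated in the Aire knockout:
#' signed LFC strictly below `lfc_cut` at adjusted p strictly below
#' `fdr_cut`.
#'
#' @param de DE table from [de_test] on the KO-vs-control mTEC contrast.
#' @param lfc_cut signed log2 fold-change cut (default -1).
#' @param fdr_cut FDR cut (default 0.05).
#' @return a [gene_set] named "aire_dependent".
#' @export
define_aire_dependent <- function(de, lfc_cut = -1, fdr_cut = 0.05) {
  sel <- de$lfc < lfc_cut & de$fdr < fdr_cut
  at_log("define_aire_dependent", "%d/%d genes at LFC<%g, FDR<%g",
         sum(sel), nrow(de), lfc_cut, fdr_cut)
  gene_set("aire_dependent", de$gene[sel])
}

#' Holm--Bonferroni step-down adjustment
#'
#' Step-down family-wise error-rate control: p values are sorted ascending,
#' the i-th multiplied by (m - i + 1), monotonicity enforced and values
#' capped at 1, then restored to input order.
#'
#' @param pvals numeric vector of raw p values in [0, 1].
#' @param labels optional names for the result (default `names(pvals)`).
#' @return adjusted p values in input order.
#' @export
adjust_holm <- function(pvals, labels = names(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p values must lie in [0, 1]")
  stats::setNames(stats::p.adjust(pvals, method = "holm"), labels)
}

#' Benjamini--Hochberg step-up adjustment
#'
#' @param pvals numeric vector of raw p values in [0, 1].
#' @param labels optional names for the result.
#' @return adjusted p values (FDR) in input order.
#' @export
adjust_bh <- function(pvals, labels = names(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p values must lie in [0, 1]")
  stats::setNames(stats::p.adjust(pvals, method = "BH"), labels)
}
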