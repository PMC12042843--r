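# Gene-set enrichment machinery.
#
# Fisher odds-ratio enrichment of a gene set among DE "hits" (one-sided
# hypergeometric tail by default, since every use is an enrichment claim);
# per-population enrichment with Holm adjustment; gene-set downsampling to
# a common size; classic weighted running-sum pre-ranked GSEA with a
# gene-label permutation null; and Seurat-style per-cell module scores
# against expression-matched control genes.

# Core 2x2 computation on counts.  a = in-set AND hit, b = in-set not hit,
# c = hit not in set, d = neither.  One-sided "greater" p is the
# hypergeometric tail P(X >= a) for X ~ Hypergeom(N, K = a+b, n = a+c).
fisher_counts <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  K <- a + b
  n <- a + c
  N <- a + b + c + d
  flags <- character(0)
  if (K == 0 || n == 0 || K == N || n == N) flags <- c(flags, "degenerate")
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }
  if (any(c(a, b, c, d) == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    flags <- c(flags, "haldane")
  } else {
    or <- (a * d) / (b * c)
  }
  list(a = a, b = b, c = c, d = d, odds_ratio = or, p = p, flags = flags)
}

#' Fisher odds-ratio enrichment of a gene set among hits
#'
#' Builds the 2x2 table (in set x hit) over `universe`, reports the sample
#' (cross-product) odds ratio and the one-sided exact tail probability.
#' When any cell is zero the odds ratio carries a Haldane--Anscombe +0.5
#' correction and the result is flagged.
#'
#' @param universe character vector of tested genes.
#' @param hits character vector of hit genes (must be a subset of
#'   `universe`).
#' @param set a [gene_set]; intersected with `universe` before tabulation.
#' @param alternative "greater" (default) or "two.sided".
#' @return object of class `enrichment_result`: list with 2x2 counts
#'   `a`,`b`,`c`,`d`, `odds_ratio`, `p`, `flags`, `set`.
#' @export
fisher_enrichment <- function(universe, hits, set,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(as.character(hits))
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_genes <- intersect(set$genes, universe)
  a <- length(intersect(set_genes, hits))
  b <- length(set_genes) - a
  c_ <- length(hits) - a
  d <- length(universe) - a - b - c_
  res <- fisher_counts(a, b, c_, d, alternative = alternative)
  res$set <- set$name
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment of '%s': a=%d b=%d c=%d d=%d OR=%.3g p=%.3g%s\n",
              x$set, x$a, x$b, x$c, x$d, x$odds_ratio, x$p,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Per-population gene-set enrichment among downregulated genes
#'
#' For each population's DE table, hits are the genes with signed LFC below
#' `lfc_cut` at FDR below `fdr_cut`; the universe is that population's
#' tested genes.  P values are Holm-adjusted across populations (degenerate
#' populations stay in the family size m).
#'
#' @param de_tables named list of DE tables (one per cell population).
#' @param set a [gene_set] (e.g. tonic-sensitive ISGs).
#' @param lfc_cut,fdr_cut downregulation thresholds (defaults -1, 0.05).
#' @return data.frame with population, 2x2 counts, odds_ratio, p, holm_p,
#'   flags.
#' @export
enrichment_by_population <- function(de_tables, set, lfc_cut = -1, fdr_cut = 0.05) {
  if (length(de_tables) == 0 || is.null(names(de_tables)))
    stop("de_tables must be a non-empty named list")
  rows <- lapply(names(de_tables), function(pop) {
    de <- de_tables[[pop]]
    hits <- de$gene[de$lfc < lfc_cut & de$fdr < fdr_cut]
    r <- fisher_enrichment(de$gene, hits, set)
    data.frame(population = pop, a = r$a, b = r$b, c = r$c, d = r$d,
               odds_ratio = r$odds_ratio, p = r$p,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$holm_p <- adjust_holm(out$p)
  at_log("enrichment_by_population",
         "%d populations, %d with Holm p < 0.05 (set '%s')",
         nrow(out), sum(out$holm_p < 0.05), set$name)
  out
}

#' Downsample gene sets to a common size
#'
#' All sets are reduced to the size of the smallest by sampling without
#' replacement; sets already at the target size are returned unchanged.
#'
#' @param sets list of [gene_set] objects.
#' @param seed integer seed for the sampling.
#' @return list of [gene_set] objects, all of equal size.
#' @export
downsample_sets <- function(sets, seed) {
  if (length(sets) == 0) stop("need at least one set")
  sizes <- vapply(sets, function(s) length(s$genes), integer(1))
  target <- min(sizes)
  set.seed(seed)
  lapply(sets, function(s) {
    if (length(s$genes) == target) return(s)
    gene_set(s$name, sample(s$genes, target))
  })
}

# ES of the weighted running sum given hit positions in the ranked list.
# pos: sorted positions of set genes; w: |stat|^p over the full ranked
# list; returns the signed maximum deviation.  Candidate extrema occur
# right after each hit (maxima) and right before each hit or at the end
# (minima), so only O(|set|) work per evaluation.
.es_from_positions <- function(pos, w, N) {
  Nh <- length(pos)
  wh <- w[pos]
  denom <- sum(wh)
  cw <- if (denom > 0) cumsum(wh) / denom else seq_len(Nh) / Nh
  miss_step <- 1 / (N - Nh)
  drop_before <- (pos - seq_len(Nh)) * miss_step
  up <- cw - drop_before                 # value just after hit i
  down <- c(0, cw[-Nh]) - drop_before    # value just before hit i
  hi <- max(up)
  lo <- min(down, 0)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked GSEA with a gene-label permutation null
#'
#' Classic weighted running-sum statistic: walking down the ranked list,
#' set members increment the sum by |s|^weight (normalized by the summed
#' weights of the set) and non-members decrement by 1/(N - |set|); ES is
#' the signed maximum deviation.  The null is built by placing the set on
#' random gene labels; NES divides ES by the mean |null ES| of matching
#' sign and the permutation p is (1 + #{same-sign nulls at least as
#' extreme}) / (#same-sign nulls + 1).
#'
#' @param stats named numeric vector, gene -> ranking statistic (need not
#'   be pre-sorted; descending order defines the ranking, ties broken by
#'   gene name).
#' @param set a [gene_set]; must overlap the ranked genes and must not
#'   cover all of them.
#' @param weight exponent on |statistic| for hit increments (default 1).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return object of class `gsea_result`: list with `set`, `es`, `nes`,
#'   `p_perm`, `leading_edge`, `size` (set genes in the list), `n_perm`,
#'   and `running` (data.frame gene/position/running sum for plotting).
#' @export
gsea_preranked <- function(stats, set, weight = 1, n_perm = 10000, seed = 1) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stop("stats must be uniquely named by gene")
  if (any(!is.finite(stats))) stop("ranking statistics must be finite")
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  N <- length(s)
  hit <- names(s) %in% set$genes
  Nh <- sum(hit)
  if (Nh == 0) stop("set does not overlap the ranked genes")
  if (Nh == N) stop("degenerate: set covers all ranked genes")
  w <- abs(s)^weight
  pos <- which(hit)
  es <- .es_from_positions(pos, w, N)
  # full running sum for the observed configuration (trace + leading edge)
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / Nh
  step <- inc - (!hit) / (N - Nh)
  run <- cumsum(step)
  ext <- if (es >= 0) which.max(run) else which.min(run)
  leading <- if (es >= 0) names(s)[seq_len(ext)][hit[seq_len(ext)]]
             else names(s)[ext:N][hit[ext:N]]
  set.seed(seed)
  null_es <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    null_es[b] <- .es_from_positions(sort(sample.int(N, Nh)), w, N)
  }
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  at_log("gsea_preranked", "set '%s' (n=%d): ES=%.3f NES=%.3f p=%.4g",
         set$name, Nh, es, nes, p_perm)
  structure(list(set = set$name, es = es, nes = nes, p_perm = p_perm,
                 leading_edge = leading, size = Nh, n_perm = n_perm,
                 running = data.frame(gene = names(s),
                                      position = seq_len(N),
                                      running_es = run,
                                      hit = hit,
                                      stringsAsFactors = FALSE)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA '%s': ES=%.3f NES=%.3f p_perm=%.3g (n=%d, %d permutations)\n",
              x$set, x$es, x$nes, x$p_perm, x$size, x$n_perm))
  invisible(x)
}

#' Per-cell module score against expression-matched controls
#'
#' Genes are binned into `n_bins` equal-frequency bins by mean expression
#' across cells; for each set gene, `n_ctrl` control genes are sampled from
#' its bin (with replacement when the bin is smaller than `n_ctrl`).  The
#' score for each cell is the mean expression of the set genes minus the
#' mean expression of the pooled control draws.
#'
#' @param mat log-normalized cell x gene matrix (see [log_normalize]).
#' @param set a [gene_set]; must intersect the matrix genes.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(mat, set, n_bins = 24, n_ctrl = 100, seed = 1) {
  mat <- as.matrix(mat)
  genes <- colnames(mat)
  set_genes <- intersect(set$genes, genes)
  if (length(set_genes) == 0) stop("set does not intersect the matrix genes")
  avg <- colMeans(mat)
  n_bins <- min(n_bins, length(genes))
  bin <- ceiling(rank(avg, ties.method = "first") / (length(genes) / n_bins))
  names(bin) <- genes
  set.seed(seed)
  ctrl <- unlist(lapply(set_genes, function(g) {
    pool <- genes[bin == bin[[g]]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  score <- rowMeans(mat[, set_genes, drop = FALSE]) -
    rowMeans(mat[, ctrl, drop = FALSE])
  stats::setNames(as.numeric(score), rownames(mat))
}

#' Log-normalize single-cell counts
#'
#' Per-cell library-size normalization followed by log1p, the convention of
#' single-cell module scoring: log(1 + scale_factor * count / library
#' size).
#'
#' @param cm a [count_matrix] or cell x gene counts matrix.
#' @param scale_factor default 1e4.
#' @return dense cell x gene matrix of log-normalized values.
#' @export
log_normalize <- function(cm, scale_factor = 1e4) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(scale_factor * counts / lib)
}
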