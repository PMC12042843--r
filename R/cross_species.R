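# Cross-species comparison of Aire-regulated genes.
#
# Rat and mouse KO-vs-control DE results are combined over a one-to-one
# ortholog map into a gene x dataset LFC matrix; samples/datasets are
# inspected by PCA, genes are clustered into modules by K-means, module
# membership is tested for TRA/ISG enrichment, populations are clustered
# on correlation distance with plain bootstrap support, and relative ISG
# expression between datasets is compared by Spearman correlation.

#' Combine rat and mouse DE tables over an ortholog map
#'
#' @param rat_de DE table with rat gene ids.
#' @param mouse_des named list of DE tables with mouse gene ids.
#' @param map data.frame with `rat_gene`, `mouse_gene`; must be one-to-one
#'   after filtering (duplicated genes on either side are an error).
#' @return gene x dataset LFC matrix (rows: rat ids of orthologs present in
#'   the rat table and at least one mouse table; columns: "rat" plus the
#'   mouse dataset names).  Missing entries are NA (absent, not zero).
#' @export
combine_orthologs <- function(rat_de, mouse_des, map) {
  if (anyDuplicated(map$rat_gene) || anyDuplicated(map$mouse_gene))
    stop("ortholog map must be one-to-one (duplicated genes remain)")
  if (is.null(names(mouse_des))) stop("mouse_des must be a named list")
  rat2mouse <- stats::setNames(map$mouse_gene, map$rat_gene)
  genes <- intersect(rat_de$gene, map$rat_gene)
  lfc <- matrix(NA_real_, length(genes), 1 + length(mouse_des),
                dimnames = list(genes, c("rat", names(mouse_des))))
  lfc[, "rat"] <- rat_de$lfc[match(genes, rat_de$gene)]
  for (ds in names(mouse_des)) {
    idx <- match(rat2mouse[genes], mouse_des[[ds]]$gene)
    lfc[, ds] <- mouse_des[[ds]]$lfc[idx]
  }
  keep <- rowSums(!is.na(lfc[, -1, drop = FALSE])) >= 1
  lfc <- lfc[keep, , drop = FALSE]
  at_log("combine_orthologs", "%d orthologous genes x %d datasets (union policy: rat + >=1 mouse)",
         nrow(lfc), ncol(lfc))
  lfc
}

#' PCA of samples on a gene subset
#'
#' Genes are standardized (z per gene; zero-variance genes dropped first)
#' and sample coordinates obtained by eigendecomposition of the sample
#' covariance.  The sign convention fixes each component so its
#' largest-magnitude gene loading is positive.
#'
#' @param mat samples x genes numeric matrix (e.g. expression restricted
#'   to Aire-regulated genes).
#' @return list with `coordinates` (samples x PCs), `loadings`,
#'   `var_explained` (fractions, sum <= 1).
#' @export
pca_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 samples")
  v <- apply(mat, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all genes have zero variance")
  if (any(!keep))
    at_log("pca_samples", "dropping %d zero-variance genes", sum(!keep))
  z <- scale(mat[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, `*`)
  loads <- sweep(pc$rotation, 2, flip, `*`)
  list(coordinates = coords, loadings = loads,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' K-means gene modules on a gene x dataset LFC matrix
#'
#' Columns are z-scaled per dataset, absent entries imputed as 0 after
#' scaling (flagged in the log; imputation is for clustering only), and
#' the best of `n_init` K-means runs by within-cluster sum of squares is
#' kept.  Module labels are renumbered by descending size.
#'
#' @param lfc gene x dataset LFC matrix (NAs allowed).
#' @param k number of modules (default 4, as fixed by the study design).
#' @param n_init random initializations (default 50).
#' @param seed integer seed.
#' @return object of class `module_assignment`: list with `assignment`
#'   (named integer gene -> module), `sizes`, `wcss`, `centers`.
#' @export
kmeans_modules <- function(lfc, k = 4, n_init = 50, seed = 1) {
  lfc <- as.matrix(lfc)
  if (k >= nrow(lfc)) stop("k must be smaller than the number of genes")
  z <- scale(lfc)
  n_na <- sum(is.na(z))
  if (n_na > 0) {
    at_log("kmeans_modules", "imputing %d absent entries as 0 after scaling", n_na)
    z[is.na(z)] <- 0
  }
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  ord <- order(-km$size)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignment <- stats::setNames(relabel[km$cluster], rownames(lfc))
  structure(list(assignment = assignment,
                 sizes = as.integer(km$size[ord]),
                 wcss = km$tot.withinss,
                 centers = km$centers[ord, , drop = FALSE]),
            class = "module_assignment")
}

#' Per-module gene-set enrichment
#'
#' For each module, a 2x2 table (in-module x in-set) over the universe of
#' all clustered genes, tested with [fisher_enrichment]; Holm adjustment
#' across modules.
#'
#' @param modules a `module_assignment` from [kmeans_modules].
#' @param set a [gene_set] (e.g. TRAs or ISGs).
#' @return data.frame with module, 2x2 counts, odds_ratio, p, holm_p,
#'   flags.
#' @export
module_set_enrichment <- function(modules, set) {
  universe <- names(modules$assignment)
  rows <- lapply(sort(unique(modules$assignment)), function(m) {
    hits <- universe[modules$assignment == m]
    r <- fisher_enrichment(universe, hits, set)
    data.frame(module = m, a = r$a, b = r$b, c = r$c, d = r$d,
               odds_ratio = r$odds_ratio, p = r$p,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$holm_p <- adjust_holm(out$p)
  out
}

# Clade key: sorted member labels collapsed to one string.
.clades_of <- function(hc, labels) {
  n <- length(labels)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- hc$merge[i, ]
    get <- function(j) if (j < 0) labels[-j] else members[[j]]
    members[[i]] <- c(get(m[1]), get(m[2]))
  }
  vapply(members, function(x) paste(sort(x), collapse = "|"), character(1))
}

#' Correlation-distance clustering of populations with bootstrap support
#'
#' Average-linkage hierarchical clustering of populations on 1 - Pearson
#' correlation over genes.  Support values are plain bootstrap proportions
#' (BP): genes are resampled with replacement, the tree recomputed, and
#' each original clade's recovery frequency recorded.  (Multiscale
#' approximately-unbiased bootstrap is out of scope; supports are labeled
#' BP.)
#'
#' @param mat population x gene mean-expression matrix (>= 3 populations).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `tree` (hclust), `support` (per internal node, in
#'   merge order), `phylo` (ape phylo with node labels = support) and
#'   `newick` (string).
#' @export
cluster_populations <- function(mat, n_boot = 1000, seed = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 populations")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance population(s): ",
         paste(rownames(mat)[sds == 0], collapse = ", "))
  labels <- rownames(mat)
  cluster_once <- function(m) {
    stats::hclust(stats::as.dist(1 - stats::cor(t(m))), method = "average")
  }
  hc <- cluster_once(mat)
  ref_clades <- .clades_of(hc, labels)
  hits <- stats::setNames(numeric(length(ref_clades)), ref_clades)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ncol(mat), replace = TRUE)
    mb <- mat[, idx, drop = FALSE]
    if (any(apply(mb, 1, stats::sd) == 0)) next
    bc <- .clades_of(cluster_once(mb), labels)
    found <- ref_clades %in% bc
    hits[found] <- hits[found] + 1
  }
  support <- hits / n_boot
  phylo <- ape::as.phylo(hc)
  part <- ape::prop.part(phylo)
  node_keys <- vapply(part, function(tips)
    paste(sort(attr(part, "labels")[tips]), collapse = "|"), character(1))
  phylo$node.label <- sprintf("%.3f", support[node_keys])
  list(tree = hc, support = support, phylo = phylo,
       newick = ape::write.tree(phylo))
}

# All permutations of a vector (used for the exact Spearman null).
.all_perms <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(x[i], .all_perms(x[-i]))))
}

#' Spearman comparison of relative expression between two datasets
#'
#' Rank correlation with average ranks for ties.  The two-sided p value is
#' exact (full enumeration of rank permutations) for n <= 9 and uses the
#' t approximation otherwise.
#'
#' @param x,y paired per-gene values (>= 5 pairs, non-constant).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_compare <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired genes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .all_perms(seq_len(n))
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    cx <- rx - mean(rx)
    cy <- sweep(ry_perm, 1, rowMeans(ry_perm))
    rho_perm <- as.vector(cy %*% cx) /
      (sqrt(sum(cx^2)) * sqrt(rowSums(cy^2)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(1, p), n = n, method = method)
}
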