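# Dynamic-step tissue-restricted antigen (TRA) calling.
#
# Tissue samples are first reduced to a small number of groups by
# average-linkage hierarchical clustering on correlation distance, so that
# over-represented similar tissues do not dominate.  For each gene the
# group-level expression values are ranked; the gene is called
# tissue-restricted if its expression in the top j groups exceeds a
# threshold T that depends on the expression level E in the next highest
# (j+1-th) group.  The printed rendering of T(E) admits two algebraic
# parses; both are available behind `form` (see dynamic_threshold).

#' Reduce tissue samples to expression groups
#'
#' Average-linkage hierarchical clustering of samples on correlation
#' distance (1 - Pearson over genes), cut to exactly `n_groups`; group
#' expression is the arithmetic mean of member samples on linear scale.
#'
#' @param expr an [expression_matrix] (log2 input is unlogged to linear
#'   first) or a plain linear-scale gene x sample matrix.
#' @param n_groups number of groups to cut the tree into (default 11).
#' @return list with `group_means` (gene x group matrix, columns
#'   `group_01`...), `assignment` (named integer vector sample -> group) and
#'   the `hclust` tree, class `tra_groups`.
#' @export
reduce_to_groups <- function(expr, n_groups = 11) {
  values <- .as_values(expr)
  if (inherits(expr, "expression_matrix") && expr$scale == "log2")
    values <- 2^values - 1
  if (ncol(values) < n_groups)
    stop(sprintf("need at least n_groups=%d samples, got %d", n_groups, ncol(values)))
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s), correlation distance undefined: ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(values))
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = n_groups)
  gm <- vapply(seq_len(n_groups), function(k)
    rowMeans(values[, grp == k, drop = FALSE]), numeric(nrow(values)))
  colnames(gm) <- sprintf("group_%02d", seq_len(n_groups))
  rownames(gm) <- rownames(values)
  at_log("reduce_to_groups", "%d samples -> %d groups (sizes: %s)",
         ncol(values), n_groups, paste(tabulate(grp, n_groups), collapse = ","))
  structure(list(group_means = gm, assignment = grp, tree = hc),
            class = "tra_groups")
}

#' Dynamic-step threshold T(E)
#'
#' Two algebraic forms of the expression-dependent threshold are
#' implemented: `gap` (default), T = E + E/250 + 50, which requires a gene
#' to exceed the next-ranked group by an expression-dependent margin; and
#' `saturating`, T = E/(250 + E) + 50, which is nearly constant (~50-51).
#' Both are monotone non-decreasing in E with T >= 50.
#'
#' @param E expression level(s) in the next highest group (linear scale,
#'   non-negative; vectorized).
#' @param form "gap" or "saturating".
#' @return threshold value(s) T.
#' @export
dynamic_threshold <- function(E, form = c("gap", "saturating")) {
  form <- match.arg(form)
  if (any(E < 0)) stop("expression level E must be non-negative")
  switch(form,
         gap = E + E / 250 + 50,
         saturating = E / (250 + E) + 50)
}

#' Call tissue-restricted genes by the dynamic-step rule
#'
#' For each gene, group expression values are sorted descending (ties
#' broken deterministically by group label).  For j = 1..j_max the
#' criterion is: j-th highest group expression > T(E_(j+1)) where E_(j+1)
#' is the (j+1)-th highest.  `j_star` is the smallest j satisfying the
#' criterion (0 if none) and `is_tra` is `j_star >= 1`.
#'
#' @param group_means gene x group matrix on linear scale, a `tra_groups`
#'   result, or an [expression_matrix].
#' @param j_max largest number of expressing groups considered "few"
#'   (default 5); must be smaller than the number of groups.
#' @param form threshold form passed to [dynamic_threshold].
#' @return data.frame with columns `gene`, `j_star`, `threshold_at_j` (T at
#'   the group ranked j_star + 1; NA when j_star = 0), `is_tra`,
#'   `n_groups`; the descending group means are attached as attribute
#'   `sorted_group_means`.
#' @export
call_tra <- function(group_means, j_max = 5, form = c("gap", "saturating")) {
  form <- match.arg(form)
  if (inherits(group_means, "tra_groups")) group_means <- group_means$group_means
  gm <- .as_values(group_means)
  n <- ncol(gm)
  if (j_max >= n)
    stop(sprintf("j_max=%d must be smaller than the number of groups (%d)", j_max, n))
  if (j_max < 1) stop("j_max must be >= 1")
  labels <- colnames(gm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  sorted <- t(apply(gm, 1, function(x) x[order(-x, labels)]))
  j_star <- integer(nrow(gm))
  thr_at <- rep(NA_real_, nrow(gm))
  for (j in seq_len(j_max)) {
    thr <- dynamic_threshold(sorted[, j + 1], form = form)
    hit <- j_star == 0L & sorted[, j] > thr
    j_star[hit] <- j
    thr_at[hit] <- thr[hit]
  }
  out <- data.frame(gene = rownames(gm), j_star = j_star,
                    threshold_at_j = thr_at, is_tra = j_star >= 1L,
                    n_groups = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  at_log("call_tra", "%d/%d genes called tissue-restricted (j_max=%d, form=%s)",
         sum(out$is_tra), nrow(out), j_max, form)
  attr(out, "sorted_group_means") <- sorted
  out
}
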