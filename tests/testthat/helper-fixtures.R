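# Shared fixtures and small scoring helpers, all built in code.

options(airetonic.log_level = "quiet")

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Tiny count matrix with explicit values for IO and pseudobulk tests.
tiny_count_matrix <- function() {
  counts <- matrix(c(1, 0, 2,
                     0, 0, 3,
                     4, 1, 0,
                     2, 2, 2), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("bc", 1:4), paste0("g", 1:3)))
  meta <- data.frame(cell_id = paste0("bc", 1:4),
                     cell_type = c("A", "A", "B", "B"),
                     genotype = c("KO", "KO", "HE", "HE"),
                     animal = c("a1", "a1", "a2", "a2"),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Log2-scale expression matrix from explicit values.
tiny_expression_matrix <- function(values, genotype = NULL, scale = "log2") {
  if (is.null(genotype)) genotype <- rep("WT", ncol(values))
  meta <- data.frame(sample_id = colnames(values), genotype = genotype,
                     group = "g", animal = colnames(values),
                     stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = scale)
}

# Exhaustive hypergeometric tail: P(X >= a) for the 2x2 table, by direct
# enumeration over the support with choose().
enum_fisher_p <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  ks <- max(0, K + n - N):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= a])
}

# Exhaustive rarefaction oracle: average distinct-gene count over all
# C(N, m) subsamples of the individual UMIs.
enum_rarefaction <- function(abundance, m) {
  units <- rep(seq_along(abundance), abundance)
  subs <- utils::combn(length(units), m)
  mean(apply(subs, 2, function(idx) length(unique(units[idx]))))
}

# Brute-force multiple-testing oracles straight from the definitions.
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_along(ord)) {
    k <- m - i + 1
    running <- min(running, p[ord[i]] * m / k)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# ES oracle: plain cumulative-sum evaluation of the weighted running sum.
brute_es <- function(stats_sorted, hit, weight = 1) {
  w <- abs(stats_sorted)^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / sum(hit)
  run <- cumsum(inc - (!hit) / sum(!hit))
  unname(run[which.max(abs(run))])
}
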