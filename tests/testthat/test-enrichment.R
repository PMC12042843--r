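# Fisher enrichment (vs exhaustive enumeration), per-population enrichment,
# downsampling, pre-ranked GSEA (vs cumsum oracle, enumeration and fgsea),
# and module scores.

test_that("fisher_enrichment reproduces exact hand-enumerated tables", {
  universe <- paste0("g", 1:40)
  r <- fisher_enrichment(universe, paste0("g", 1:20),
                         gene_set("s", paste0("g", c(1:10, 21:30))))
  expect_equal(c(r$a, r$b, r$c, r$d), c(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, enum_fisher_p(10, 10, 10, 10), tolerance = 1e-12)
  r2 <- fisher_enrichment(paste0("g", 1:20), paste0("g", c(1:9, 11)),
                          gene_set("s", paste0("g", 1:10)))
  expect_equal(r2$odds_ratio, 81)
  expect_equal(r2$p, 101 / 184756, tolerance = 1e-12)
  # set disjoint from universe: degenerate, p = 1
  r3 <- fisher_enrichment(paste0("g", 1:10), paste0("g", 1:5),
                          gene_set("s", paste0("x", 1:4)))
  expect_true("degenerate" %in% r3$flags)
  expect_equal(r3$p, 1)
  expect_error(fisher_enrichment(character(0), character(0), gene_set("s", "a")),
               "empty universe")
  expect_error(fisher_enrichment(paste0("g", 1:5), "g9", gene_set("s", "g1")),
               "subset")
})

test_that("the hypergeometric tail matches enumeration over many tables", {
  set.seed(14)
  # dense scan of small tables plus random larger ones up to N = 60
  for (N in c(4, 9, 15)) {
    for (K in 0:N) for (n in 0:N) {
      for (a in max(0, K + n - N):min(K, n)) {
        b <- K - a; c_ <- n - a; d <- N - K - c_
        got <- airetonic:::fisher_counts(a, b, c_, d)
        expect_equal(got$p, enum_fisher_p(a, b, c_, d), tolerance = 1e-10)
      }
    }
  }
  for (rep in 1:400) {
    N <- sample(16:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    a <- sample(max(0, K + n - N):min(K, n), 1)
    b <- K - a; c_ <- n - a; d <- N - K - c_
    got <- airetonic:::fisher_counts(a, b, c_, d)
    expect_equal(got$p, enum_fisher_p(a, b, c_, d), tolerance = 1e-10)
    if (all(c(a, b, c_, d) > 0))
      expect_equal(got$odds_ratio, a * d / (b * c_))
  }
})

test_that("per-population enrichment uses per-population universes and Holm", {
  de1 <- data.frame(gene = paste0("g", 1:20),
                    lfc = c(rep(-2, 5), rep(0, 15)),
                    fdr = c(rep(0.01, 5), rep(0.9, 15)))
  de2 <- data.frame(gene = paste0("g", 1:10),
                    lfc = rep(0, 10), fdr = rep(0.9, 10))
  set <- gene_set("isg", paste0("g", 1:5))
  res <- enrichment_by_population(list(A = de1, B = de2), set)
  expect_equal(res$a[res$population == "A"], 5L)
  expect_equal(res$a[res$population == "B"], 0L)      # no hits in B
  expect_equal(res$holm_p, unname(adjust_holm(res$p)))
  single <- enrichment_by_population(list(A = de1), set)
  expect_equal(single$holm_p, single$p)               # m = 1
})

test_that("downsampling preserves membership and the minimum-size set", {
  sets <- list(gene_set("a", paste0("g", 1:10)),
               gene_set("b", paste0("h", 1:50)))
  down <- downsample_sets(sets, seed = 3)
  expect_equal(down[[1]]$genes, sets[[1]]$genes)      # already at target
  expect_length(down[[2]]$genes, 10)
  expect_true(all(down[[2]]$genes %in% sets[[2]]$genes))
  expect_equal(downsample_sets(sets, seed = 3)[[2]]$genes, down[[2]]$genes)
  expect_false(identical(downsample_sets(sets, seed = 4)[[2]]$genes,
                         down[[2]]$genes))
  even <- downsample_sets(list(gene_set("a", letters[1:4]),
                               gene_set("b", letters[5:8])), seed = 1)
  expect_equal(lapply(even, `[[`, "genes"), list(letters[1:4], letters[5:8]))
})

test_that("GSEA ES matches the plain cumulative-sum oracle and fgsea", {
  set.seed(20)
  for (rep in 1:20) {
    stats <- setNames(rnorm(40), paste0("g", 1:40))
    genes <- paste0("g", sample(40, 8))
    set <- gene_set("s", genes)
    res <- gsea_preranked(stats, set, n_perm = 100, seed = 1)
    ord <- order(-stats, names(stats))
    hit <- names(stats)[ord] %in% genes
    expect_equal(res$es, brute_es(stats[ord], hit), tolerance = 1e-12)
    expect_true(abs(res$es) <= 1)
    # reversing the ranking negates the ES
    rev_res <- gsea_preranked(-stats, set, n_perm = 100, seed = 1)
    expect_equal(rev_res$es, -res$es, tolerance = 1e-12)
    expect_equal(sign(res$nes), sign(res$es))
  }
  skip_if_not_installed("fgsea")
  stats <- setNames(rnorm(100), paste0("g", 1:100))
  set <- gene_set("s", paste0("g", sample(100, 15)))
  mine <- gsea_preranked(stats, set, n_perm = 100, seed = 1)
  fg <- suppressWarnings(
    fgsea::fgsea(list(s = set$genes), stats, nperm = 100, gseaParam = 1))
  expect_equal(mine$es, fg$ES, tolerance = 1e-9)
})

test_that("GSEA edge cases: top-gene set, degenerate set, symmetry", {
  stats <- setNames(seq(5, 1, length.out = 5), paste0("g", 1:5))
  res <- gsea_preranked(stats, gene_set("t", "g1"), n_perm = 200, seed = 1)
  expect_equal(res$es, 1)                    # running sum hits 1.0 at rank 1
  expect_equal(res$leading_edge, "g1")
  expect_error(gsea_preranked(stats, gene_set("all", names(stats))),
               "degenerate")
  expect_error(gsea_preranked(stats, gene_set("none", "zz")), "overlap")
  # equal statistics, random sets: ES symmetric about 0 across seeds
  flat <- setNames(rep(1, 20), paste0("g", 1:20))
  es <- vapply(1:300, function(s) {
    set.seed(s)
    gsea_preranked(flat, gene_set("r", paste0("g", sample(20, 5))),
                   n_perm = 100, seed = 1)$es
  }, numeric(1))
  expect_lt(abs(mean(es)), 3 * sd(es) / sqrt(length(es)))
})

test_that("permutation p is within Monte-Carlo error of exact enumeration", {
  stats <- setNames(c(3, 2.2, 1.4, 0.8, -0.5, -1.7), paste0("g", 1:6))
  genes <- c("g1", "g2", "g4")
  set <- gene_set("s", genes)
  obs <- gsea_preranked(stats, set, n_perm = 4000, seed = 9)
  # exact: enumerate all C(6,3) = 20 label placements
  combos <- combn(6, 3)
  es_all <- apply(combos, 2, function(idx) {
    hit <- seq_len(6) %in% idx
    brute_es(stats, hit)
  })
  same <- if (obs$es >= 0) es_all[es_all >= 0] else es_all[es_all < 0]
  p_exact <- sum(abs(same) >= abs(obs$es) - 1e-9) / length(same)
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 4000) + 1 / 4000
  expect_lt(abs(obs$p_perm - p_exact), 3 * mc_sd + 0.01)
})

test_that("module scores center at null, detect planted shifts, and are reproducible", {
  set.seed(33)
  n_cells <- 200; n_genes <- 300
  mat <- matrix(rlnorm(n_cells * n_genes, 0, 0.5), n_cells, n_genes,
                dimnames = list(paste0("c", 1:n_cells), paste0("g", 1:n_genes)))
  # exchangeable set: mean score ~ 0
  set <- gene_set("null", paste0("g", sample(n_genes, 20)))
  sc <- module_score(mat, set, seed = 2)
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(n_cells))
  expect_equal(module_score(mat, set, seed = 2), sc)   # same seed, same scores
  # planted 2-fold upregulation in half the cells
  up_cells <- 1:100
  mat2 <- mat
  mat2[up_cells, set$genes] <- mat2[up_cells, set$genes] * 2
  sc2 <- module_score(mat2, set, seed = 2)
  expect_lt(wilcox.test(sc2[up_cells], sc2[-up_cells],
                        alternative = "greater")$p.value, 0.01)
  expect_error(module_score(mat, gene_set("x", "nope")), "intersect")
})
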