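# Ortholog combination, PCA, K-means modules, module enrichment,
# population clustering with bootstrap support, and Spearman comparison.

test_that("combine_orthologs aligns tables and marks absences as NA", {
  map <- data.frame(rat_gene = paste0("r", 1:5), mouse_gene = paste0("m", 1:5))
  rat <- data.frame(gene = paste0("r", 1:5), lfc = 1:5)
  mouse <- data.frame(gene = paste0("m", 1:5), lfc = 1:5)
  comb <- combine_orthologs(rat, list(ms = mouse), map)
  expect_equal(unname(comb[, "rat"]), unname(comb[, "ms"]))
  # gene missing from one mouse dataset: absent there only
  comb2 <- combine_orthologs(rat, list(ms = mouse[-2, ], ms2 = mouse), map)
  expect_true(is.na(comb2["r2", "ms"]))
  expect_equal(comb2["r2", "ms2"], 2)
  bad <- rbind(map, data.frame(rat_gene = "r9", mouse_gene = "m1"))
  expect_error(combine_orthologs(rat, list(ms = mouse), bad), "one-to-one")
})

test_that("PCA: duplicated samples coincide, variance fractions decrease", {
  set.seed(15)
  mat <- matrix(rnorm(8 * 30), 8, 30,
                dimnames = list(paste0("s", 1:8), paste0("g", 1:30)))
  mat[8, ] <- mat[1, ]                          # duplicate sample
  pc <- pca_samples(mat)
  expect_equal(pc$coordinates[1, ], pc$coordinates[8, ], tolerance = 1e-9)
  expect_true(all(diff(pc$var_explained) <= 1e-9))
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  # two well-separated planted groups: PC1 separates with high silhouette
  grp <- rep(c(0, 8), each = 4)
  mat2 <- mat + grp
  pc2 <- pca_samples(mat2)
  x <- pc2$coordinates[, 1]
  sil <- vapply(1:8, function(i) {
    own <- mean(abs(x[i] - x[setdiff(which(grp == grp[i]), i)]))
    oth <- mean(abs(x[i] - x[grp != grp[i]]))
    (oth - own) / max(oth, own)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  expect_error(pca_samples(matrix(1, 4, 3)), "zero variance")
})

test_that("PCA coordinates are invariant to row/column ordering up to the sign convention", {
  set.seed(25)
  mat <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:20)))
  pc <- pca_samples(mat)
  perm_g <- sample(20); perm_s <- sample(6)
  pc2 <- pca_samples(mat[perm_s, perm_g])
  expect_equal(abs(pc2$coordinates[order(perm_s), 1:3]),
               abs(pc$coordinates[, 1:3]), tolerance = 1e-8)
})

test_that("K-means modules recover planted structure and satisfy WCSS optimality", {
  cs <- make_cross_species(n_genes = 400, n_modules = 2, seed = 5)
  comb <- combine_orthologs(cs$rat_de, cs$mouse_des, cs$ortholog_map)
  mod <- kmeans_modules(comb, k = 2, seed = 3)
  truth <- cs$truth$modules[names(mod$assignment)]
  expect_gte(adjusted_rand_index(mod$assignment, truth), 0.9)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(mod$assignment, truth),
               mclust::adjustedRandIndex(mod$assignment, truth),
               tolerance = 1e-12)
  # determinism and degenerate k
  expect_identical(kmeans_modules(comb, k = 2, seed = 3)$assignment,
                   mod$assignment)
  one <- kmeans_modules(comb, k = 1, n_init = 1, seed = 1)
  z <- scale(comb); z[is.na(z)] <- 0
  expect_equal(one$wcss, sum(scale(z, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(kmeans_modules(comb[1:3, ], k = 3), "smaller")
  # best-of-n_init: returned WCSS no worse than single-start runs
  singles <- vapply(1:5, function(s)
    kmeans_modules(comb, k = 3, n_init = 1, seed = s)$wcss, numeric(1))
  expect_lte(kmeans_modules(comb, k = 3, n_init = 20, seed = 1)$wcss,
             min(singles) + 1e-8)
})

test_that("module enrichment composes fisher_enrichment and finds planted TRA excess", {
  # constructed counts: module of 100 genes at 50% set membership vs 10%
  genes <- paste0("g", 1:1000)
  assignment <- setNames(rep(2L, 1000), genes)
  assignment[1:100] <- 1L
  modules <- structure(list(assignment = assignment), class = "module_assignment")
  set.seed(60)
  in_set <- c(genes[1:100][runif(100) < 0.5], genes[101:1000][runif(900) < 0.1])
  res <- module_set_enrichment(modules, gene_set("TRA", in_set))
  r1 <- res[res$module == 1, ]
  direct <- fisher_enrichment(genes, genes[assignment == 1],
                              gene_set("TRA", in_set))
  expect_equal(r1$odds_ratio, direct$odds_ratio)
  expect_equal(r1$p, direct$p)
  expect_gt(r1$odds_ratio, 4)      # expected cross-product OR ~ 9
  expect_lt(r1$odds_ratio, 20)
  # empty set: degenerate flag
  res0 <- module_set_enrichment(modules, gene_set("none", "zz"))
  expect_true(all(grepl("degenerate", res0$flags)))
})

test_that("population clustering: duplicate profiles get full support; determinism", {
  set.seed(44)
  mat <- matrix(rnorm(5 * 200), 5, 200,
                dimnames = list(paste0("p", 1:5), paste0("g", 1:200)))
  mat[2, ] <- mat[1, ] + rnorm(200, 0, 1e-8)      # near-identical pair
  cl <- cluster_populations(mat, n_boot = 100, seed = 2)
  pair_key <- "p1|p2"
  expect_equal(unname(cl$support[pair_key]), 1)
  expect_equal(cluster_populations(mat, n_boot = 100, seed = 2)$support,
               cl$support)
  expect_match(cl$newick, "^\\(")
  expect_error(cluster_populations(mat[1:2, ], n_boot = 50), "3 populations")
  flat <- mat; flat[3, ] <- 1
  expect_error(cluster_populations(flat, n_boot = 50), "zero-variance.*p3")
})

test_that("random profiles do not produce systematically certain clades", {
  # under independent noise, no internal (non-root) clade should be
  # recovered in 100% of bootstraps across many datasets
  set.seed(71)
  always_certain <- replicate(10, {
    mat <- matrix(rnorm(6 * 150), 6, 150,
                  dimnames = list(paste0("p", 1:6), paste0("g", 1:150)))
    cl <- cluster_populations(mat, n_boot = 60, seed = 1)
    internal <- cl$support[-length(cl$support)]   # drop the trivial root
    any(internal >= 1)
  })
  expect_lt(mean(always_certain), 0.5)
})

test_that("Spearman: monotone transforms, reversals, ties vs exhaustive enumeration", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6.0)
  expect_equal(spearman_compare(x, exp(x))$rho, 1)
  expect_equal(spearman_compare(x, -x)$rho, -1)
  expect_error(spearman_compare(x[1:4], x[1:4]), "5 paired")
  expect_error(spearman_compare(x, rep(1, 6)), "constant")
  # n = 6 with a tie: against a plain-loop enumeration of all 720 permutations
  y <- c(2, 2, 1, 4, 6, 5)
  got <- spearman_compare(x, y)
  ry <- rank(y); rx <- rank(x)
  # plain recursive enumeration, independent of the implementation's path
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in gen(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(gen(ry), function(p) cor(rx, p), numeric(1))
  expect_equal(got$p, mean(abs(rhos) >= abs(got$rho) - 1e-12), tolerance = 1e-12)
  expect_equal(got$rho, cor(rx, ry), tolerance = 1e-12)
  expect_equal(got$method, "exact permutation")
  # larger n uses the t approximation
  set.seed(3)
  big <- spearman_compare(rnorm(30), rnorm(30))
  expect_equal(big$method, "t approximation")
  expect_true(big$p >= 0 && big$p <= 1)
})
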