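# Hill q = 0 rarefaction/extrapolation, bootstrap SEs and Wald comparisons.

test_that("rarefied richness matches closed form, boundaries and vegan", {
  expect_equal(rarefy_richness(c(5, 3, 2), 4), 520 / 210, tolerance = 1e-12)
  expect_equal(rarefy_richness(c(5, 3, 2), 10), 3)      # m = N gives S_obs
  expect_equal(rarefy_richness(c(7), 3), 1)             # single gene
  expect_error(rarefy_richness(c(5, 3, 2), 11), "extrapolate")
  expect_error(rarefy_richness(c(5, 3), 2, q = 1), "order q = 0")
  skip_if_not_installed("vegan")
  set.seed(2)
  ab <- rpois(30, 5) + 1
  for (m in c(3, 10, 50)) {
    expect_equal(rarefy_richness(ab, m),
                 as.numeric(suppressWarnings(vegan::rarefy(ab, m))),
                 tolerance = 1e-8)
  }
})

test_that("rarefied richness equals exhaustive subsample enumeration (N <= 12)", {
  set.seed(4)
  cases <- list(c(5, 3, 2), c(1, 1, 2), c(4, 4, 4), c(2, 1, 1, 1, 1),
                c(6, 3, 1, 1), c(12))
  for (ab in cases) {
    N <- sum(ab)
    for (m in unique(c(1, 2, N %/% 2, N))) {
      expect_equal(rarefy_richness(ab, m), enum_rarefaction(ab, m),
                   tolerance = 1e-10,
                   label = sprintf("ab=%s m=%d", paste(ab, collapse = ","), m))
    }
  }
})

test_that("Chao1 and extrapolation follow their closed forms", {
  ch <- chao1(c(1, 1, 2))
  expect_equal(ch$f1, 2); expect_equal(ch$f2, 1)
  expect_equal(ch$S_est, 5)                    # 3 + 4/2
  expect_gte(ch$S_est, ch$S_obs)
  # no singletons: flat extrapolation, flagged
  flatx <- extrapolate_richness(c(3, 2, 5), c(11, 20))
  expect_true(attr(flatx, "flat"))
  expect_equal(as.numeric(flatx), c(3, 3))
  # limit behavior: approaches the Chao1 asymptote
  far <- extrapolate_richness(c(1, 1, 2), sum(c(1, 1, 2)) + 1e6)
  expect_equal(as.numeric(far), 5, tolerance = 1e-6)
  expect_error(extrapolate_richness(c(1, 1, 2), 4), "exceed N")
})

test_that("curves are monotone and continuous at the interpolation junction", {
  set.seed(6)
  ab <- c(rpois(40, 3) + 1, rep(1, 10))
  N <- sum(ab)
  curve <- diversity_curve(ab, m_grid = c(seq(1, N, length.out = 15), N + 1,
                                          seq(N + 2, 2 * N, length.out = 10)),
                           n_boot = 60, seed = 2)
  expect_true(all(diff(curve$qD) >= -1e-9))
  expect_equal(curve$qD[curve$m == N], length(ab))       # exact at N
  # continuity: value and first difference comparable across the junction
  below <- diff(rev(rev(curve$qD[curve$regime == "interp"])[1:2]))
  above <- curve$qD[curve$regime == "extrap"][1] - curve$qD[curve$m == N]
  expect_lt(abs(above - below), 1)
  expect_true(all(curve$se >= 0))
})

test_that("adding a duplicate cell never decreases richness; abundance pools correctly", {
  counts <- matrix(c(1, 0, 2,
                     0, 0, 3), 2, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  meta <- data.frame(cell_id = c("c1", "c2"), cell_type = "A",
                     genotype = "KO", animal = "a1")
  cm <- count_matrix(counts, meta)
  ab <- pooled_abundance(cm, "A")
  expect_equal(unname(ab), c(1, 5))            # zero-total gene dropped
  expect_equal(sum(ab), sum(counts))
  expect_error(pooled_abundance(cm, "missing"), "empty population")
  cm2 <- count_matrix(rbind(counts, c3 = counts["c1", ]),
                      rbind(meta, data.frame(cell_id = "c3", cell_type = "A",
                                             genotype = "KO", animal = "a1")))
  ab2 <- pooled_abundance(cm2, "A")
  # interior of the smaller sample's range: the augmented sample is never
  # poorer.  (At m = N exactly, the smaller sample is complete, qD = S_obs,
  # while the larger one is still subsampled there, so the boundary point
  # is excluded.)
  grid <- 1:(sum(ab) - 1)
  expect_true(all(rarefy_richness(ab2, grid) >= rarefy_richness(ab, grid) - 1e-9))
})

test_that("bootstrap SEs are stable, reproducible and honest about n_boot", {
  set.seed(10)
  ab <- rpois(60, 4) + 1
  grid <- c(20, sum(ab), 2 * sum(ab))
  s1 <- diversity_se(ab, grid, n_boot = 100, seed = 5)
  expect_equal(diversity_se(ab, grid, n_boot = 100, seed = 5), s1)
  s2 <- diversity_se(ab, grid, n_boot = 200, seed = 6)
  # doubling n_boot moves the SE by less than 3 MC SDs of an SE estimate
  expect_lt(max(abs(s2$se - s1$se) / (s1$se + 1e-9)), 3 * sqrt(2 / 99))
  expect_error(diversity_se(ab, grid, n_boot = 10), "n_boot")
})

test_that("Wald comparison: zero for identical curves, antisymmetric, powered at 2:1", {
  set.seed(8)
  ab <- rpois(50, 4) + 1
  c1 <- diversity_curve(ab, m_grid = c(10, 50, sum(ab)), n_boot = 60, seed = 1)
  res <- compare_to_reference(list(a = c1, ref = c1), "ref", m_star = 50)
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)
  # planted 2:1 richness: population A over 1000 genes, B over 500
  scA <- make_sc_counts(cell_types = "A", n_animals_per_genotype = 2,
                        cells_per_animal = 100, n_genes = 1000, n_isg = 10,
                        tonic_lfc = 0, libsize_mean = 3000, seed = 31)
  scB <- make_sc_counts(cell_types = "B", n_animals_per_genotype = 2,
                        cells_per_animal = 100, n_genes = 500, n_isg = 10,
                        tonic_lfc = 0, libsize_mean = 3000, seed = 32)
  abA <- pooled_abundance(scA$counts, "A")
  abB <- pooled_abundance(scB$counts, "B")
  m_star <- min(sum(abA), sum(abB))
  grid <- sort(unique(c(round(seq(1, m_star, length.out = 8)), m_star)))
  cA <- diversity_curve(abA, m_grid = grid, n_boot = 80, seed = 2, population = "A")
  cB <- diversity_curve(abB, m_grid = grid, n_boot = 80, seed = 3, population = "B")
  cmp <- compare_to_reference(list(A = cA, B = cB), "B", m_star = m_star)
  expect_gt(abs(cmp$Z), 3.29)
  swap <- compare_to_reference(list(A = cA, B = cB), "A", m_star = m_star)
  expect_equal(swap$Z, -cmp$Z, tolerance = 1e-9)
  expect_error(compare_to_reference(list(A = cA), "nope", m_star), "reference")
})
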