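# Synthetic-data generators with planted, machine-readable ground truth.
#
# Each generator is a pure function of its parameters and seed and emits a
# truth record sufficient to score the downstream stage (recall/precision,
# Jaccard, ARI) without re-reading generator internals.  The defaults
# mirror the structure of the study data: a multi-tissue bulk panel with
# planted tissue-restricted genes, KO-vs-control bulk mTEC transcriptomes
# (log2 scale, Gaussian noise, the microarray-style regime), multi-animal
# negative-binomial single-cell counts with planted tonic-ISG
# downregulation in the knockout, and paired rat/mouse DE tables with a
# planted conserved module.

#' Simulate a multi-tissue bulk panel with planted TRA genes
#'
#' Background genes sit at `expr_lo` plus Gaussian noise (truncated at 0)
#' in every sample; each planted TRA gets `expr_hi` in the samples of 1-3
#' randomly chosen tissue groups and background elsewhere.  Samples within
#' a true group share a gene-level group offset (SD `noise_sd`) on top of
#' which independent within-group noise (SD `noise_sd * within_frac`) is
#' added, so replicates are correlated and group structure is recoverable
#' by clustering.
#'
#' @param n_genes,n_tissue_samples,n_groups_true panel dimensions; samples
#'   are assigned to true groups round-robin so some groups have >= 2
#'   replicates.
#' @param n_tra number of planted tissue-restricted genes.
#' @param expr_hi,expr_lo expressing / background linear expression levels.
#' @param noise_sd SD of the shared group-level noise.
#' @param within_frac within-group noise SD as a fraction of `noise_sd`
#'   (default 0.5).
#' @param seed integer seed.
#' @return list with `expr` (linear-scale [expression_matrix]) and `truth`
#'   (list with `planted_tra`: data.frame gene/n_expressing_groups;
#'   `group_assignment`: named integer vector sample -> true group).
#' @export
make_tissue_panel <- function(n_genes = 2000, n_tissue_samples = 33,
                              n_groups_true = 11, n_tra = 50,
                              expr_hi = 1000, expr_lo = 10, noise_sd = 1,
                              within_frac = 0.5, seed = 1) {
  if (n_tra > n_genes) stop("n_tra must not exceed n_genes")
  if (!(expr_hi > expr_lo && expr_lo >= 0))
    stop("need expr_hi > expr_lo >= 0")
  if (n_tissue_samples < n_groups_true)
    stop("need at least n_groups_true samples")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- sprintf("sample_%02d", seq_len(n_tissue_samples))
  grp <- rep(seq_len(n_groups_true), length.out = n_tissue_samples)
  names(grp) <- samples
  base <- matrix(expr_lo, n_genes, n_groups_true,
                 dimnames = list(genes, NULL))
  tra_genes <- sort(sample(genes, n_tra))
  n_expr <- integer(n_tra)
  for (i in seq_along(tra_genes)) {
    k <- sample(1:3, 1)
    gs <- sample(n_groups_true, k)
    base[tra_genes[i], gs] <- expr_hi
    n_expr[i] <- k
  }
  delta <- matrix(stats::rnorm(n_genes * n_groups_true, 0, noise_sd),
                  n_genes, n_groups_true)
  values <- base[, grp] + delta[, grp] +
    matrix(stats::rnorm(n_genes * n_tissue_samples, 0, noise_sd * within_frac),
           n_genes, n_tissue_samples)
  values <- pmax(values, 0)
  colnames(values) <- samples
  meta <- data.frame(sample_id = samples, genotype = "WT",
                     group = sprintf("tissue_%02d", grp),
                     animal = samples, stringsAsFactors = FALSE)
  truth <- list(planted_tra = data.frame(gene = tra_genes,
                                         n_expressing_groups = n_expr,
                                         stringsAsFactors = FALSE),
                group_assignment = grp)
  list(expr = expression_matrix(values, meta, scale = "linear"), truth = truth)
}

#' Simulate KO-vs-control bulk mTEC transcriptomes
#'
#' Log2-scale matrix: null genes share a common mean across genotypes
#' (drawn Uniform over `baseline_range`); planted Aire-dependent genes
#' have their KO mean shifted by `lfc_effect` (negative = downregulated in
#' KO); Gaussian noise with SD `noise_sd`; values truncated at 0 to stay
#' on the log2(x+1) scale.
#'
#' @param n_genes,n_aire_dep matrix size and number of planted genes.
#' @param lfc_effect true log2 effect in KO.
#' @param n_ko,n_he replicates per genotype (>= 2 each; the DE test is
#'   undefined below that).
#' @param noise_sd Gaussian noise SD on log2 scale.
#' @param baseline_range range of baseline log2 means (default c(6, 12)).
#' @param seed integer seed.
#' @return list with `expr` (log2-scale [expression_matrix]) and `truth`
#'   (`planted_aire_dep`: data.frame gene/lfc).
#' @export
make_mtec_bulk <- function(n_genes = 2000, n_aire_dep = 100, lfc_effect = -4,
                           n_ko = 4, n_he = 3, noise_sd = 0.25,
                           baseline_range = c(6, 12), seed = 1) {
  if (n_ko < 2 || n_he < 2) stop("need >= 2 replicates per genotype")
  if (n_aire_dep > n_genes) stop("n_aire_dep must not exceed n_genes")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- c(sprintf("KO_%d", seq_len(n_ko)), sprintf("HE_%d", seq_len(n_he)))
  genotype <- c(rep("KO", n_ko), rep("HE", n_he))
  base <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  aire_genes <- sort(sample(genes, n_aire_dep))
  mu <- matrix(base, n_genes, length(samples), dimnames = list(genes, samples))
  mu[aire_genes, genotype == "KO"] <- mu[aire_genes, genotype == "KO"] + lfc_effect
  values <- pmax(mu + matrix(stats::rnorm(length(mu), 0, noise_sd),
                             n_genes, length(samples)), 0)
  meta <- data.frame(sample_id = samples, genotype = genotype,
                     group = "mTEC_hi",
                     animal = samples, stringsAsFactors = FALSE)
  truth <- list(planted_aire_dep = data.frame(gene = aire_genes,
                                              lfc = lfc_effect,
                                              stringsAsFactors = FALSE))
  list(expr = expression_matrix(values, meta, scale = "log2"), truth = truth)
}

#' Simulate multi-cell-type, multi-animal single-cell UMI counts
#'
#' Negative-binomial counts with a global dispersion: the mean of gene g in
#' a cell is library_size x gene_proportion x genotype_effect, where the
#' genotype effect is 2^tonic_lfc for tonic-sensitive ISGs in KO cells and
#' 1 otherwise.  Library sizes are log-normal around `libsize_mean`; gene
#' proportions are a fixed Dirichlet-like draw shared by all cell types.
#'
#' @param cell_types character vector of cell type labels.
#' @param n_animals_per_genotype animals per genotype (genotypes KO, HE).
#' @param cells_per_animal cells per (animal, cell type) stratum.
#' @param n_genes,n_isg total genes and ISG-set size.
#' @param frac_tonic fraction of ISGs that are tonic-sensitive.
#' @param tonic_lfc true log2 effect of KO on tonic-sensitive ISGs.
#' @param libsize_mean mean library size (UMIs per cell).
#' @param libsize_sdlog log-normal SD of library sizes (default 0.3).
#' @param nb_dispersion negative-binomial dispersion phi > 0
#'   (variance = mu + phi mu^2, i.e. size = 1/phi).
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix]), `isg_set` (a [gene_set]
#'   with `tonic_sensitive` labels) and `truth` (`planted_isg`:
#'   data.frame gene/tonic_sensitive/true_lfc).
#' @export
make_sc_counts <- function(cell_types = c("B_cell", "Macrophage", "NK"),
                           n_animals_per_genotype = 3, cells_per_animal = 100,
                           n_genes = 2000, n_isg = 100, frac_tonic = 0.5,
                           tonic_lfc = -2, libsize_mean = 5000,
                           libsize_sdlog = 0.3, nb_dispersion = 0.1, seed = 1) {
  if (length(cell_types) == 0) stop("cell_types must be non-empty")
  if (frac_tonic < 0 || frac_tonic > 1) stop("frac_tonic must lie in [0, 1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_isg > n_genes) stop("n_isg must not exceed n_genes")
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  isg_genes <- sort(sample(genes, n_isg))
  n_tonic <- round(frac_tonic * n_isg)
  tonic_genes <- sort(sample(isg_genes, n_tonic))
  prop <- stats::rgamma(n_genes, shape = 0.8)
  prop <- prop / sum(prop)
  names(prop) <- genes
  animals <- c(sprintf("KO_%d", seq_len(n_animals_per_genotype)),
               sprintf("HE_%d", seq_len(n_animals_per_genotype)))
  genotype_of <- stats::setNames(rep(c("KO", "HE"), each = n_animals_per_genotype),
                                 animals)
  effect <- rep(1, n_genes)
  names(effect) <- genes
  meta_rows <- list()
  blocks <- list()
  cell_counter <- 0L
  for (an in animals) {
    for (ct in cell_types) {
      nc <- cells_per_animal
      ids <- sprintf("cell_%05d", cell_counter + seq_len(nc))
      cell_counter <- cell_counter + nc
      lib <- stats::rlnorm(nc, meanlog = log(libsize_mean) - libsize_sdlog^2 / 2,
                           sdlog = libsize_sdlog)
      eff <- effect
      if (genotype_of[[an]] == "KO") eff[tonic_genes] <- 2^tonic_lfc
      mu <- outer(lib, prop * eff)
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                    nrow = nc, dimnames = list(ids, genes))
      blocks[[length(blocks) + 1L]] <- cnt
      meta_rows[[length(meta_rows) + 1L]] <-
        data.frame(cell_id = ids, cell_type = ct,
                   genotype = genotype_of[[an]], animal = an,
                   stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta_rows)
  labels <- stats::setNames(isg_genes %in% tonic_genes, isg_genes)
  truth <- list(planted_isg = data.frame(
    gene = isg_genes, tonic_sensitive = isg_genes %in% tonic_genes,
    true_lfc = ifelse(isg_genes %in% tonic_genes, tonic_lfc, 0),
    stringsAsFactors = FALSE))
  list(counts = count_matrix(counts, meta),
       isg_set = gene_set("ISG", isg_genes, labels = labels),
       truth = truth)
}

#' Simulate a synthetic tonic-sensitivity reference contrast
#'
#' Stands in for a baseline interferon-receptor-knockout vs wild-type DE
#' table (synthetic; no external dataset is used): planted tonic-sensitive
#' genes get a strong negative LFC with tiny FDR, everything else is null.
#'
#' @param isg_set ISG [gene_set] whose `tonic_sensitive` labels define the
#'   planted classes.
#' @param extra_genes additional null genes to pad the reference universe.
#' @param tonic_lfc reference effect for tonic genes (default -3).
#' @param seed integer seed.
#' @return DE table (gene, lfc, p, fdr).
#' @export
make_tonic_reference <- function(isg_set, extra_genes = character(0),
                                 tonic_lfc = -3, seed = 1) {
  set.seed(seed)
  genes <- unique(c(isg_set$genes, extra_genes))
  tonic <- genes %in% names(isg_set$labels)[isg_set$labels]
  lfc <- stats::rnorm(length(genes), 0, 0.2)
  lfc[tonic] <- tonic_lfc + stats::rnorm(sum(tonic), 0, 0.3)
  p <- ifelse(tonic, stats::runif(length(genes), 1e-12, 1e-6),
              stats::runif(length(genes), 0.2, 1))
  data.frame(gene = genes, lfc = lfc, p = p,
             fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

#' Simulate paired rat/mouse DE tables with a planted conserved module
#'
#' Genes are split evenly into `n_modules` modules over a one-to-one
#' ortholog map.  Module 1 is downregulated in KO in every dataset
#' (conserved); module 2 only in the rat; module 3 in every mouse dataset;
#' further modules are null.  Non-affected entries are null noise.  TRA
#' membership is planted at `conserved_module_frac_tra` inside the
#' conserved module and `background_frac_tra` elsewhere.
#'
#' @param n_genes orthologous genes.
#' @param n_datasets_mouse number of mouse DE tables (default 4).
#' @param n_modules number of modules (>= 2; default 4).
#' @param conserved_module_frac_tra,background_frac_tra TRA rates.
#' @param effect,effect_sd affected-entry LFC distribution (default
#'   N(-3, 0.3)).
#' @param null_sd null-entry LFC SD (default 0.3).
#' @param lfc_se standard error used to convert LFCs to p values.
#' @param seed integer seed.
#' @return list with `rat_de` (DE table on rat ids), `mouse_des` (named
#'   list of DE tables on mouse ids), `ortholog_map` (data.frame
#'   rat_gene/mouse_gene), `tra_set` (a [gene_set] on rat ids) and `truth`
#'   (`modules`: named integer vector rat gene -> module).
#' @export
make_cross_species <- function(n_genes = 1000, n_datasets_mouse = 4,
                               n_modules = 4, conserved_module_frac_tra = 0.5,
                               background_frac_tra = 0.1, effect = -3,
                               effect_sd = 0.3, null_sd = 0.3, lfc_se = 0.4,
                               seed = 1) {
  if (n_modules < 2) stop("n_modules must be >= 2")
  set.seed(seed)
  rat <- sprintf("rg_%04d", seq_len(n_genes))
  mouse <- sprintf("mg_%04d", seq_len(n_genes))
  module <- sample(rep(seq_len(n_modules), length.out = n_genes))
  names(module) <- rat
  datasets <- c("rat", sprintf("mouse_%d", seq_len(n_datasets_mouse)))
  affected <- function(m, ds) {
    if (m == 1) TRUE
    else if (m == 2) ds == "rat"
    else if (m == 3) grepl("^mouse", ds)
    else FALSE
  }
  de_for <- function(ds, ids) {
    hit <- vapply(module, affected, logical(1), ds = ds)
    lfc <- stats::rnorm(n_genes, 0, null_sd)
    lfc[hit] <- stats::rnorm(sum(hit), effect, effect_sd)
    p <- 2 * stats::pnorm(-abs(lfc) / lfc_se)
    data.frame(gene = ids, lfc = lfc, p = p, fdr = stats::p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  }
  rat_de <- de_for("rat", rat)
  mouse_des <- stats::setNames(
    lapply(datasets[-1], de_for, ids = mouse), datasets[-1])
  tra_prob <- ifelse(module == 1, conserved_module_frac_tra, background_frac_tra)
  tra_genes <- rat[stats::runif(n_genes) < tra_prob]
  list(rat_de = rat_de, mouse_des = mouse_des,
       ortholog_map = data.frame(rat_gene = rat, mouse_gene = mouse,
                                 provenance = "synthetic",
                                 stringsAsFactors = FALSE),
       tra_set = gene_set("TRA", tra_genes),
       truth = list(modules = module))
}
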