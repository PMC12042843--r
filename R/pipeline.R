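# Pipeline orchestration.
#
# Stages run in a fixed order (simulate -> tra-call -> de -> enrich ->
# gsea -> ifn-score -> diversity -> cross-species); every stage is
# file-based: it reads the run directory written by earlier stages and
# writes its own outputs, so each stage also runs standalone (this is what
# the CLI subcommands call).  Every output table carries the config hash
# and seed in a `#` header comment, and a JSON summary is written per
# stage.  Deterministic stages are byte-identical across reruns of the
# same configuration.

.stage_order <- c("simulate", "tra-call", "de", "enrich", "gsea",
                  "ifn-score", "diversity", "cross-species")

.read_de <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.write_summary <- function(dir, stage, x) {
  jsonlite::write_json(x, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage on a run directory
#'
#' @param stage one of simulate, tra-call, de, enrich, gsea, ifn-score,
#'   diversity, cross-species.
#' @param config a `pipeline_config`.
#' @param run_dir run directory (created if needed); earlier stages must
#'   already have written their outputs there.
#' @return invisibly, the stage output directory.
#' @export
run_stage <- function(stage, config, run_dir) {
  stage <- match.arg(stage, .stage_order)
  config <- validate_config(config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  fun <- switch(stage,
                "simulate" = .stage_simulate,
                "tra-call" = .stage_tra,
                "de" = .stage_de,
                "enrich" = .stage_enrich,
                "gsea" = .stage_gsea,
                "ifn-score" = .stage_ifn,
                "diversity" = .stage_diversity,
                "cross-species" = .stage_cross_species)
  out_dir <- file.path(run_dir, sub("-", "_", stage, fixed = TRUE))
  tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fun(config, run_dir, out_dir)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s (partial outputs under %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' Executes all stages in order on synthetic inputs generated by the
#' simulate stage, writing TSV/JSON outputs under `run_dir`.
#'
#' @param config a `pipeline_config` (see [pipeline_config]).
#' @param run_dir output directory.
#' @return invisibly, `run_dir`.
#' @export
run_pipeline <- function(config, run_dir) {
  config <- validate_config(config)
  for (stage in .stage_order) {
    at_log("pipeline", "running stage %s", stage)
    run_stage(stage, config, run_dir)
  }
  invisible(run_dir)
}

.stage_simulate <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  sim <- config$simulate
  panel <- do.call(make_tissue_panel,
                   c(sim$tissue_panel, list(seed = stage_seed(config$seed, "simulate.panel"))))
  write_expression_matrix(panel$expr,
                          file.path(out_dir, "tissue_panel.tsv"),
                          file.path(out_dir, "tissue_panel_meta.tsv"),
                          header = sprintf("airetonic stage=simulate seed=%d config=%s",
                                           config$seed, hash))
  bulk <- do.call(make_mtec_bulk,
                  c(sim$mtec_bulk, list(seed = stage_seed(config$seed, "simulate.bulk"))))
  write_expression_matrix(bulk$expr,
                          file.path(out_dir, "mtec_bulk.tsv"),
                          file.path(out_dir, "mtec_bulk_meta.tsv"),
                          header = sprintf("airetonic stage=simulate seed=%d config=%s",
                                           config$seed, hash))
  sc <- do.call(make_sc_counts,
                c(sim$sc_counts, list(seed = stage_seed(config$seed, "simulate.sc"))))
  write_count_matrix(sc$counts, file.path(out_dir, "sc"))
  write_gmt(list(sc$isg_set), file.path(out_dir, "isg.gmt"))
  tonic_tab <- data.frame(gene = names(sc$isg_set$labels),
                          tonic_sensitive = sc$isg_set$labels)
  write_stage_table(tonic_tab, file.path(out_dir, "isg_tonic_truth.tsv"),
                    "simulate", config$seed, hash)
  ref <- make_tonic_reference(sc$isg_set,
                              extra_genes = setdiff(colnames(sc$counts$counts),
                                                    sc$isg_set$genes),
                              seed = stage_seed(config$seed, "simulate.ref"))
  write_stage_table(ref, file.path(out_dir, "reference_de.tsv"),
                    "simulate", config$seed, hash)
  cs <- do.call(make_cross_species,
                c(sim$cross_species, list(seed = stage_seed(config$seed, "simulate.cs"))))
  cs_dir <- file.path(out_dir, "cross_species")
  dir.create(cs_dir, showWarnings = FALSE)
  write_stage_table(cs$rat_de, file.path(cs_dir, "rat_de.tsv"),
                    "simulate", config$seed, hash)
  for (ds in names(cs$mouse_des))
    write_stage_table(cs$mouse_des[[ds]], file.path(cs_dir, paste0(ds, "_de.tsv")),
                      "simulate", config$seed, hash)
  write_stage_table(cs$ortholog_map, file.path(cs_dir, "ortholog_map.tsv"),
                    "simulate", config$seed, hash)
  write_gmt(list(cs$tra_set), file.path(cs_dir, "tra.gmt"))
  truth <- list(planted_tra = panel$truth$planted_tra,
                tissue_group_assignment = as.list(panel$truth$group_assignment),
                planted_aire_dep = bulk$truth$planted_aire_dep,
                planted_isg = sc$truth$planted_isg,
                planted_modules = as.list(cs$truth$modules))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_summary(out_dir, "simulate",
                 list(stage = "simulate", seed = config$seed, config = hash,
                      n_panel_genes = nrow(panel$expr$values),
                      n_bulk_genes = nrow(bulk$expr$values),
                      n_cells = nrow(sc$counts$counts)))
}

.stage_tra <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  expr <- read_expression_matrix(file.path(run_dir, "simulate", "tissue_panel.tsv"),
                                 file.path(run_dir, "simulate", "tissue_panel_meta.tsv"),
                                 scale = "linear")
  groups <- reduce_to_groups(expr, n_groups = config$tra$n_groups)
  calls <- call_tra(groups, j_max = config$tra$j_max,
                    form = config$tra$threshold_form)
  write_stage_table(calls, file.path(out_dir, "tra_calls.tsv"),
                    "tra-call", config$seed, hash)
  assign_tab <- data.frame(sample_id = names(groups$assignment),
                           group = groups$assignment)
  write_stage_table(assign_tab, file.path(out_dir, "group_assignment.tsv"),
                    "tra-call", config$seed, hash)
  .write_summary(out_dir, "tra-call",
                 list(stage = "tra-call", seed = config$seed, config = hash,
                      n_genes = nrow(calls), n_tra = sum(calls$is_tra),
                      n_groups = config$tra$n_groups, j_max = config$tra$j_max,
                      threshold_form = config$tra$threshold_form))
}

.stage_de <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  bulk <- read_expression_matrix(file.path(run_dir, "simulate", "mtec_bulk.tsv"),
                                 file.path(run_dir, "simulate", "mtec_bulk_meta.tsv"),
                                 scale = "log2")
  ko <- bulk$sample_meta$sample_id[bulk$sample_meta$genotype == "KO"]
  he <- bulk$sample_meta$sample_id[bulk$sample_meta$genotype != "KO"]
  de <- de_test(bulk, ko, he)
  write_stage_table(de, file.path(out_dir, "de_mtec.tsv"), "de", config$seed, hash)
  aire <- define_aire_dependent(de, config$thresholds$lfc_cut,
                                config$thresholds$fdr_cut)
  write_gmt(list(aire), file.path(out_dir, "aire_dependent.gmt"))
  cm <- read_count_matrix(file.path(run_dir, "simulate", "sc"),
                          file.path(run_dir, "simulate", "sc", "meta.tsv"))
  des <- pseudobulk_de_by_celltype(cm)
  for (ct in names(des))
    write_stage_table(des[[ct]], file.path(out_dir, sprintf("de_sc_%s.tsv", ct)),
                      "de", config$seed, hash)
  .write_summary(out_dir, "de",
                 list(stage = "de", seed = config$seed, config = hash,
                      n_aire_dependent = length(aire$genes),
                      cell_types = names(des)))
}

.sc_de_tables <- function(run_dir) {
  files <- list.files(file.path(run_dir, "de"), pattern = "^de_sc_.*\\.tsv$",
                      full.names = TRUE)
  tabs <- lapply(files, .read_de)
  names(tabs) <- sub("^de_sc_(.*)\\.tsv$", "\\1", basename(files))
  tabs
}

.stage_enrich <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  tonic <- .read_tonic(run_dir, config)
  tonic_set <- gene_set("tonic_ISG",
                        tonic$gene[tonic$status == "tonic_sensitive"])
  des <- .sc_de_tables(run_dir)
  enr <- enrichment_by_population(des, tonic_set,
                                  lfc_cut = config$thresholds$lfc_cut,
                                  fdr_cut = config$thresholds$fdr_cut)
  write_stage_table(enr, file.path(out_dir, "isg_enrichment.tsv"),
                    "enrich", config$seed, hash)
  .write_summary(out_dir, "enrich",
                 list(stage = "enrich", seed = config$seed, config = hash,
                      min_or = min(enr$odds_ratio),
                      max_holm_p = max(enr$holm_p)))
}

.read_tonic <- function(run_dir, config) {
  isg <- read_gmt(file.path(run_dir, "simulate", "isg.gmt"))[[1]]
  ref <- .read_de(file.path(run_dir, "simulate", "reference_de.tsv"))
  classify_tonic(ref, isg, lfc_cut = config$thresholds$lfc_cut,
                 fdr_cut = config$thresholds$fdr_cut)
}

.stage_gsea <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  isg <- read_gmt(file.path(run_dir, "simulate", "isg.gmt"))[[1]]
  des <- .sc_de_tables(run_dir)
  rows <- list()
  for (ct in names(des)) {
    de <- des[[ct]]
    ranked <- stats::setNames(de$t, de$gene)
    res <- gsea_preranked(ranked, isg, weight = config$gsea$weight,
                          n_perm = config$gsea$n_perm,
                          seed = stage_seed(config$seed, paste0("gsea.", ct)))
    rows[[ct]] <- data.frame(population = ct, set = res$set, size = res$size,
                             es = res$es, nes = res$nes, p_perm = res$p_perm,
                             n_perm = res$n_perm, stringsAsFactors = FALSE)
    write_stage_table(res$running,
                      file.path(out_dir, sprintf("running_%s.tsv", ct)),
                      "gsea", config$seed, hash)
  }
  tab <- do.call(rbind, rows)
  write_stage_table(tab, file.path(out_dir, "gsea.tsv"), "gsea", config$seed, hash)
  .write_summary(out_dir, "gsea",
                 list(stage = "gsea", seed = config$seed, config = hash,
                      mean_nes = mean(tab$nes)))
}

.stage_ifn <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  tonic <- .read_tonic(run_dir, config)
  write_stage_table(tonic, file.path(out_dir, "tonic_labels.tsv"),
                    "ifn-score", config$seed, hash)
  cm <- read_count_matrix(file.path(run_dir, "simulate", "sc"),
                          file.path(run_dir, "simulate", "sc", "meta.tsv"))
  scores <- ifn_score_table(cm, tonic)
  write_stage_table(scores, file.path(out_dir, "ifn_scores.tsv"),
                    "ifn-score", config$seed, hash)
  .write_summary(out_dir, "ifn-score",
                 list(stage = "ifn-score", seed = config$seed, config = hash,
                      mean_score = mean(scores$score),
                      n_scores = nrow(scores)))
}

.stage_diversity <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  cm <- read_count_matrix(file.path(run_dir, "simulate", "sc"),
                          file.path(run_dir, "simulate", "sc", "meta.tsv"))
  pops <- unique(cm$cell_meta$cell_type)
  abunds <- lapply(pops, function(p) pooled_abundance(cm, p))
  names(abunds) <- pops
  m_star <- 2 * min(vapply(abunds, sum, numeric(1)))
  grid_for <- function(ab) {
    N <- sum(ab)
    sort(unique(c(round(seq(1, N, length.out = 10)), N, m_star)))
  }
  curves <- lapply(pops, function(p)
    diversity_curve(abunds[[p]], m_grid = grid_for(abunds[[p]]),
                    n_boot = config$diversity$n_boot,
                    seed = stage_seed(config$seed, paste0("diversity.", p)),
                    population = p))
  names(curves) <- pops
  tab <- do.call(rbind, lapply(pops, function(p)
    cbind(population = p, as.data.frame(curves[[p]]))))
  write_stage_table(tab, file.path(out_dir, "curves.tsv"),
                    "diversity", config$seed, hash)
  cmp <- compare_to_reference(curves, reference = pops[1], m_star = m_star)
  write_stage_table(cmp, file.path(out_dir, "comparison.tsv"),
                    "diversity", config$seed, hash)
  .write_summary(out_dir, "diversity",
                 list(stage = "diversity", seed = config$seed, config = hash,
                      reference = pops[1], m_star = m_star))
}

.stage_cross_species <- function(config, run_dir, out_dir) {
  hash <- config_hash(unclass(config))
  cs_dir <- file.path(run_dir, "simulate", "cross_species")
  rat_de <- .read_de(file.path(cs_dir, "rat_de.tsv"))
  mouse_files <- list.files(cs_dir, pattern = "^mouse_.*_de\\.tsv$",
                            full.names = TRUE)
  mouse_des <- lapply(mouse_files, .read_de)
  names(mouse_des) <- sub("_de\\.tsv$", "", basename(mouse_files))
  map <- read_ortholog_map(file.path(cs_dir, "ortholog_map.tsv"))
  tra <- read_gmt(file.path(cs_dir, "tra.gmt"))[[1]]
  combined <- combine_orthologs(rat_de, mouse_des, map)
  k <- config$simulate$cross_species$n_modules
  if (is.null(k)) k <- 4
  modules <- kmeans_modules(combined, k = k,
                            seed = stage_seed(config$seed, "cross.kmeans"))
  mod_tab <- data.frame(gene = names(modules$assignment),
                        module = modules$assignment,
                        as.data.frame(combined[names(modules$assignment), ,
                                               drop = FALSE]))
  write_stage_table(mod_tab, file.path(out_dir, "modules.tsv"),
                    "cross-species", config$seed, hash)
  enr <- module_set_enrichment(modules, tra)
  write_stage_table(enr, file.path(out_dir, "module_tra_enrichment.tsv"),
                    "cross-species", config$seed, hash)
  pca <- pca_samples(t(replace(combined, is.na(combined), 0)))
  pca_tab <- data.frame(dataset = rownames(pca$coordinates),
                        pca$coordinates[, seq_len(min(4, ncol(pca$coordinates))),
                                        drop = FALSE])
  write_stage_table(pca_tab, file.path(out_dir, "pca.tsv"),
                    "cross-species", config$seed, hash)
  cm <- read_count_matrix(file.path(run_dir, "simulate", "sc"),
                          file.path(run_dir, "simulate", "sc", "meta.tsv"))
  pb <- pseudobulk(cm, by = "cell_type", min_cells = 1)
  clust <- cluster_populations(pb$log2cpm, n_boot = min(200, config$diversity$n_boot * 2),
                               seed = stage_seed(config$seed, "cross.boot"))
  writeLines(clust$newick, file.path(out_dir, "populations.nwk"))
  sp <- spearman_compare(combined[, "rat"], combined[, 2])
  sp_tab <- data.frame(dataset_a = "rat", dataset_b = colnames(combined)[2],
                       rho = sp$rho, p = sp$p, n = sp$n, method = sp$method)
  write_stage_table(sp_tab, file.path(out_dir, "spearman.tsv"),
                    "cross-species", config$seed, hash)
  .write_summary(out_dir, "cross-species",
                 list(stage = "cross-species", seed = config$seed, config = hash,
                      k = k, module_sizes = modules$sizes,
                      spearman_rho = sp$rho))
}

#' Pseudobulk DE per cell type
#'
#' Sums counts to (animal, cell type) strata and runs the KO-vs-control
#' Welch test within each cell type.
#'
#' @param cm a [count_matrix] with genotype metadata.
#' @param min_cells minimum cells per stratum (default 10).
#' @param control_genotypes genotypes treated as controls (default HE, WT).
#' @return named list of DE tables, one per cell type with at least two
#'   strata per genotype.
#' @export
pseudobulk_de_by_celltype <- function(cm, min_cells = 10,
                                      control_genotypes = c("HE", "WT")) {
  pb <- pseudobulk(cm, by = c("animal", "cell_type"), min_cells = min_cells)
  out <- list()
  for (ct in unique(pb$meta$cell_type)) {
    meta <- pb$meta[pb$meta$cell_type == ct, ]
    ko <- meta$stratum[!meta$genotype %in% control_genotypes]
    ctrl <- meta$stratum[meta$genotype %in% control_genotypes]
    if (length(ko) < 2 || length(ctrl) < 2) {
      at_log("pseudobulk_de", "skipping %s: <2 replicates per genotype", ct,
             level = "warn")
      next
    }
    sub <- structure(list(log2cpm = pb$log2cpm[c(ko, ctrl), , drop = FALSE],
                          counts = pb$counts[c(ko, ctrl), , drop = FALSE],
                          meta = meta), class = "pseudobulk")
    out[[ct]] <- de_test(sub, ko, ctrl)
  }
  out
}
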