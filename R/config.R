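# Structured pipeline configuration.
#
# A flat YAML file with sections; the seed is mandatory because every
# stochastic stage draws from a generator derived from (global seed, stage
# name) via stage_seed(), so stages are independently reproducible.

#' Default pipeline configuration
#'
#' @param seed mandatory integer seed for all stochastic stages.
#' @param thresholds list(lfc_cut, fdr_cut) used for Aire-dependent gene
#'   definition, tonic classification and enrichment hits.
#' @param tra list(n_groups, j_max, threshold_form) for the TRA caller.
#' @param gsea list(n_perm, weight).
#' @param diversity list(n_boot, extrapolation_factor).
#' @param simulate named list of generator overrides, keyed
#'   `tissue_panel`, `mtec_bulk`, `sc_counts`, `cross_species` (arguments
#'   of the respective make_* functions, minus `seed`).
#' @return validated `pipeline_config` object.
#' @export
pipeline_config <- function(seed,
                            thresholds = list(lfc_cut = -1, fdr_cut = 0.05),
                            tra = list(n_groups = 11, j_max = 5,
                                       threshold_form = "gap"),
                            gsea = list(n_perm = 1000, weight = 1),
                            diversity = list(n_boot = 200,
                                             extrapolation_factor = 2),
                            simulate = list()) {
  cfg <- list(seed = seed, thresholds = thresholds, tra = tra, gsea = gsea,
              diversity = diversity, simulate = simulate)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list.
#' @return the configuration, classed `pipeline_config`, or an error.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop("validation error: seed is mandatory (stochastic stages present)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed != round(cfg$seed))
    stop("validation error: seed must be a single integer")
  defaults <- list(thresholds = list(lfc_cut = -1, fdr_cut = 0.05),
                   tra = list(n_groups = 11, j_max = 5, threshold_form = "gap"),
                   gsea = list(n_perm = 1000, weight = 1),
                   diversity = list(n_boot = 200, extrapolation_factor = 2),
                   simulate = list())
  for (sec in names(defaults)) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], as.list(cfg[[sec]]))
  }
  with(cfg, {
    if (thresholds$fdr_cut <= 0 || thresholds$fdr_cut > 1)
      stop("validation error: fdr_cut must lie in (0, 1]")
    if (tra$n_groups < 2) stop("validation error: tra n_groups must be >= 2")
    if (tra$j_max < 1 || tra$j_max >= tra$n_groups)
      stop("validation error: need 1 <= j_max < n_groups")
    if (!tra$threshold_form %in% c("gap", "saturating"))
      stop("validation error: threshold_form must be gap or saturating")
    if (gsea$n_perm < 100) stop("validation error: gsea n_perm must be >= 100")
    if (gsea$weight < 0) stop("validation error: gsea weight must be >= 0")
    if (diversity$n_boot < 50) stop("validation error: diversity n_boot must be >= 50")
    if (diversity$extrapolation_factor <= 1)
      stop("validation error: extrapolation_factor must exceed 1")
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
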