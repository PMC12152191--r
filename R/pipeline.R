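# End-to-end pipeline driver: one validated configuration, deterministic
# outputs under a fixed seed, and a machine-readable run report. The thin
# command-line wrapper in inst/scripts/dropout3d.R maps onto these
# functions; input-validation failures and computation failures carry
# distinct condition classes so the wrapper can exit 2 vs 3.

.RUN_CONFIG_DEFAULTS <- function() list(
  seed = 1L,
  out_dir = "dropout3d_out",
  inputs = list(library = NULL, samples = NULL, counts = NULL),
  simulate = list(enabled = TRUE),       # plus any simConfig() field
  score = list(pseudocount = 0.5, pairing = "replicate", welch = FALSE,
               size_factor_method = "median_ratio", min_eligible = 100L),
  call = list(gene_lfc_max = -0.1, min_guides_dropped = 3L,
              guide_drop_max = -0.1, exclusive_mode = "both_days"),
  prioritize = list(membership = NULL, survival = NULL, top_n = 20L,
                    min_count = 9L, hr_min = 1, p_max = 0.05))

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      .input_error("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(user[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list; unknown keys are rejected by name,
#' and every parameter has a documented default. Sections: `seed`,
#' `out_dir`, `inputs` (library/samples/counts TSV paths), `simulate`
#' (`enabled` plus any [simConfig()] field, used when no counts are given),
#' `score`, `call`, `prioritize`.
#'
#' @param config YAML path or list
#' @return validated configuration list
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) .input_error("config must be a list or a YAML path")
  sim_defaults <- .RUN_CONFIG_DEFAULTS()
  sim_extra <- config$simulate
  if (!is.null(sim_extra)) {
    sim_keys <- setdiff(names(sim_extra), "enabled")
    allowed <- names(formals(simConfig))
    bad <- setdiff(sim_keys, allowed)
    if (length(bad))
      .input_error("unknown configuration key: ",
                   paste0("simulate.", bad[1]))
    sim_defaults$simulate <- c(sim_defaults$simulate,
                               stats::setNames(vector("list", length(sim_keys)),
                                               sim_keys))
  }
  cfg <- .merge_config(sim_defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) .input_error("seed must be an integer")
  cfg
}

#' Run the full screen-analysis pipeline
#'
#' Stages: load or simulate a screen; compute enrichment and phenotype
#' scores; call dropouts and the exclusivity partition; when simulating,
#' score truth recovery; when annotation tables are configured, run the
#' prioritization cascade on the 3D-exclusive set. All outputs are TSV/JSON
#' under `out_dir`, plus a `run_report.json` capturing package version,
#' parameters and per-stage summary counts. Deterministic given the
#' configuration (including its seed).
#'
#' @param config YAML path or list, see [runConfig()]
#' @return the run report, invisibly
#' @export
runPipeline <- function(config = list()) {
  cfg <- runConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "dropout3d",
                 version = as.character(utils::packageVersion("dropout3d")),
                 parameters = cfg, stages = list())
  truth <- NULL
  if (!is.null(cfg$inputs$counts)) {
    library <- readGuideLibrary(cfg$inputs$library)
    design <- readSampleSheet(cfg$inputs$samples)
    se <- readCounts(cfg$inputs$counts, library, design)
    report$stages$load <- list(n_guides = length(library),
                               n_samples = ncol(se))
  } else if (isTRUE(cfg$simulate$enabled)) {
    sim_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    sim_args <- sim_args[!vapply(sim_args, is.null, logical(1))]
    if (!"seed" %in% names(sim_args)) sim_args$seed <- cfg$seed
    scfg <- do.call(simConfig, sim_args)
    sim <- simulateScreenExperiment(scfg)
    se <- sim$se; library <- sim$library; truth <- sim$truth
    writeGuideLibrary(library, file.path(cfg$out_dir, "library.tsv"))
    writeSampleSheet(screenDesign(se), file.path(cfg$out_dir, "samples.tsv"))
    writeCounts(se, file.path(cfg$out_dir, "counts.tsv"))
    .write_tsv(truthEffects(truth), file.path(cfg$out_dir, "truth_guides.tsv"))
    .write_tsv(truth@genes, file.path(cfg$out_dir, "truth_genes.tsv"))
    report$stages$simulate <- list(n_guides = length(library),
                                   n_samples = ncol(se),
                                   seed = scfg$seed)
  } else {
    .input_error("either inputs.counts or simulate.enabled must be set")
  }
  vr <- validateDesign(se)
  report$stages$validate <- list(n_comparisons = nrow(vr$comparisons),
                                 warnings = vr$warnings)
  et <- logFoldEnrichment(se, pseudocount = cfg$score$pseudocount,
                          pairing = cfg$score$pairing,
                          method = cfg$score$size_factor_method,
                          minEligible = cfg$score$min_eligible)
  writeEnrichment(et, file.path(cfg$out_dir, "enrichment.tsv"))
  pheno <- screenPhenotypes(et, library,
                            guideDropMax = cfg$call$guide_drop_max,
                            welch = cfg$score$welch)
  writePhenotypes(pheno, file.path(cfg$out_dir, "phenotypes.tsv"),
                  file.path(cfg$out_dir, "controls.tsv"))
  report$stages$score <- list(n_genes = length(unique(genePhenotypes(pheno)$gene)),
                              n_comparisons = length(unique(genePhenotypes(pheno)$comparison)))
  ccfg <- callConfig(geneLfcMax = cfg$call$gene_lfc_max,
                     minGuidesDropped = cfg$call$min_guides_dropped,
                     guideDropMax = cfg$call$guide_drop_max)
  sets <- callDropouts(pheno, ccfg)
  for (nm in names(sets))
    .write_tsv(data.frame(gene = sets[[nm]], stringsAsFactors = FALSE),
               file.path(cfg$out_dir, paste0("called_", nm, ".tsv")))
  partition <- exclusivityPartition(
    sets, universe = sort(targetedGenes(library)),
    mode = cfg$call$exclusive_mode)
  writePartition(partition, file.path(cfg$out_dir, "partition.tsv"),
                 file.path(cfg$out_dir, "upset_membership.tsv"))
  lab <- partitionLabels(partition)
  report$stages$call <- c(list(per_comparison = lapply(sets, length)),
                          as.list(table(factor(lab, levels = .PARTITION_LABELS))))
  if (!is.null(truth)) {
    rec <- evaluateRecovery(partition, truth)
    jsonlite::write_json(list(metrics = rec$metrics,
                              confusion = as.data.frame(rec$confusion)),
                         file.path(cfg$out_dir, "recovery.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    report$stages$evaluate <- stats::setNames(
      as.list(rec$metrics$sensitivity), paste0("sensitivity_", rec$metrics$class))
  }
  if (!is.null(cfg$prioritize$membership) && !is.null(cfg$prioritize$survival)) {
    membership <- readPathwayMembership(cfg$prioritize$membership)
    survival <- readSurvivalStats(cfg$prioritize$survival)
    candidates <- names(lab)[lab == "THREE_D_EXCLUSIVE"]
    casc <- prioritizeCascade(candidates, membership, survival,
                              topN = cfg$prioritize$top_n,
                              minCount = cfg$prioritize$min_count,
                              hrMin = cfg$prioritize$hr_min,
                              pMax = cfg$prioritize$p_max)
    writeCascadeReport(casc, file.path(cfg$out_dir, "cascade.tsv"),
                       file.path(cfg$out_dir, "cascade.json"))
    report$stages$prioritize <- list(
      n_candidates = length(candidates),
      staged = vapply(casc$stages, `[[`, integer(1), "n_out"),
      final = casc$final)
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(report)
}
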