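#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort configuration,
#' the model registry, the statistics options and the output directory.
#'
#' @param out_dir output directory (created if missing).
#' @param cohort a [cohort_config()].
#' @param models model registry list; default [default_models()].
#' @param control control condition for the post-hoc family.
#' @param pairs optional explicit pair list (see [dunnett_posthoc()]).
#' @param alpha significance level.
#' @param stats_seed seed for the Dunnett Monte-Carlo reference.
#' @param metrics optional restriction of the metric panel.
#' @param write_grids also write every patient-condition volumetric
#'   container (slow, large; default FALSE).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_config(),
                       models = default_models(), control = "AAA",
                       pairs = NULL, alpha = 0.05, stats_seed = 1L,
                       metrics = NULL, write_grids = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!control %in% names(cohort$effects) && is.null(pairs))
    stop(sprintf("control '%s' is not one of the configured conditions",
                 control))
  structure(list(out_dir = out_dir, cohort = cohort, models = models,
                 control = control, pairs = pairs, alpha = alpha,
                 stats_seed = as.integer(stats_seed), metrics = metrics,
                 write_grids = isTRUE(write_grids)),
            class = "run_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[radbioeval] ", fmt), ...))
}

#' Run the full evaluation pipeline
#'
#' simulate -> DVH/metrics -> radiobiology -> compare. Each stage writes a
#' CSV into `out_dir` and is skipped when its output already exists (delete
#' an output to recompute from that stage on). A JSON manifest recording the
#' resolved configuration, all derived seeds and per-output MD5 hashes is
#' written last; on a stage failure the manifest records the failing stage.
#'
#' @param config a [run_config()].
#' @param verbose log per-stage progress.
#' @param stop_after run only up to this stage: `"simulate"` (cohort +
#'   manifest only), `"evaluate"` (metrics + outcomes) or `"compare"`
#'   (everything, the default).
#' @return list with the output paths and the manifest, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE,
                         stop_after = c("compare", "evaluate", "simulate")) {
  stop_after <- match.arg(stop_after)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(metrics = file.path(config$out_dir, "metrics.csv"),
                outcomes = file.path(config$out_dir, "outcomes.csv"),
                comparison = file.path(config$out_dir, "comparison.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  manifest <- list(tool = "radbioeval",
                   version = as.character(utils::packageVersion("radbioeval")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   master_seed = config$cohort$master_seed,
                   stats_seed = config$stats_seed,
                   n_patients = config$cohort$n_patients,
                   prescription_cGy = config$cohort$prescription,
                   n_fractions = config$cohort$n_fractions,
                   conditions = names(config$cohort$effects),
                   control = config$control,
                   alpha = config$alpha,
                   gamma50 = lapply(config$models, function(m) m$gamma50),
                   completed_stages = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  cohort <- NULL
  need_cohort <- function() {
    if (is.null(cohort)) {
      pipeline_log(verbose, "simulate: %d patients x %d conditions (seed %d)",
                   config$cohort$n_patients, length(config$cohort$effects),
                   config$cohort$master_seed)
      cohort <<- generate_cohort(config$cohort)
      utils::write.csv(cohort$manifest,
                       file.path(config$out_dir, "cohort_manifest.csv"),
                       row.names = FALSE)
      if (config$write_grids) {
        gdir <- file.path(config$out_dir, "grids")
        dir.create(gdir, showWarnings = FALSE)
        for (pid in names(cohort$grids))
          for (cond in names(cohort$grids[[pid]]))
            write_volumetric(cohort$grids[[pid]][[cond]],
                             cohort$phantoms[[pid]]$masks,
                             file.path(gdir, sprintf("%s_%s.rbevol", pid, cond)))
      }
    }
    cohort
  }
  want_evaluate <- stop_after %in% c("evaluate", "compare")
  want_compare <- stop_after == "compare"
  result <- try({
    if (stop_after == "simulate") need_cohort()
    if (want_evaluate && !file.exists(paths$metrics)) {
      co <- need_cohort()
      pipeline_log(verbose, "evaluate: plan metrics")
      met <- compute_cohort_metrics(co, metrics = config$metrics)
      utils::write.csv(met, paths$metrics, row.names = FALSE)
      manifest$completed_stages <- c(manifest$completed_stages, "metrics")
    } else if (want_evaluate)
      pipeline_log(verbose, "evaluate: metrics.csv exists, skipping")
    if (want_evaluate && !file.exists(paths$outcomes)) {
      co <- need_cohort()
      pipeline_log(verbose, "evaluate: radiobiological outcomes")
      scheme <- fractionation(config$cohort$prescription,
                              config$cohort$n_fractions)
      dvhs <- compute_cohort_dvhs(co)
      write_outcome_table(evaluate_outcomes(dvhs, config$models, scheme),
                          paths$outcomes)
      manifest$completed_stages <- c(manifest$completed_stages, "outcomes")
    } else if (want_evaluate)
      pipeline_log(verbose, "evaluate: outcomes.csv exists, skipping")
    if (want_compare && !file.exists(paths$comparison)) {
      pipeline_log(verbose, "compare: Friedman + Dunnett")
      met <- utils::read.csv(paths$metrics, stringsAsFactors = FALSE)
      cmp <- compare_cohort(met, pairs = config$pairs,
                            control = config$control, alpha = config$alpha,
                            seed = config$stats_seed)
      write_comparison_table(cmp, paths$comparison)
      manifest$completed_stages <- c(manifest$completed_stages, "comparison")
    } else if (want_compare)
      pipeline_log(verbose, "compare: comparison.csv exists, skipping")
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    manifest$failed <- attr(result, "condition")$message
    write_manifest()
    stop(attr(result, "condition"))
  }
  existing <- unlist(paths[c("metrics", "outcomes", "comparison")])
  manifest$outputs <- as.list(tools::md5sum(existing[file.exists(existing)]))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  pipeline_log(verbose, "done: outputs in %s", config$out_dir)
  invisible(list(paths = paths, manifest = manifest))
}
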