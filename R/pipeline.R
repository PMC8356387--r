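#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation config (data are
#' generated in memory) or a named list of input bundle directories, plus
#' the QC thresholds, analysis parameters, concordance options, output
#' directory and seed.
#'
#' @param simulation A [sim_config()], or `NULL` to read `inputs`.
#' @param inputs Named list of bundle directories
#'   (`whole_cell`, `nucleus`, optionally `graft_nucleus`); ignored when
#'   `simulation` is given.
#' @param include_graft Simulate/process the graft modality?
#' @param reference A [build_reference_profiles()] object or a reference
#'   centroid matrix for annotation; defaults to the simulation's own
#'   profiles when simulating.
#' @param thresholds A [qc_thresholds()].
#' @param params An [analysis_params()].
#' @param fold,alpha,n_list Concordance options.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed propagated (with fixed offsets) to every
#'   stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), inputs = NULL,
                            include_graft = FALSE, reference = NULL,
                            thresholds = qc_thresholds(),
                            params = analysis_params(),
                            fold = 1.5, alpha = 0.05,
                            n_list = c(100L, 200L, 500L, 1000L),
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulation) && is.null(inputs))
    stop("either a simulation config or input directories are required",
         call. = FALSE)
  structure(list(simulation = simulation, inputs = inputs,
                 include_graft = include_graft, reference = reference,
                 thresholds = thresholds, params = params, fold = fold,
                 alpha = alpha, n_list = n_list, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> droplet QC -> clustering/annotation ->
#' concordance (nucleus vs whole cell), and writes per-stage tables, a JSON
#' concordance summary, and a run manifest recording the seed and every
#' threshold applied. Identical config + seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with `qc`, `typing`,
#'   `concordance`, `manifest` (invisibly if `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  captured <- character()
  withCallingHandlers({
    modalities <- c("whole_cell", "nucleus",
                    if (config$include_graft) "graft_nucleus")

    if (!is.null(config$simulation)) {
      sim <- simulate_paired_experiment(config$simulation, seed = config$seed,
                                        include_graft = config$include_graft)
      data <- lapply(modalities, function(m) sim[[m]]$matrix)
      names(data) <- modalities
      truth <- lapply(modalities, function(m) sim[[m]]$truth)
      names(truth) <- modalities
      reference <- config$reference %||% sim$profiles
    } else {
      missing_dirs <- setdiff(modalities, names(config$inputs))
      if (length(missing_dirs))
        stop("[input] no bundle directory for: ",
             paste(missing_dirs, collapse = ", "), call. = FALSE)
      for (m in modalities) {
        if (!dir.exists(config$inputs[[m]]))
          stop("[input] missing input directory: ", config$inputs[[m]],
               call. = FALSE)
      }
      data <- lapply(modalities, function(m)
        read_tenx_bundle(config$inputs[[m]], modality = m))
      names(data) <- modalities
      truth <- NULL
      reference <- config$reference
      if (is.null(reference))
        stop("[input] a reference is required when reading external bundles",
             call. = FALSE)
    }

    qc <- list(); typing <- list()
    for (i in seq_along(modalities)) {
      m <- modalities[i]
      qc[[m]] <- stage(paste0("qc:", m), run_droplet_qc(
        data[[m]], config$thresholds, graft_mode = m == "graft_nucleus",
        seed = config$seed + 10L + i))
      params_m <- config$params
      params_m$seed <- config$seed + 20L + i
      typing[[m]] <- stage(paste0("typing:", m),
                           annotate_dataset(qc[[m]]$matrix, reference,
                                            params_m))
    }

    concordance <- stage("concord", concordance_report(
      qc$nucleus$matrix, qc$whole_cell$matrix,
      typing$nucleus$labels, typing$whole_cell$labels,
      min_cells = config$thresholds$min_cells_per_gene,
      n_list = config$n_list, fold = config$fold, alpha = config$alpha))

    manifest <- list(
      package = "snconcord",
      version = as.character(utils::packageVersion("snconcord")),
      seed = config$seed,
      modalities = modalities,
      simulated = !is.null(config$simulation),
      thresholds = unclass(config$thresholds),
      params = unclass(config$params),
      concord = list(fold = config$fold, alpha = config$alpha,
                     n_list = config$n_list),
      warnings = captured
    )

    result <- structure(list(data = data, truth = truth, qc = qc,
                             typing = typing, concordance = concordance,
                             manifest = manifest),
                        class = "pipeline_result")
    if (!is.null(config$out_dir)) {
      write_pipeline_outputs(result, config$out_dir)
      invisible(result)
    } else result
  }, warning = function(w) {
    captured <<- c(captured, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

# run one stage, prefixing any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) readr::write_tsv(x, file.path(out_dir, name),
                                           progress = FALSE)
  for (m in names(result$qc)) {
    wt(result$qc[[m]]$droplets, sprintf("qc_droplets_%s.tsv", m))
    wt(result$qc[[m]]$tally, sprintf("qc_tally_%s.tsv", m))
    wt(result$typing[[m]]$labels, sprintf("labels_%s.tsv", m))
    wt(result$typing[[m]]$markers, sprintf("markers_%s.tsv", m))
  }
  cr <- result$concordance
  wt(cr$overlap, "concord_overlap.tsv")
  wt(cr$correlations, "concord_correlations.tsv")
  wt(cr$top_overlap, "concord_top_overlap.tsv")
  wt(cr$enrichment$table, "concord_enrichment.tsv")
  wt(cr$enrichment$biotype_proportions, "concord_biotype_proportions.tsv")
  jsonlite::write_json(
    list(overlap = cr$overlap, provenance = cr$provenance,
         n_enriched = cr$enrichment$n_enriched),
    file.path(out_dir, "concordance_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
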