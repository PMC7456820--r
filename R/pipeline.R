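#' Run the full lesion-symptom mapping pipeline
#'
#' Executes the stages in order — collinearity screen, voxel-wise GLM fit,
#' permutation thresholding, importance maps, regional aggregation and
#' clustering — writing every intermediate artifact, a machine-readable
#' manifest (inputs, effective settings, seed, per-file checksums) and a
#' short text report into `output_dir`. A blocking collinearity flag halts
#' the pipeline after the first stage unless `force = TRUE`. Reruns with the
#' same inputs and seed are bit-identical for all text outputs.
#'
#' @param cohort A `lesion_cohort`.
#' @param table A `covariate_table` aligned to the cohort.
#' @param parc A `parcellation` on the same grid (optional; regional stage
#'   is skipped when NULL).
#' @param output_dir Run directory (created if needed).
#' @param spec A `design_spec`.
#' @param n_permutations,alpha Permutation settings (defaults 1000, 0.05).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param convention Importance standardization convention (see
#'   [standardized_betas()]).
#' @param filter_mode,filter_value Regional overlap filter (defaults:
#'   percentile 50).
#' @param linkage Clustering linkage (default "average").
#' @param cor_threshold,vif_threshold Collinearity flags (defaults 0.1, 5).
#' @param force Continue past a blocking collinearity flag (default FALSE).
#' @return Invisibly, a `vlsm_run`: list with each stage's result
#'   (`collinearity`, `fit`, `permutation`, `eloquence`, `importance`,
#'   `regional`, `clustering`), plus `manifest` and `output_dir`. If halted,
#'   `halted = TRUE` and later elements are NULL.
#' @export
run_pipeline <- function(cohort, table, parc = NULL, output_dir,
                         spec = design_spec(),
                         n_permutations = 1000L, alpha = 0.05, seed,
                         convention = "covariate_variance",
                         filter_mode = "percentile", filter_value = 50,
                         linkage = "average",
                         cor_threshold = 0.1, vif_threshold = 5,
                         force = FALSE) {
  if (missing(seed) || is.null(seed)) {
    abort("An explicit integer `seed` is required.")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  settings <- list(
    covariates = spec$covariates,
    include_interactions = spec$include_interactions,
    min_lesion_count = spec$min_lesion_count,
    min_nonlesion_count = spec$min_nonlesion_count,
    intercept = spec$intercept,
    n_permutations = as.integer(n_permutations), alpha = alpha,
    seed = as.integer(seed), convention = convention,
    filter_mode = filter_mode, filter_value = filter_value,
    linkage = linkage, cor_threshold = cor_threshold,
    vif_threshold = vif_threshold, force = force
  )
  stages <- character(0)
  run <- list(output_dir = output_dir, halted = FALSE)

  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # 1. collinearity screen
  run$collinearity <- with_stage("collinearity", {
    rep <- check_collinearity(table, covariates = spec$covariates,
                              cor_threshold = cor_threshold,
                              vif_threshold = vif_threshold)
    write_collinearity_report(rep, file.path(output_dir, "collinearity.json"))
    rep
  })
  stages <- c(stages, "collinearity")
  if (run$collinearity$blocking && !force) {
    run$halted <- TRUE
    finish_run(run, settings, stages, output_dir)
    warn("Blocking collinearity flag raised; pipeline halted (use force = TRUE to continue).")
    return(invisible(structure(run, class = "vlsm_run")))
  }

  # 2. voxel-wise GLM
  run$fit <- with_stage("fit", fit_voxelwise_glm(cohort, table, spec))
  with_stage("fit", {
    tmap0 <- lesion_t_map(run$fit)
    write_statistic_map(ifelse(is.na(tmap0$t), 0, tmap0$t), cohort$grid,
                        file.path(output_dir, "lesion_t.nii.gz"),
                        mask = run$fit$testable)
    jsonlite::write_json(list(
      n = run$fit$n, df_residual = run$fit$df,
      n_testable = length(run$fit$voxels),
      covariate_variances = as.list(run$fit$covariate_variances)
    ), file.path(output_dir, "fit_metadata.json"),
    auto_unbox = TRUE, digits = NA)
  })
  stages <- c(stages, "fit")

  # 3. permutation threshold
  run$permutation <- with_stage("threshold",
    permutation_max_t(cohort, table, spec,
                      n_permutations = n_permutations,
                      alpha = alpha, seed = seed))
  run$eloquence <- apply_threshold(lesion_t_map(run$fit), run$permutation)
  with_stage("threshold", {
    readr::write_csv(tibble(max_t = run$permutation$max_t),
                     file.path(output_dir, "null_max_t.csv"))
    jsonlite::write_json(list(
      threshold = run$permutation$threshold,
      n_permutations = run$permutation$n_permutations,
      alpha = alpha, seed = settings$seed,
      n_surviving = sum(run$eloquence$surviving)
    ), file.path(output_dir, "threshold.json"),
    auto_unbox = TRUE, digits = NA)
  })
  stages <- c(stages, "threshold")

  # 4. importance maps
  if (sum(run$eloquence$surviving) > 0) {
    run$importance <- with_stage("importance", {
      maps <- standardized_betas(run$fit, run$eloquence,
                                 convention = convention)
      write_importance_maps(maps, output_dir)
      maps
    })
    stages <- c(stages, "importance")
  } else {
    warn("Skipping importance and regional stages: no surviving voxels.")
  }

  # 5. regional aggregation + clustering
  if (!is.null(run$importance) && !is.null(parc)) {
    with_stage("regional", {
      tab <- regional_means(run$importance, parc)
      if (nrow(tab)) {
        tab <- overlap_filter(tab, mode = filter_mode, value = filter_value)
      }
      if (nrow(tab)) tab <- dominant_covariate(tab)
      run$regional <- tab
      run$clustering <- if (nrow(tab) >= 2L) {
        cluster_regions(tab, linkage = linkage)
      }
      write_regional_results(tab, run$clustering, output_dir)
    })
    stages <- c(stages, "regional")
  }

  finish_run(run, settings, stages, output_dir)
  run$manifest <- jsonlite::read_json(file.path(output_dir, "manifest.json"))
  invisible(structure(run, class = "vlsm_run"))
}

finish_run <- function(run, settings, stages, output_dir) {
  files <- setdiff(list.files(output_dir, recursive = TRUE),
                   c("manifest.json", "report.txt"))
  checksums <- as.list(tools::md5sum(file.path(output_dir, files)))
  names(checksums) <- files
  jsonlite::write_json(list(
    package = "covima",
    version = as.character(utils::packageVersion("covima")),
    completed_stages = stages,
    halted = run$halted,
    settings = settings,
    files = checksums
  ), file.path(output_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  lines <- c(
    "Lesion-symptom mapping run report",
    paste0("completed stages: ", paste(stages, collapse = ", ")),
    if (run$halted) "HALTED: blocking collinearity flag.",
    if (!is.null(run$collinearity))
      paste0("max VIF: ", signif(max(run$collinearity$vif$vif), 4)),
    if (!is.null(run$fit))
      paste0("testable voxels: ", length(run$fit$voxels),
             " (n = ", run$fit$n, ", df = ", run$fit$df, ")"),
    if (!is.null(run$permutation))
      paste0("max-t threshold (alpha = ", run$permutation$alpha, ", B = ",
             run$permutation$n_permutations, "): ",
             signif(run$permutation$threshold, 6)),
    if (!is.null(run$eloquence) && !is.null(run$eloquence$surviving))
      paste0("surviving voxels: ", sum(run$eloquence$surviving)),
    if (!is.null(run$regional))
      paste0("regions retained after overlap filter: ", nrow(run$regional))
  )
  writeLines(lines, file.path(output_dir, "report.txt"))
  invisible(NULL)
}

#' @export
print.vlsm_run <- function(x, ...) {
  cat("<vlsm_run> in ", x$output_dir, "\n", sep = "")
  rep <- file.path(x$output_dir, "report.txt")
  if (file.exists(rep)) writeLines(paste0("  ", readLines(rep)))
  invisible(x)
}

#' Simulate a cohort and write it to disk in one step
#'
#' Convenience wrapper for the command-line `simulate` subcommand: builds
#' the spec, simulates, writes NIfTI masks + covariate CSV + ground truth.
#'
#' @param spec A `simulation_spec`.
#' @param output_dir Output directory.
#' @return Invisibly, the file-path list from [write_cohort()].
#' @export
simulate_cohort_files <- function(spec, output_dir) {
  sim <- simulate_cohort(spec)
  invisible(write_cohort(sim, output_dir))
}
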