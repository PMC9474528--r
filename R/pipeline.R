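# End-to-end orchestration: simulate -> segment -> extract -> reduce ->
# evaluate -> sham from a single YAML-configurable run definition, with
# recorded seeds and reproducible outputs.

#' Default run configuration
#'
#' All pipeline settings in one list, YAML round-trippable. Defaults
#' reproduce the reference analysis settings: 13/18/9 cohort, 41%
#' background-corrected isocontour, 64-voxel filter, 0.5 g/mL and 25 HU
#' bins, 1.5 mm isotropic CT, Spearman 0.95, one factor per ten training
#' subjects, 5 folds, 100 sham iterations.
#'
#' @param seed master seed.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n1 = 13L, n2 = 18L, ns = 9L),
    simulation = list(effect_scale = 1),
    segmentation = list(fraction = 0.41, min_voxels = 64L,
                        background_inner_mm = 15, background_outer_mm = 22.5),
    radiomics = list(ct_iso_spacing = 1.5, pet_bin_width = 0.5,
                     ct_bin_width = 25),
    dimred = list(spearman_threshold = 0.95, subjects_per_factor = 10L,
                  kmo_min = 0.9),
    evaluation = list(k = 5L),
    sham = list(iterations = 100L),
    modalities = c("PET", "CT")
  ), class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(unclass(run_config()), yaml::read_yaml(path))
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(config) {
  params <- cluster_sim_params(config$simulation$effect_scale %||% 1)
  params$simulate_ct <- "CT" %in% config$modalities
  list(
    params = params,
    radiomics = radiomics_config(
      ct_iso_spacing = config$radiomics$ct_iso_spacing,
      pet_bin_width = config$radiomics$pet_bin_width,
      ct_bin_width = config$radiomics$ct_bin_width),
    dimred = dimred_config(
      spearman_threshold = config$dimred$spearman_threshold,
      subjects_per_factor = config$dimred$subjects_per_factor,
      kmo_min = config$dimred$kmo_min)
  )
}

fold_model_report <- function(models) {
  lapply(seq_along(models), function(f) {
    m <- models[[f]]
    if (is.null(m$dimred) || !inherits(m$dimred, "factor_model"))
      return(list(fold = f))
    dr <- m$dimred
    list(fold = f,
         retained_features = dr$retained_features,
         m = dr$m, kmo = dr$kmo, estimator = dr$estimator,
         factor_labels = dr$factor_labels,
         loadings = apply(dr$loadings, 2, function(col)
           stats::setNames(as.numeric(col), rownames(dr$loadings)),
           simplify = FALSE))
  })
}

#' Run the complete pipeline
#'
#' Simulates the cohort, writes volumes/masks and the cohort table,
#' segments and extracts features, evaluates every model in the menu by
#' stratified cross-validation, runs the sham experiment, and writes
#' `features.csv`, `results.json`, `sham.json`, per-fold model JSONs and a
#' log into `out_dir`. Rerunning with the same config reproduces the same
#' CSV/JSON payload values.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param write_volumes write per-lesion NIfTI pairs and truth masks
#'   (default TRUE; disable for quick smoke runs).
#' @param specs model menu (default [model_menu()]).
#' @param verbose log progress to the console as well as the log file.
#' @return `out_dir`, invisibly; side effect: files on disk.
#' @export
run_all <- function(config = run_config(), out_dir = "petclust_run",
                    write_volumes = TRUE, specs = model_menu(),
                    verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  stage <- "simulate"
  result <- tryCatch({
    logf("seed = %d", config$seed)
    obj <- config_objects(config)
    cohort <- simulate_cohort(config$cohort$n1, config$cohort$n2,
                              config$cohort$ns, obj$params,
                              seed = config$seed)
    logf("simulated %d lesions", length(cohort))
    if (write_volumes) {
      vol_dir <- file.path(out_dir, "volumes")
      dir.create(vol_dir, showWarnings = FALSE)
      meta <- cohort_table(cohort)
      for (i in seq_along(cohort)) {
        write_volume(cohort[[i]]$pet,
                     file.path(vol_dir, paste0(meta$id[i], "_pet.nii.gz")))
        write_mask(cohort[[i]]$truth_mask,
                   file.path(vol_dir, paste0(meta$id[i], "_truth.nii.gz")))
        if (!is.null(cohort[[i]]$ct))
          write_volume(cohort[[i]]$ct,
                       file.path(vol_dir, paste0(meta$id[i], "_ct.nii.gz")))
      }
    }
    write_lesion_table(cohort_table(cohort),
                       file.path(out_dir, "cohort.csv"))
    stage <- "extract"
    features <- extract_cohort(cohort, obj$radiomics,
                               modalities = config$modalities,
                               verbose = verbose)
    write_lesion_table(features, file.path(out_dir, "features.csv"))
    logf("extracted %d lesions x %d columns (%d excluded by size filter)",
         nrow(features), ncol(features), length(attr(features, "excluded")))
    stage <- "evaluate"
    results <- list()
    for (spec in specs) {
      cv <- run_cv(features, spec, obj$dimred, k = config$evaluation$k,
                   seed = derive_seed(config$seed, 50021L),
                   keep_models = TRUE)
      results[[spec$label]] <- list(
        spec = spec$label,
        mean_train = as.list(cv$mean_train),
        mean_test = as.list(cv$mean_test),
        per_fold = cv$per_fold)
      jsonlite::write_json(
        fold_model_report(cv$models),
        file.path(out_dir, paste0("folds_", gsub("\\+", "_", spec$label),
                                  ".json")),
        auto_unbox = TRUE, digits = NA)
      logf("evaluated %s: mean test multiclass AUC %.3f", spec$label,
           cv$mean_test[["multiclass"]])
    }
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    stage <- "sham"
    sham <- sham_experiment(features, specs,
                            iterations = config$sham$iterations,
                            config = obj$dimred, k = config$evaluation$k,
                            seed = derive_seed(config$seed, 90001L))
    jsonlite::write_json(list(mean = as.list(sham$mean),
                              iterations = sham$iterations,
                              per_iteration = sham$per_iteration),
                         file.path(out_dir, "sham.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("sham means: %s",
         paste(sprintf("%s=%.3f", names(sham$mean), sham$mean),
               collapse = " "))
    out_dir
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
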