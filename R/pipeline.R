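# Workflow orchestration: bind the modules into the end-to-end chain
# simulate -> preprocess -> train -> predict -> evaluate, driven by a config
# list (YAML on disk for the command-line wrapper in inst/cli/rildseg).
# Every run writes its resolved configuration next to its outputs.

#' Load a cohort written by [generate_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the NIfTI triplets.
#' @return List with `cases` and `manifest`.
#' @export
load_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cs <- load_case(row$volume_path, row$mask_path, row$labels_path)
    cs$patient <- row$patient_id
    cs$timepoint <- row$timepoint
    cs
  })
  names(cases) <- sprintf("%s_T%d", manifest$patient_id, manifest$timepoint)
  list(cases = cases, manifest = manifest)
}

resolve_config <- function(config) {
  defaults <- list(seed = 1L, target = c(288L, 384L), tau = 0.01,
                   preset = "stage2", base_filters = c(32L, 64L),
                   epochs = 10L, lr = 1e-3, k = 5L, n_patients = 6L,
                   timepoints = 5L, grid_shape = c(48L, 64L, 96L))
  utils::modifyList(defaults, config)
}

write_run_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
}

#' Run one pipeline command
#'
#' Commands: `simulate` (phantom cohort to `out`), `preprocess` (slice plans
#' + class-frequency table), `train` (ensemble on a cohort), `predict`
#' (label maps for a cohort), `evaluate` (global Dice + confusion of
#' predictions vs ground truth), `crossval` (patient-level K-fold run),
#' `compare` (disagreement between two segmentation directories). All
#' randomness is governed by `config$seed`.
#'
#' @param command one of the above.
#' @param config named list; unset fields fall back to package defaults
#'   (resolved config is written next to the outputs).
#' @param out output directory.
#' @return Command-specific result, invisibly where the output is on disk.
#' @export
rild_run <- function(command = c("simulate", "preprocess", "train",
                                 "predict", "evaluate", "crossval",
                                 "compare"),
                     config = list(), out) {
  command <- match.arg(command)
  cfg <- resolve_config(config)
  write_run_config(c(list(command = command), cfg), out)

  if (command == "simulate") {
    spec <- phantom_spec(n_patients = cfg$n_patients,
                         timepoints_per_patient = cfg$timepoints,
                         grid_shape = cfg$grid_shape, seed = cfg$seed)
    return(invisible(generate_cohort(spec, dir = out)))
  }

  cohort <- load_cohort(cfg$cohort)
  if (command == "preprocess") {
    plans <- lapply(cohort$cases, slice_plan, target = cfg$target,
                    tau = cfg$tau)
    freq_all <- class_frequencies(cohort$cases, "all", tau = cfg$tau)
    freq_flt <- class_frequencies(cohort$cases, "filtered", tau = cfg$tau)
    utils::write.csv(cbind(freq_all,
                           fraction_filtered = freq_flt$fraction),
                     file.path(out, "class_frequencies.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(plans, function(p) list(retained = p$retained,
                                     lung_slices = p$lung_slices,
                                     bbox = as.list(p$crop$bbox),
                                     scale = p$crop$scale)),
      file.path(out, "slice_plans.json"), auto_unbox = TRUE)
    return(invisible(list(plans = plans, all = freq_all,
                          filtered = freq_flt)))
  }
  if (command == "train") {
    samples <- unlist(lapply(cohort$cases, function(cs)
      make_samples(cs, slice_plan(cs, target = cfg$target, tau = cfg$tau))),
      recursive = FALSE)
    freqs <- class_frequencies(cohort$cases, "filtered", tau = cfg$tau)
    weights <- weights_from_frequencies(freqs)
    configs <- ensemble_config(cfg$preset, base_filters = cfg$base_filters,
                               seed = cfg$seed)
    nets <- train_ensemble(configs, samples, weights = weights,
                           epochs = cfg$epochs, lr = cfg$lr,
                           seed = cfg$seed)
    saveRDS(nets, file.path(out, "ensemble.rds"))
    return(invisible(nets))
  }
  if (command == "predict") {
    nets <- readRDS(cfg$model)
    for (id in names(cohort$cases)) {
      cs <- cohort$cases[[id]]
      pred <- predict_case(nets, cs, slice_plan(cs, target = cfg$target,
                                                tau = cfg$tau))
      save_labels(pred, cs$volume,
                  file.path(out, paste0(id, "_pred.nii.gz")))
    }
    return(invisible(out))
  }
  if (command == "evaluate") {
    ids <- names(cohort$cases)
    preds <- lapply(ids, function(id) {
      path <- file.path(cfg$predictions, paste0(id, "_pred.nii.gz"))
      if (!file.exists(path)) stop("missing prediction: ", path,
                                   call. = FALSE)
      g <- read_grid_nifti(path)
      label_map(round(g$voxels), g$spacing)
    })
    truths <- lapply(cohort$cases, `[[`, "labels")
    masks <- lapply(cohort$cases, `[[`, "mask")
    M <- confusion_matrix(preds, truths, masks)
    report <- list(dice = as.list(global_dice(preds, truths, masks)),
                   n_scans = length(ids))
    jsonlite::write_json(report, file.path(out, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(M, file.path(out, "confusion_matrix.csv"))
    return(invisible(report))
  }
  if (command == "crossval") {
    configs <- ensemble_config(cfg$preset, base_filters = cfg$base_filters,
                               seed = cfg$seed)
    freqs <- class_frequencies(cohort$cases, "filtered", tau = cfg$tau)
    cv <- crossval_run(cohort$cases, configs, k = cfg$k, seed = cfg$seed,
                       target = cfg$target, tau = cfg$tau,
                       epochs = cfg$epochs, lr = cfg$lr,
                       weights = weights_from_frequencies(freqs))
    utils::write.csv(cv$summary, file.path(out, "crossval_summary.csv"),
                     row.names = FALSE)
    return(invisible(cv))
  }
  # compare: voxel-wise disagreement between two segmentation sets
  other <- load_cohort(cfg$other)
  rows <- lapply(names(cohort$cases), function(id) {
    a <- cohort$cases[[id]]; b <- other$cases[[id]]
    d <- disagreement_map(a$labels, b$labels, a$mask)
    data.frame(case_id = id, fraction = d$fraction)
  })
  res <- do.call(rbind, rows)
  utils::write.csv(res, file.path(out, "disagreement.csv"),
                   row.names = FALSE)
  invisible(res)
}
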