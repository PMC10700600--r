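#' Configuration of an end-to-end pipeline run
#'
#' Bundles every stage's parameters: study-cohort simulation, training-set
#' size, augmentation, architecture and training protocol for the two
#' segmentation tasks (target structure and intracranial compartment). Every
#' random stage derives its own seed deterministically from the global seed,
#' so a rerun with the same configuration reproduces the run.
#'
#' @param seed global integer seed.
#' @param out_dir run directory (default: a fresh temporary directory).
#' @param cohort [cohort_spec()] of the study cohort.
#' @param n_train,n_val numbers of labelled training/validation subjects
#'   simulated for model fitting.
#' @param augment [augment_spec()] for the training slices.
#' @param model [model_config()] shared by both tasks.
#' @param train [train_config()] for the target-structure task.
#' @param icv_train [train_config()] for the ICV task (an easier,
#'   high-contrast task that needs fewer epochs).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, cohort = NULL,
                       n_train = 10L, n_val = 3L, augment = NULL,
                       model = NULL, train = NULL, icv_train = NULL) {
  seed <- as.integer(seed)
  cohort <- cohort %||% cohort_spec(seed = derive_seed(seed, "simulate"))
  cfg <- list(
    seed = seed,
    out_dir = out_dir %||% tempfile("hyposeg_run_"),
    cohort = cohort,
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    augment = augment %||% augment_spec(factor = 2L,
                                        gain_range = c(0.8, 1.2),
                                        offset_range = c(-0.1, 0.1),
                                        gamma_range = c(0.8, 1.25),
                                        seed = derive_seed(seed, "augment")),
    model = model %||% model_config(input_size = cohort$grid_shape[1]),
    train = train %||% train_config(max_epochs = 25L, patience = 10L,
                                    iou_target = 0.95,
                                    seed = derive_seed(seed, "train-target")),
    icv_train = icv_train %||% train_config(max_epochs = 2L, patience = 2L,
                                            seed = derive_seed(seed, "train-icv"))
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  bad <- character()
  if (!inherits(cfg$cohort, "cohort_spec")) bad <- c(bad, "cohort")
  if (!inherits(cfg$augment, "augment_spec")) bad <- c(bad, "augment")
  if (!inherits(cfg$model, "model_config")) bad <- c(bad, "model")
  if (!inherits(cfg$train, "train_config")) bad <- c(bad, "train")
  if (!inherits(cfg$icv_train, "train_config")) bad <- c(bad, "icv_train")
  if (cfg$n_train < 2L) bad <- c(bad, "n_train")
  if (cfg$n_val < 1L) bad <- c(bad, "n_val")
  if (inherits(cfg$cohort, "cohort_spec") && inherits(cfg$model, "model_config")) {
    gs <- cfg$cohort$grid_shape
    if (gs[1] != gs[2] || gs[1] != cfg$model$input_size)
      bad <- c(bad, "model.input_size (must equal the square in-plane grid)")
  }
  if (length(bad) > 0)
    stop_param("invalid run configuration, offending fields: %s",
               paste(bad, collapse = ", "))
  invisible(cfg)
}

read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  build <- function(f, x) if (is.null(x)) NULL else do.call(f, x)
  run_config(seed = raw$seed %||% 1L, out_dir = raw$out_dir,
             cohort = build(cohort_spec, raw$cohort),
             n_train = raw$n_train %||% 12L, n_val = raw$n_val %||% 4L,
             augment = build(augment_spec, raw$augment),
             model = build(model_config, raw$model),
             train = build(train_config, raw$train),
             icv_train = build(train_config, raw$icv_train))
}

dep_error <- function(what, path) {
  stop_param("missing upstream artifact: %s (expected at '%s'); run the earlier stages first",
             what, path)
}

#' Pipeline stage: simulate the cohorts
#'
#' Generates the labelled training/validation cohorts and the study cohort
#' and writes them (NIfTI + manifests) under the run directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, the run directory.
#' @rdname stages
#' @export
stage_simulate <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- config$cohort
  mk_train_spec <- function(n, label) {
    s <- co
    s$n_control <- max(1L, ceiling(n / 2)); s$n_case <- n - s$n_control + 0L
    if (s$n_case < 1L) { s$n_case <- 1L }
    s$seed <- derive_seed(config$seed, label)
    s
  }
  tr <- generate_cohort(mk_train_spec(config$n_train, "simulate-train"))
  va <- generate_cohort(mk_train_spec(config$n_val, "simulate-val"))
  st <- generate_cohort(co)
  write_cohort(tr, file.path(config$out_dir, "train"))
  write_cohort(va, file.path(config$out_dir, "val"))
  write_cohort(st, file.path(config$out_dir, "study"))
  invisible(config$out_dir)
}

#' Pipeline stage: train the two segmenters
#'
#' Builds and trains the target-structure and ICV segmenters on the simulated
#' training cohort (with contrast augmentation), storing checkpoints, JSON
#' sidecars and training-curve CSVs under `models/`.
#'
#' @rdname stages
#' @export
stage_train <- function(config) {
  dtr <- file.path(config$out_dir, "train")
  dva <- file.path(config$out_dir, "val")
  if (!dir.exists(dtr) || !dir.exists(dva)) dep_error("training cohort", dtr)
  tr <- read_cohort(dtr); va <- read_cohort(dva)
  mdir <- file.path(config$out_dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  # target task: train on the slice block containing the structure (+/- 2
  # slices), the desk-scale analogue of the pre-selected coronal block
  zr <- range(unlist(lapply(tr, function(v) which(apply(v$target_mask, 3, sum) > 0))))
  nz <- dim(tr[[1]]$intensity)[3]
  block <- max(1L, zr[1] - 2L):min(nz, zr[2] + 2L)
  for (task in c("target", "icv")) {
    tcfg <- if (task == "target") config$train else config$icv_train
    rng <- if (task == "target") block else NULL
    slices <- as_slice_set(tr, task, slice_range = rng)
    # contrast augmentation matters for the low-contrast target task; the
    # high-contrast ICV task converges without it
    if (task == "target") slices <- build_augmented_set(slices, config$augment)
    vslices <- as_slice_set(va, task, slice_range = rng)
    model <- build_model(config$model,
                         seed = derive_seed(config$seed, paste0("init-", task)))
    model <- train_unet(model, slices, vslices, tcfg)
    saveRDS(model, file.path(mdir, paste0(task, ".rds")))
    jsonlite::write_json(
      list(task = task, model_config = unclass(config$model),
           train_config = unclass(tcfg), best_epoch = model$best_epoch,
           n_params = n_params(model)),
      file.path(mdir, paste0(task, "_config.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(model$history, file.path(mdir, paste0(task, "_history.csv")),
              row.names = FALSE)
  }
  invisible(config$out_dir)
}

#' Pipeline stage: segment the study cohort
#'
#' Applies both trained segmenters slice-wise to every study volume, writing
#' predicted masks and a prediction log (timing, empty-prediction flags).
#'
#' @rdname stages
#' @export
stage_predict <- function(config) {
  mdir <- file.path(config$out_dir, "models")
  if (!file.exists(file.path(mdir, "target.rds")))
    dep_error("trained models", mdir)
  sdir <- file.path(config$out_dir, "study")
  if (!dir.exists(sdir)) dep_error("study cohort", sdir)
  study <- read_cohort(sdir)
  models <- list(target = readRDS(file.path(mdir, "target.rds")),
                 icv = readRDS(file.path(mdir, "icv.rds")))
  pdir <- file.path(config$out_dir, "predictions")
  dir.create(pdir, showWarnings = FALSE)
  rows <- list()
  for (v in study) {
    row <- list(subject_id = v$subject_id, group = v$group)
    for (task in c("target", "icv")) {
      pr <- predict_volume(models[[task]], v, batch_size = 32L)
      msk <- pr$mask
      RNifti::pixdim(msk) <- v$voxel_size
      RNifti::writeNifti(msk, file.path(pdir, paste0(v$subject_id, "_",
                                                     task, "-pred.nii.gz")),
                         datatype = "uint8")
      row[[paste0(task, "_ms_per_image")]] <- pr$ms_per_image
      row[[paste0(task, "_empty")]] <- pr$empty
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), file.path(pdir, "predictions.csv"),
            row.names = FALSE)
  invisible(config$out_dir)
}

read_predictions <- function(config, task) {
  pdir <- file.path(config$out_dir, "predictions")
  if (!file.exists(file.path(pdir, "predictions.csv")))
    dep_error("predicted masks", pdir)
  study <- read_cohort(file.path(config$out_dir, "study"))
  lapply(study, function(v) {
    p <- file.path(pdir, paste0(v$subject_id, "_", task, "-pred.nii.gz"))
    m <- as.array(RNifti::readNifti(p))
    attributes(m) <- list(dim = dim(m))
    list(volume = v, mask = m > 0)
  })
}

#' Pipeline stage: evaluate segmentations against ground truth
#'
#' Per-subject overlap metrics (IoU, precision, recall, Dice) and HD95 for
#' the target task, computed per volume and written to `metrics.csv`.
#'
#' @rdname stages
#' @export
stage_evaluate <- function(config) {
  preds <- read_predictions(config, "target")
  log <- read.csv(file.path(config$out_dir, "predictions", "predictions.csv"))
  rows <- lapply(preds, function(pv) {
    v <- pv$volume
    cm <- confusion(pv$mask + 0L, v$target_mask + 0L)
    om <- overlap_metrics(cm)
    data.frame(subject_id = v$subject_id, group = v$group,
               iou = om$iou, precision = om$precision, recall = om$recall,
               dice = om$dice,
               hd95_mm = as.numeric(hd95(pv$mask, v$target_mask,
                                         v$voxel_size)),
               prediction_time_ms =
                 log$target_ms_per_image[log$subject_id == v$subject_id][1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  invisible(config$out_dir)
}

#' Pipeline stage: volume quantification and QC
#'
#' Computes target and ICV volumes from the predicted masks, applies the IQR
#' rejection cascade per group, and writes `cohort_results.csv` plus a QC
#' summary JSON (frozen fences, acceptance rates).
#'
#' @rdname stages
#' @export
stage_quantify <- function(config) {
  tpred <- read_predictions(config, "target")
  pdir <- file.path(config$out_dir, "predictions")
  ipaths <- file.path(pdir, paste0(vapply(tpred, function(p) p$volume$subject_id,
                                          character(1)), "_icv-pred.nii.gz"))
  if (!all(file.exists(ipaths)))
    dep_error("ICV masks", pdir)
  rows <- lapply(seq_along(tpred), function(i) {
    v <- tpred[[i]]$volume
    im <- as.array(RNifti::readNifti(ipaths[i]))
    data.frame(subject_id = v$subject_id, group = v$group,
               v_target = as.numeric(mask_volume(tpred[[i]]$mask + 0L,
                                                 v$voxel_size)),
               v_icv = as.numeric(mask_volume((im > 0) + 0L, v$voxel_size)),
               true_target = v$true_target_volume,
               true_icv = v$true_icv_volume,
               stringsAsFactors = FALSE)
  })
  rec <- qc_cohort(do.call(rbind, rows))
  out <- rec
  names(out)[names(out) == "v_target"] <- "v_target_mm3"
  names(out)[names(out) == "v_icv"] <- "v_icv_mm3"
  names(out)[names(out) == "v_norm"] <- "v_norm_mm3"
  write.csv(out, file.path(config$out_dir, "cohort_results.csv"),
            row.names = FALSE)
  s <- qc_summary(rec)
  f <- attr(rec, "fences")
  jsonlite::write_json(
    list(acceptance_rate = s$acceptance_rate,
         rejection_rate = s$rejection_rate,
         acceptance_by_group = as.list(s$acceptance_by_group),
         n = s$n, n_rejected = s$n_rejected,
         reasons = as.list(s$reasons),
         reference_mean_control_icv_mm3 = f$reference$mean_control_icv,
         fences = lapply(f$groups, function(g) lapply(g, unclass))),
    file.path(config$out_dir, "qc_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Pipeline stage: group statistics
#'
#' Group summaries of accepted normalized volumes, the unpaired group
#' comparison, percent differences (predicted and ground truth), the
#' normality-gated paired agreement test and the Bland--Altman analysis of
#' predicted vs true target volumes. Written to `stats.json`.
#'
#' @rdname stages
#' @export
stage_stats <- function(config) {
  cpath <- file.path(config$out_dir, "cohort_results.csv")
  if (!file.exists(cpath)) dep_error("cohort results", cpath)
  rec <- read.csv(cpath, stringsAsFactors = FALSE)
  acc <- rec[rec$qc_status == "accepted", ]
  rec$v_norm <- rec$v_norm_mm3
  gs <- group_summary(rec, value = "v_norm")
  ctrl <- acc$v_norm_mm3[acc$group == "control"]
  case <- acc$v_norm_mm3[acc$group == "case"]
  gt <- unpaired_test(ctrl, case)
  pd <- percent_difference(mean(ctrl), mean(case))
  pd_true <- percent_difference(mean(acc$true_target[acc$group == "control"]),
                                mean(acc$true_target[acc$group == "case"]))
  agree <- gated_paired_test(acc$v_target_mm3, acc$true_target)
  ba <- bland_altman(acc$v_target_mm3, acc$true_target)
  res <- list(
    group_summary = gs,
    group_test = unclass(gt),
    percent_difference = pd,
    percent_difference_true = pd_true,
    agreement_test = unclass(agree),
    bland_altman = list(n = ba$n, mean_difference = ba$mean_difference,
                        loa = as.list(ba$loa), ci_mean = ba$ci_mean,
                        ci_loa_lower = ba$ci_loa_lower,
                        ci_loa_upper = ba$ci_loa_upper))
  jsonlite::write_json(res, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(config$out_dir)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

write_provenance <- function(config) {
  cfg_json <- jsonlite::toJSON(strip_class(config),
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("hyposeg")),
         r_version = R.version.string,
         global_seed = config$seed,
         stage_seeds = list(
           simulate = derive_seed(config$seed, "simulate"),
           simulate_train = derive_seed(config$seed, "simulate-train"),
           simulate_val = derive_seed(config$seed, "simulate-val"),
           augment = config$augment$seed,
           train_target = config$train$seed,
           train_icv = config$icv_train$seed),
         config_md5 = hash,
         config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE)),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate, train, predict, evaluate, quantify and stats stages in
#' order under one run directory, writing a provenance file (config hash,
#' seeds, versions) first. Rerunning with the same configuration reproduces
#' all outputs.
#'
#' @param config a [run_config()].
#' @return Object of class `hyposeg_run` with the run directory and the main
#'   results loaded.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_provenance(config)
  stage_simulate(config)
  stage_train(config)
  stage_predict(config)
  stage_evaluate(config)
  stage_quantify(config)
  stage_stats(config)
  collect_run(config)
}

collect_run <- function(config) {
  dirp <- config$out_dir
  res <- list(
    dir = dirp,
    config = config,
    metrics = read.csv(file.path(dirp, "metrics.csv"), stringsAsFactors = FALSE),
    cohort = read.csv(file.path(dirp, "cohort_results.csv"),
                      stringsAsFactors = FALSE),
    qc = jsonlite::fromJSON(file.path(dirp, "qc_summary.json")),
    stats = jsonlite::fromJSON(file.path(dirp, "stats.json")))
  class(res) <- "hyposeg_run"
  res
}

#' @export
print.hyposeg_run <- function(x, ...) {
  cat("<hyposeg_run>", x$dir, "\n")
  cat(sprintf("  study subjects: %d (accepted %.1f%%)\n", nrow(x$cohort),
              100 * x$qc$acceptance_rate))
  cat(sprintf("  mean Dice (target task): %.3f   mean HD95: %.2f mm\n",
              mean(x$metrics$dice, na.rm = TRUE),
              mean(x$metrics$hd95_mm, na.rm = TRUE)))
  cat(sprintf("  normalized volume reduction (case vs control): %.1f%% (p = %.3g)\n",
              x$stats$percent_difference$percent, x$stats$group_test$p_value))
  invisible(x)
}
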