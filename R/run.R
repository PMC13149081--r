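# End-to-end experiment driver: simulate -> split -> train (both tasks) ->
# two-stage inference on the holdout -> evaluation report. All randomness
# flows from the single run seed through named sub-seeds recorded in the
# run log.

#' Declarative run configuration
#'
#' Nested sections mirroring the module configs. The bundled smoke defaults
#' (8 patients, base width 8, few epochs) complete end-to-end on one CPU in
#' minutes; full-scale values reproduce the published protocol sizes.
#'
#' @param phantom A [phantom_config()].
#' @param network A [network_config()] (input channels must match the
#'   phantom offset grid).
#' @param train A [train_config()].
#' @param patch_size,patch_stride Genotype patch geometry.
#' @param holdout_frac,k_folds Split plan parameters.
#' @param stats_B Bootstrap replicates for the evaluation report.
#' @param seed Run seed; sub-seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(n_patients = 8L,
                                                image_size = 48L,
                                                tumor_radius = c(9, 14),
                                                tumor_apt = 0.12,
                                                apt_effect = 0.05,
                                                noise_sigma = 0.01),
                       network = network_config(base_width = 8L),
                       train = train_config(lr = 0.05, max_epochs = 12L,
                                            patience = 11L, batch_size = 64L,
                                            warmup_epochs = 3L,
                                            seg_class_weights = c(1, 2),
                                            clip_norm = 1, augment = FALSE),
                       patch_size = 48L, patch_stride = 12L,
                       holdout_frac = 0.15, k_folds = 5L, stats_B = 500L,
                       seed = 42L) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(network, "network_config"),
            inherits(train, "train_config"))
  if (network$in_channels != length(phantom$offsets)) {
    stop("network input channels must equal the phantom offset count",
         call. = FALSE)
  }
  structure(list(phantom = phantom, network = network, train = train,
                 patch_size = as.integer(patch_size),
                 patch_stride = as.integer(patch_stride),
                 holdout_frac = holdout_frac, k_folds = as.integer(k_folds),
                 stats_B = as.integer(stats_B), seed = as.integer(seed)),
            class = "run_config")
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, tag) {
  (as.integer(seed) * 7919L + sum(utf8ToInt(tag))) %% 2000000000L
}

#' Run a full experiment
#'
#' Executes simulate -> split -> train (segmentation and genotype) ->
#' two-stage inference on the holdout patients -> evaluation, writing every
#' artifact (config echo, split plan, training histories, checkpoints,
#' per-patient predictions, evaluation report) under `out_dir`. Rerunning
#' with the same config reproduces the report.
#'
#' @param config A [run_config()].
#' @param out_dir Artifact directory (created).
#' @param k_folds_small Reduce fold count automatically when the cohort is
#'   too small for 5 folds (smoke runs); set FALSE to error instead.
#' @return List: records, plan, seg_fit, geno_fit, predictions (data.frame),
#'   evaluation. Invisibly also written to `out_dir`.
#' @export
run_experiment <- function(config, out_dir, k_folds_small = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logline("stage %s: ERROR %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logline("stage %s: done", name)
    res
  }
  ph <- config$phantom
  ph$seed <- derive_seed(config$seed, "simulate")
  records <- stage("simulate", generate_phantom(ph))
  labels <- vapply(records, function(r) r$genotype, 0L)
  k <- config$k_folds
  if (k_folds_small) {
    max_k <- max(1L, min(table(labels)) - 1L)
    k <- min(k, max_k, length(records) - 2L)
    k <- max(k, 2L)
  }
  plan <- stage("split", make_splits(labels,
                                     vapply(records, function(r) r$patient_id, ""),
                                     holdout_frac = config$holdout_frac,
                                     k = k,
                                     seed = derive_seed(config$seed, "split")))
  records <- apply_splits(records, plan)
  utils::write.csv(plan, file.path(out_dir, "split_plan.csv"),
                   row.names = FALSE)
  tc <- config$train
  tc$seed <- derive_seed(config$seed, "train-seg")
  seg_fit <- stage("train-seg", {
    net <- build_network(config$network,
                         seed = derive_seed(config$seed, "init-seg"))
    cest_train(net, records, "segmentation", tc, val_fold = 1L)
  })
  tc$seed <- derive_seed(config$seed, "train-geno")
  geno_fit <- stage("train-geno", {
    net <- build_network(config$network,
                         seed = derive_seed(config$seed, "init-geno"))
    cest_train(net, records, "genotype", tc, val_fold = 1L,
               patch_size = config$patch_size,
               patch_stride = config$patch_stride)
  })
  saveRDS(seg_fit, file.path(out_dir, "seg_model.rds"))
  saveRDS(geno_fit, file.path(out_dir, "geno_model.rds"))
  jsonlite::write_json(seg_fit$history,
                       file.path(out_dir, "history_seg.json"))
  jsonlite::write_json(geno_fit$history,
                       file.path(out_dir, "history_geno.json"))
  holdout <- records[vapply(records, function(r)
    identical(r$split, "holdout"), TRUE)]
  preds <- stage("infer", run_pipeline(holdout, seg_fit, geno_fit,
                                       config$patch_size,
                                       config$patch_stride))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  ev <- stage("evaluate", evaluate_cohort(preds, B = config$stats_B,
                                          seed = derive_seed(config$seed,
                                                             "bootstrap")))
  report <- c(list(n_holdout = length(holdout)),
              ev[!vapply(ev, is.null, TRUE)])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(records = records, plan = plan, seg_fit = seg_fit,
                 geno_fit = geno_fit, predictions = preds, evaluation = ev))
}
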