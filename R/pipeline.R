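#' Read a pipeline run configuration from YAML
#'
#' The file mirrors the module configurations under `phantom:`, `model:`,
#' `train:` and `evaluate:` sections, plus a top-level `seed` that fans out
#' deterministically to phantom generation, cohort splitting, weight
#' initialization and shuffling. Missing sections fall back to package
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_kbp("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Build a run configuration from a plain list
#'
#' Fills unspecified sections with package defaults; see [read_run_config()]
#' for the YAML equivalent.
#'
#' @param cfg Named list with any of `seed`, `n_plans`, `out_size`,
#'   `fractions` and the `phantom`, `model`, `train`, `evaluate` sections.
#' @return A `run_config` list.
#' @export
as_run_config <- function(cfg = list()) {
  ph <- cfg$phantom %||% list()
  tr <- cfg$train %||% list()
  # default patience cannot exceed a configured shorter run
  if (is.null(tr$patience) && !is.null(tr$epochs) && tr$epochs < 30)
    tr$patience <- tr$epochs
  md <- cfg$model %||% list()
  ev <- cfg$evaluate %||% list()
  structure(list(
    seed = as.integer(cfg$seed %||% 1L),
    n_plans = as.integer(cfg$n_plans %||% 10L),
    out_size = as.integer(cfg$out_size %||% (ph$grid_size %||% 64L)),
    phantom = do.call(phantom_config, ph),
    model = do.call(model_config, md),
    train = do.call(train_control, tr),
    fractions = as.numeric(cfg$fractions %||% c(0.64, 0.16, 0.20)),
    reference_dose = ev$reference_dose,
    dvh_bin_width = as.numeric(ev$dvh_bin_width %||% 0.5)
  ), class = "run_config")
}

#' Run the dose-prediction pipeline
#'
#' Executes the requested stages in dependency order inside a run directory:
#' `generate` writes synthetic plans (NIfTI volumes plus JSON manifests);
#' `preprocess` records the train/validation/test split; `train` fits the
#' network and stores the weights, learning-curve CSV and loss plot;
#' `predict` writes a predicted dose volume for every test plan; `evaluate`
#' writes the cohort metrics CSV and DVH CSV. Each invocation appends a
#' manifest entry (config, seed, stages, package version) so runs can be
#' reproduced exactly. A stage whose upstream outputs are missing fails with
#' a dependency error naming the absent artifact.
#'
#' @param config A `run_config` from [read_run_config()]/[as_run_config()],
#'   or a plain list coercible to one.
#' @param stages Subset of `c("generate", "preprocess", "train", "predict",
#'   "evaluate")`.
#' @param out_dir Run directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = as_run_config(),
                         stages = c("generate", "preprocess", "train",
                                    "predict", "evaluate"),
                         out_dir) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  all_stages <- c("generate", "preprocess", "train", "predict", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop_kbp("no stages requested")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  plans_dir <- file.path(out_dir, "plans")
  pred_dir <- file.path(out_dir, "predicted")
  split_path <- file.path(out_dir, "split.json")
  model_path <- file.path(out_dir, "model.rds")
  need <- function(path, producer) {
    if (!file.exists(path))
      stop_kbp("missing upstream artifact ", path,
               ": run the '", producer, "' stage first")
  }
  plan_ids <- function() {
    ids <- sort(list.dirs(plans_dir, recursive = FALSE, full.names = FALSE))
    if (length(ids) == 0)
      stop_kbp("missing upstream artifact ", plans_dir,
               ": run the 'generate' stage first")
    ids
  }
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  }

  for (stage in stages) {
    if (stage == "generate") {
      cohort <- generate_cohort(config$phantom, config$n_plans,
                                seed = derive_seed(config$seed, 1))
      for (i in seq_along(cohort)) {
        write_plan(cohort[[i]],
                   file.path(plans_dir, sprintf("plan_%03d", i)))
      }
      log_line(stage, paste("wrote", length(cohort), "plans"))
    } else if (stage == "preprocess") {
      ids <- plan_ids()
      split <- split_cohort(ids, config$fractions,
                            seed = derive_seed(config$seed, 2))
      jsonlite::write_json(unclass(split), split_path, auto_unbox = FALSE)
      log_line(stage, sprintf("split %d plans into %d/%d/%d", length(ids),
                              length(split$train_ids), length(split$val_ids),
                              length(split$test_ids)))
    } else if (stage == "train") {
      need(split_path, "preprocess")
      split <- jsonlite::read_json(split_path, simplifyVector = TRUE)
      load_pairs <- function(ids) lapply(ids, function(id) {
        prepare_pair(read_plan(file.path(plans_dir, id)),
                     config$out_size)[c("x", "y")]
      })
      ctl <- config$train
      ctl$seed <- derive_seed(config$seed, 3)
      net <- if (config$model$use_attention)
               build_attention_unet(config$model,
                                    seed = derive_seed(config$seed, 4))
             else build_baseline_unet(config$model,
                                      seed = derive_seed(config$seed, 4))
      net <- train_network(net, load_pairs(split$train_ids),
                           if (length(split$val_ids)) load_pairs(split$val_ids),
                           ctl)
      saveRDS(net, model_path)
      utils::write.csv(net$curve, file.path(out_dir, "learning_curve.csv"),
                       row.names = FALSE)
      grDevices::pdf(file.path(out_dir, "learning_curve.pdf"))
      plot(net)
      grDevices::dev.off()
      log_line(stage, sprintf("trained %d epochs (final train loss %.5f)",
                              net$epochs_run,
                              utils::tail(net$curve$train_loss, 1)))
    } else if (stage == "predict") {
      need(model_path, "train")
      need(split_path, "preprocess")
      net <- readRDS(model_path)
      split <- jsonlite::read_json(split_path, simplifyVector = TRUE)
      dir.create(pred_dir, showWarnings = FALSE)
      for (id in split$test_ids) {
        s <- read_plan(file.path(plans_dir, id))
        pred <- predict(net, s, prescription = s$prescription,
                        out_size = config$out_size)
        write_volume(pred, attr(s, "spacing") %||% c(3.5, 3.5, 2),
                     file.path(pred_dir, paste0(id, ".nii.gz")))
      }
      log_line(stage, paste("predicted", length(split$test_ids), "test plans"))
    } else if (stage == "evaluate") {
      need(split_path, "preprocess")
      if (!dir.exists(pred_dir))
        stop_kbp("missing upstream artifact ", pred_dir,
                 ": run the 'predict' stage first")
      split <- jsonlite::read_json(split_path, simplifyVector = TRUE)
      preds <- list(); truths <- list()
      for (id in split$test_ids) {
        p <- file.path(pred_dir, paste0(id, ".nii.gz"))
        need(p, "predict")
        pv <- read_volume(p); attr(pv, "spacing") <- NULL
        preds[[id]] <- pv
        truths[[id]] <- crop_plan(read_plan(file.path(plans_dir, id)),
                                  config$out_size)
      }
      report <- evaluate_cohort(preds, truths,
                                reference_dose = config$reference_dose)
      write_metrics_csv(report, file.path(out_dir, "metrics.csv"))
      first <- truths[[1]]
      dvhs <- list()
      for (nm in intersect(CANONICAL_STRUCTURES, names(first$masks))) {
        if (sum(first$masks[[nm]]) > 0)
          dvhs[[nm]] <- dvh(preds[[1]], first$masks[[nm]],
                            config$dvh_bin_width)
      }
      write_dvh_csv(dvhs, file.path(out_dir, "dvh.csv"))
      log_line(stage, sprintf("evaluated %d plans, %d summary rows",
                              length(preds), nrow(report$summary)))
    }
  }

  manifest <- list(seed = config$seed, stages = stages,
                   n_plans = config$n_plans, out_size = config$out_size,
                   package_version = as.character(utils::packageVersion("kbpdose")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
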