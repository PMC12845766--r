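#' Assemble an end-to-end run configuration
#'
#' Bundles data location (or synthetic-data settings), patch-extraction
#' parameters, network spec and training configuration. All nested
#' configurations are validated up front; the resolved configuration is
#' echoed to the output directory as `config.yaml` when the pipeline runs.
#'
#' @param out_dir Output directory for all artifacts.
#' @param data_dir Optional directory in the `<id>/images/`, `<id>/masks/`
#'   layout; when `NULL`, synthetic data are generated.
#' @param synth List of arguments for the synthetic generator:
#'   `n_images`, `fg_fraction`, `seed`, optionally `size_jitter`.
#' @param ada An [ada_params()].
#' @param spec A [maunet_spec()] or the string `"default"`.
#' @param train A [train_config()].
#' @param split_ratios Train/validation/test proportions.
#' @param split_seed Seed for the image-level split.
#' @param stages Character subset of
#'   `c("synth", "prepare", "train", "eval")`; earlier stages are loaded
#'   from persisted artifacts in `out_dir` when skipped.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, data_dir = NULL,
                       synth = list(n_images = 32L, fg_fraction = 0.05,
                                    seed = 42L),
                       ada = ada_params(), spec = "default",
                       train = train_config(),
                       split_ratios = c(0.8, 0.1, 0.1), split_seed = 42L,
                       stages = c("synth", "prepare", "train", "eval")) {
  if (identical(spec, "default")) spec <- maunet_spec()
  validate_spec(spec)
  stopifnot(inherits(ada, "ada_params"), inherits(train, "train_config"))
  bad <- setdiff(stages, c("synth", "prepare", "train", "eval"))
  if (length(bad)) stop_input("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, data_dir = data_dir, synth = synth,
                 ada = ada, spec = spec, train = train,
                 split_ratios = split_ratios,
                 split_seed = as.integer(split_seed), stages = stages),
            class = "run_config")
}

echo_config <- function(config, path) {
  dump <- list(out_dir = config$out_dir, data_dir = config$data_dir,
               synth = config$synth, ada = unclass(config$ada),
               spec = unclass(config$spec), train = unclass(config$train),
               split_ratios = config$split_ratios,
               split_seed = config$split_seed, stages = config$stages)
  yaml::write_yaml(dump, path)
}

#' Run the full segmentation pipeline
#'
#' Orchestrates (synthesize or load images) -> image-level split -> patch
#' extraction with balance filtering and augmentation -> training ->
#' patch-level evaluation on the test subset. Every stage persists its
#' artifacts under `config$out_dir` (patch PNG ensembles and
#' `balance_report.csv`; `history.csv` and `best_weights.rds`;
#' `report.json` and `report.csv`), and a stage omitted from
#' `config$stages` is resumed from those artifacts.
#'
#' @param config A [run_config()].
#' @param verbose Print stage and epoch progress.
#' @return Object of class `maunet_run`: list with `report`
#'   (`metrics_report` on test patches), `fit` (the fitted `maunet`, when
#'   trained in this call), `patches` summary counts, and `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo_config(config, file.path(out, "config.yaml"))
  say <- function(...) if (verbose) message(...)

  patch_dirs <- file.path(out, "patches", c("train", "validation", "test"))
  names(patch_dirs) <- c("train", "validation", "test")
  if ("prepare" %in% config$stages) {
    if (!is.null(config$data_dir)) {
      say("loading dataset from ", config$data_dir)
      records <- load_dataset(config$data_dir)
    } else if ("synth" %in% config$stages) {
      say("generating ", config$synth$n_images, " synthetic images")
      cfg <- synth_config(seed = config$synth$seed %||% 42L,
                          target_fg_fraction = config$synth$fg_fraction)
      records <- generate_dataset(
        config$synth$n_images,
        size_jitter = config$synth$size_jitter %||% c(192L, 320L),
        cfg_template = cfg)
      write_dsb_dataset(records, file.path(out, "data"))
    } else {
      say("loading dataset from ", file.path(out, "data"))
      records <- load_dataset(file.path(out, "data"))
    }
    split <- split_dataset(records, config$split_ratios, config$split_seed)
    say("split: ", length(split$train), "/", length(split$validation), "/",
        length(split$test))
    pd <- prepare_patch_dataset(split, config$ada)
    for (ss in names(patch_dirs)) save_patches(pd[[ss]], patch_dirs[[ss]])
    utils::write.csv(pd$report, file.path(out, "balance_report.csv"),
                     row.names = FALSE)
    patches <- pd[c("train", "validation", "test")]
  } else {
    say("resuming patches from ", file.path(out, "patches"))
    patches <- lapply(patch_dirs, load_patches)
  }
  say("patches: ", length(patches$train), " train / ",
      length(patches$validation), " validation / ", length(patches$test),
      " test")

  fit <- NULL
  if ("train" %in% config$stages) {
    fit <- maunet(patches$train, patches$validation, spec = config$spec,
                  config = config$train, checkpoint_dir = out,
                  verbose = verbose)
    utils::write.csv(fit$history, file.path(out, "history.csv"),
                     row.names = FALSE)
  }

  report <- NULL
  if ("eval" %in% config$stages) {
    net <- if (!is.null(fit)) fit$network else {
      wpath <- file.path(out, "best_weights.rds")
      if (!file.exists(wpath))
        stop_input("no trained weights at ", wpath, "; run the train stage")
      n <- build_network(config$spec, seed = config$train$seed)
      n$params <- readRDS(wpath)
      n
    }
    report <- evaluate_network(net, patches$test,
                               batch_size = config$train$batch_size)
    df <- as.data.frame(report)
    utils::write.csv(df, file.path(out, "report.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(df), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    say(sprintf("test: MeanIoU %.4f F1 %.4f", report$mean_iou, report$f1))
  }

  structure(list(report = report, fit = fit,
                 patches = vapply(patches, length, integer(1)),
                 out_dir = out),
            class = "maunet_run")
}

#' @export
print.maunet_run <- function(x, ...) {
  cat("<maunet_run: ", paste(sprintf("%s=%d", names(x$patches), x$patches),
                             collapse = ", "), ">\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
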