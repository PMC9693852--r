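#' End-to-end run configuration
#'
#' @param edf_path input EDF file.
#' @param labels_path stage labels CSV (`epoch_index`, `stage_string`).
#' @param out_dir output directory (created if missing).
#' @param channel EDF channel to read (default first).
#' @param tf_method "cwt" or "fsst".
#' @param variant "cnn_rnn" or "cnn".
#' @param mode "holdout" (90/10 split) or "cv" (k-fold).
#' @param split a [split_spec()].
#' @param train_cfg a [train_config()].
#' @param cv a [cv_spec()] (used when `mode = "cv"`).
#' @param seed master seed; overrides the component seeds.
#' @return object of class `run_config`.
#' @export
run_config <- function(edf_path, labels_path, out_dir,
                       channel = NULL,
                       tf_method = c("cwt", "fsst"),
                       variant = c("cnn_rnn", "cnn"),
                       mode = c("holdout", "cv"),
                       split = split_spec(), train_cfg = train_config(),
                       cv = cv_spec(), seed = 1L) {
  tf_method <- match.arg(tf_method)
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  split$seed <- substream_seed(seed, "split-spec")
  train_cfg$seed <- substream_seed(seed, "train-cfg")
  cv$seed <- substream_seed(seed, "cv-spec")
  structure(list(edf_path = edf_path, labels_path = labels_path,
                 out_dir = out_dir, channel = channel,
                 tf_method = tf_method, variant = variant, mode = mode,
                 split = split, train_cfg = train_cfg, cv = cv,
                 seed = seed),
            class = "run_config")
}

#' Run the full scoring pipeline
#'
#' preprocess (read, resample to 256 Hz, 0.3-35 Hz zero-phase bandpass,
#' segment) -> time-frequency imaging -> train/evaluate (or k-fold CV).
#' Writes an epoch manifest, metrics reports (CSV + JSON), the model
#' checkpoint and a run log into `out_dir`.
#'
#' @param cfg a [run_config()].
#' @return list with the fitted model and the evaluation results
#'   (`metrics` or `cv`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
    msg("%s done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    r
  }
  rec <- step("read", {
    r <- read_edf(cfg$edf_path, cfg$channel)
    labs <- read_stage_labels(cfg$labels_path)
    list(r = r, labs = labs)
  })
  ds <- step("preprocess", {
    r <- resample_to_256(rec$r)
    r <- bandpass_zero_phase(r, filter_spec())
    segment_epochs(r, rec$labs)
  })
  write_epoch_manifest(ds, file.path(cfg$out_dir, "epoch_manifest.csv"))
  imgs <- step("tfimage", epochs_to_images(ds, method = cfg$tf_method))
  net_cfg <- sleepnet_config(variant = cfg$variant,
                             seed = substream_seed(cfg$seed, "net"))
  result <- list(config = cfg)
  if (cfg$mode == "holdout") {
    sp <- split_train_test(imgs, cfg$split)
    fit <- step("train", {
      model <- build_sleepnet(net_cfg)
      train_sleepnet(model, sp$train, cfg$train_cfg)
    })
    metrics <- step("evaluate", {
      pred <- classify_stages(fit$model, sp$test)
      cm <- confusion_matrix(sp$test$labels, pred)
      pcm <- suppressWarnings(per_class_metrics(cm))
      list(confusion = cm, per_class = pcm,
           overall = overall_metrics(cm, pcm))
    })
    save_sleepnet(fit$model, file.path(cfg$out_dir, "model.ckpt"))
    write_metrics_report(metrics$per_class, metrics$overall,
                         file.path(cfg$out_dir, "metrics.csv"))
    write_metrics_report(metrics$per_class, metrics$overall,
                         file.path(cfg$out_dir, "metrics.json"))
    result$model <- fit$model
    result$loss <- fit$loss
    result$metrics <- metrics
  } else {
    cvres <- step("cv", {
      kfold_cv(imgs, cfg$cv, train_fn = function(tr) {
        model <- build_sleepnet(net_cfg)
        train_sleepnet(model, tr, cfg$train_cfg)$model
      }, verbose = TRUE)
    })
    jsonlite::write_json(
      list(mean = cvres$summary$mean, sd = cvres$summary$sd,
           class_average = as.list(cvres$summary$class_average)),
      file.path(cfg$out_dir, "cv_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    result$cv <- cvres
  }
  log <- list(seed = cfg$seed, tf_method = cfg$tf_method,
              variant = cfg$variant, mode = cfg$mode,
              n_epochs = n_epochs(ds),
              class_counts = as.list(ds$class_counts),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
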