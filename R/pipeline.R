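#' Default end-to-end pipeline configuration
#'
#' A desk-scale configuration: synthetic images, normalization to a small
#' square, a reduced-width network and a short training budget, suitable
#' for CPU runs. Every section can be overridden by supplying a nested
#' list; unknown keys are rejected by [validate_run_config()].
#'
#' @param seed Global seed; section seeds are derived from it.
#' @param n_images Number of synthetic images (default 8).
#' @param image_size Side of the generated images (default 64).
#' @param train_size Network input side (default 64).
#' @param base_channels Network width (default 8).
#' @param max_epochs Training epoch cap (default 30).
#' @return A `run_config` nested list.
#' @export
default_run_config <- function(seed = 1, n_images = 8, image_size = 64,
                               train_size = 64, base_channels = 8,
                               max_epochs = 30) {
  list(
    seed = as.integer(seed),
    n_images = as.integer(n_images),
    synth = list(image_size = c(image_size, image_size), seed = seed),
    preprocess = list(target_size = image_size, train_size = train_size,
                      threshold = 10),
    augment = list(expansion_factor = 2, seed = seed + 1),
    model = list(input_size = train_size, num_classes = 4,
                 base_channels = base_channels,
                 attention_stages = c(3, 4), dropout_rate = 0.25),
    train = list(batch_size = 2, lr = 1e-3, max_epochs = max_epochs,
                 seed = seed + 2),
    match = list(sigma = 0.2, connectivity = 8),
    split_seed = seed + 3
  )
}

#' Validate a pipeline configuration
#'
#' Checks every section before any work begins; the error message names
#' the offending key.
#'
#' @param config Nested list as produced by [default_run_config()].
#' @return The validated config (with constructed section objects attached),
#'   invisibly on success; otherwise an error naming the key.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "n_images", "synth", "preprocess", "augment", "model",
            "train", "match", "split_seed")
  for (k in need)
    if (is.null(config[[k]])) stop("config key missing: ", k)
  if (config$n_images < 3) stop("config key invalid: n_images (need >= 3)")
  ps <- config$preprocess
  for (k in c("target_size", "train_size"))
    if (is.null(ps[[k]]) || ps[[k]] < 16)
      stop("config key invalid: preprocess$", k)
  built <- list(
    synth = do.call(synthetic_config, config$synth),
    augment = do.call(augment_config, config$augment),
    model = do.call(model_config, config$model),
    train = do.call(train_config, config$train),
    match = do.call(match_config, config$match)
  )
  config$built <- built
  invisible(config)
}

#' Run the full pipeline: synthesize, preprocess, train, predict, evaluate
#'
#' Generates a synthetic dataset, normalizes it and resizes to the training
#' resolution, splits 2:1 into train/test, augments the training split,
#' trains the network, predicts the test split, and scores it with the
#' component-overlap metric plus pixel-level ROC/AUC and PR/AUPR. Artifacts
#' written to `out_dir`: `metrics.csv` (one row per class plus a pooled
#' row), `history.csv` (per-epoch loss and learning rate), per-image
#' prediction masks and colored overlays.
#'
#' @param config Nested configuration, see [default_run_config()].
#' @param out_dir Output directory.
#' @param verbose Log stage progress (default TRUE).
#' @return List with `metrics` (data frame), `history`, `model`, `counts`
#'   (per-image predicted vs true lesion counts) and `paths`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run"),
                         verbose = TRUE) {
  config <- validate_run_config(config)
  built <- config$built
  say <- function(...) if (verbose) message(sprintf(...))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say("[synth] generating %d images", config$n_images)
  items <- lapply(seq_len(config$n_images), function(i) {
    cfg <- built$synth
    cfg$seed <- cfg$seed + i
    generate_image(cfg)
  })

  say("[preprocess] normalizing to %d, training size %d",
      config$preprocess$target_size, config$preprocess$train_size)
  items <- lapply(items, function(it) {
    nm <- normalize_image(it$image, it$masks,
                          target_size = config$preprocess$target_size,
                          threshold = config$preprocess$threshold)
    tr <- to_train_resolution(nm$image, nm$masks,
                              train_size = config$preprocess$train_size)
    list(image = tr$image, masks = tr$masks, counts = it$counts)
  })

  split <- split_dataset(items, seed = config$split_seed)
  say("[split] %d train / %d test", length(split$train), length(split$test))

  train_set <- augment_dataset(split$train, built$augment)
  say("[augment] training set expanded to %d samples", length(train_set))

  say("[train] building model (base %d) and training up to %d epochs",
      built$model$base_channels, built$train$max_epochs)
  model <- with_seed(config$seed, build_model(built$model))
  fit <- train_model(model, train_set, built$train)
  say("[train] stopped at epoch %d (%s), best loss %.4f",
      fit$stop_epoch, fit$stop_reason, min(fit$history$loss))

  say("[predict/evaluate] scoring %d test images", length(split$test))
  cls <- lesion_classes()
  counts_tbl <- NULL
  per_class_counts <- stats::setNames(
    rep(list(c(TP = 0, FP = 0, FN = 0, TN = 0)), length(cls)), cls)
  probs_all <- stats::setNames(rep(list(numeric(0)), length(cls)), cls)
  truth_all <- stats::setNames(rep(list(integer(0)), length(cls)), cls)
  pred_dir <- file.path(out_dir, "predictions")
  if (!dir.exists(pred_dir)) dir.create(pred_dir)
  for (it in split$test) {
    pred <- predict_lesions(fit$model, it$image)
    write_mask_set(pred$masks, pred_dir)
    write_overlay(it$image, pred$masks,
                  file.path(pred_dir, paste0(it$image$source_id, "_overlay.png")))
    for (cl in cls) {
      cp <- classify_pixels(pred$masks$masks[[cl]], it$masks$masks[[cl]],
                            built$match)
      per_class_counts[[cl]] <- per_class_counts[[cl]] + cp$counts
      probs_all[[cl]] <- c(probs_all[[cl]], as.numeric(pred$probs[[cl]]))
      truth_all[[cl]] <- c(truth_all[[cl]], as.integer(it$masks$masks[[cl]]))
    }
    counts_tbl <- rbind(counts_tbl, data.frame(
      source_id = it$image$source_id, class = cls,
      true_count = as.integer(count_lesions(it$masks)),
      predicted_count = as.integer(count_lesions(pred$masks))))
  }

  metric_row <- function(name, counts, probs = NULL, truth = NULL) {
    m <- compute_metrics(counts)
    auc <- aupr <- NA_real_
    if (!is.null(probs) && length(unique(truth)) > 1) {
      auc <- roc_curve(probs, truth)$auc
      aupr <- pr_curve(probs, truth)$aupr
    }
    data.frame(class = name, TP = counts[["TP"]], FP = counts[["FP"]],
               FN = counts[["FN"]], TN = counts[["TN"]],
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, accuracy = m$accuracy, f1 = m$f1,
               auc = auc, aupr = aupr)
  }
  metrics <- do.call(rbind, lapply(cls, function(cl)
    metric_row(cl, per_class_counts[[cl]], probs_all[[cl]], truth_all[[cl]])))
  pooled <- Reduce(`+`, per_class_counts)
  metrics <- rbind(metrics, metric_row(
    "pooled", pooled, unlist(probs_all, use.names = FALSE),
    unlist(truth_all, use.names = FALSE)))

  paths <- list(metrics = file.path(out_dir, "metrics.csv"),
                history = file.path(out_dir, "history.csv"),
                counts = file.path(out_dir, "lesion_counts.csv"),
                model = file.path(out_dir, "model.rds"),
                predictions = pred_dir)
  saveRDS(fit$model, paths$model)
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(fit$history, paths$history, row.names = FALSE)
  utils::write.csv(counts_tbl, paths$counts, row.names = FALSE)
  say("[done] metrics written to %s", paths$metrics)

  list(metrics = metrics, history = fit$history, model = fit$model,
       counts = counts_tbl, paths = paths)
}
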