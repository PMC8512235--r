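#' Experiment configuration
#'
#' Bundles the stage configurations of a full run: simulate, texture stats,
#' feature stacks, CNN training (RGB branch = the traditional CNN), decision
#' fusion, Bayesian uncertainty and patch attribution. One global seed
#' deterministically derives every stage seed.
#'
#' @param generator an [generator_config()].
#' @param split `(train, validation, test)` fractions.
#' @param cnn an [cnn_config()].
#' @param n_trees trees in the fusion random forest.
#' @param mc_passes Monte-Carlo passes per test image for the Bayesian model.
#' @param mc_max_images cap on the number of test images carried through the
#'   Monte-Carlo evaluation (the passes dominate the pipeline's run time; the
#'   cap subsamples the shuffled test set deterministically).
#' @param bayes_epochs epochs for the Bayesian model (defaults to the CNN's).
#' @param attribution_grid patch grid for Shapley maps.
#' @param n_permutations sampled permutations per attribution map.
#' @param n_attribution_images test images to explain.
#' @param seed global seed.
#' @return An `ir_experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(),
                              split = c(0.6, 0.2, 0.2),
                              cnn = cnn_config(),
                              n_trees = 300L,
                              mc_passes = 300L,
                              mc_max_images = Inf,
                              bayes_epochs = cnn$epochs,
                              attribution_grid = c(8L, 8L),
                              n_permutations = 200L,
                              n_attribution_images = 2L,
                              seed = 1L) {
  structure(list(generator = generator, split = split, cnn = cnn,
                 n_trees = as.integer(n_trees),
                 mc_passes = as.integer(mc_passes),
                 mc_max_images = mc_max_images,
                 bayes_epochs = as.integer(bayes_epochs),
                 attribution_grid = as.integer(attribution_grid),
                 n_permutations = as.integer(n_permutations),
                 n_attribution_images = as.integer(n_attribution_images),
                 seed = as.integer(seed)),
            class = "ir_experiment_config")
}

# standardize one representation's train/val/test image lists
standardize_stack <- function(train, val, test) {
  s <- standardize(train, val = val, test = test)
  list(train = s$train, val = s$val, test = s$test, params = s$params)
}

train_branch <- function(images, labels, cfg, class_weights, augmentation,
                         seed, epochs = cfg$epochs, verbose = FALSE) {
  bcfg <- cfg
  bcfg$seed <- seed
  bcfg$epochs <- as.integer(epochs)
  d <- dim(images$train[[1]])
  model <- build_cnn(bcfg, d)
  train_classifier(model, images$train, labels$train,
                   images$val, labels$val,
                   class_weights = class_weights,
                   augmentation = augmentation, verbose = verbose)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: synthetic data generation; per-class entropy/contrast
#' summary; HOG/LBP feature stacks; shuffled 60/20/20 split; per-stack
#' standardization; training of the three CNN branches (the RGB branch is
#' also reported alone as the traditional CNN); decision-level fusion (random
#' forest trained on the branches' validation-fold probabilities); Bayesian
#' CNN training, Monte-Carlo prediction and per-class uncertainty intervals;
#' and Shapley patch attribution for a few test images. All stage seeds
#' derive from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory: writes `stats.csv`,
#'   `model_comparison.csv`, `uncertainty.csv`, `attribution_<i>.csv` and a
#'   `run.json` sidecar (config hash, seeds, metrics).
#' @param stages subset of
#'   `c("stats", "cnn", "fusion", "bayes", "attribution")` to run (the
#'   simulate/split stages always run; later stages may require earlier ones).
#' @param augment apply rotation/zoom/flip augmentation to training batches.
#' @param verbose print progress lines.
#' @return A result bundle (list) with the pieces produced by the requested
#'   stages: `dataset`, `split`, `stats`, `models`, `comparison`,
#'   `uncertainty`, `attributions`, `config_hash`, `seeds`.
#' @export
run_experiment <- function(config = experiment_config(), output_dir = NULL,
                           stages = c("stats", "cnn", "fusion", "bayes",
                                      "attribution"),
                           augment = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "ir_experiment_config"))
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("stats", "cnn", "fusion", "bayes",
                                  "attribution"))
  seeds <- list(
    simulate = derive_seed(config$seed, "simulate"),
    split = derive_seed(config$seed, "split"),
    rgb = derive_seed(config$seed, "branch_rgb"),
    hog = derive_seed(config$seed, "branch_hog"),
    lbp = derive_seed(config$seed, "branch_lbp"),
    fusion = derive_seed(config$seed, "fusion"),
    bayes = derive_seed(config$seed, "bayes"),
    mc = derive_seed(config$seed, "mc"),
    attribution = derive_seed(config$seed, "attribution")
  )
  say <- function(...) if (verbose) cat(sprintf(...), "\n")
  bundle <- list(config = config, config_hash = config_hash(config),
                 seeds = seeds)

  gen <- config$generator
  gen$seed <- seeds$simulate
  say("simulate: 18 classes x %d images", gen$images_per_class)
  dataset <- generate_dataset(gen)
  bundle$dataset <- dataset

  if ("stats" %in% stages) {
    say("stats: entropy / red-channel contrast per class")
    bundle$stats <- class_summary(dataset)
  }

  split <- split_dataset(dataset, config$split, seed = seeds$split)
  bundle$split <- split
  labels <- list(train = split$train$labels, val = split$validation$labels,
                 test = split$test$labels)

  needs_models <- any(c("cnn", "fusion", "bayes", "attribution") %in% stages)
  if (!needs_models) {
    if (!is.null(output_dir)) write_bundle(bundle, output_dir)
    return(bundle)
  }

  class_weights <- compute_class_weights(labels$train,
                                         n_classes = config$cnn$n_classes)
  aug <- if (augment) augmentation_params() else NULL

  say("features: HOG/LBP stacks")
  stacks <- list(train = feature_image_stack(split$train),
                 val = feature_image_stack(split$validation),
                 test = feature_image_stack(split$test))
  reps <- list()
  for (rep_name in c("rgb", "hog", "lbp")) {
    reps[[rep_name]] <- standardize_stack(stacks$train[[rep_name]],
                                          stacks$val[[rep_name]],
                                          stacks$test[[rep_name]])
  }

  models <- list()
  probs <- list(val = list(), test = list())
  for (rep_name in c("rgb", "hog", "lbp")) {
    if (rep_name != "rgb" && !("fusion" %in% stages)) next
    say("train branch: %s", rep_name)
    models[[rep_name]] <- train_branch(reps[[rep_name]], labels, config$cnn,
                                       class_weights, aug,
                                       seed = seeds[[rep_name]],
                                       verbose = verbose)
    probs$val[[rep_name]] <- predict_proba(models[[rep_name]],
                                           reps[[rep_name]]$val)
    probs$test[[rep_name]] <- predict_proba(models[[rep_name]],
                                            reps[[rep_name]]$test)
  }

  comparison <- list()
  if (!is.null(models$rgb)) {
    pred_rgb <- max.col(probs$test$rgb) - 1L
    comparison$cnn <- evaluation_report(pred_rgb, labels$test,
                                        config$cnn$n_classes)
  }

  if ("fusion" %in% stages) {
    say("fusion: random forest on concatenated branch probabilities")
    feat_val <- fuse_probabilities(probs$val$rgb, probs$val$hog,
                                   probs$val$lbp)
    feat_test <- fuse_probabilities(probs$test$rgb, probs$test$hog,
                                    probs$test$lbp)
    meta <- fusion_meta_classifier(feat_val, labels$val,
                                   n_trees = config$n_trees,
                                   seed = seeds$fusion)
    pred_fusion <- predict(meta, feat_test)
    models$fusion <- meta
    comparison$fusion <- evaluation_report(pred_fusion, labels$test,
                                           config$cnn$n_classes)
  }

  if ("bayes" %in% stages) {
    say("bayes: variational CNN + %d MC passes", config$mc_passes)
    bcfg <- config$cnn
    bcfg$seed <- seeds$bayes
    bcfg$epochs <- config$bayes_epochs
    bmodel <- build_bayesian_cnn(bcfg, dim(reps$rgb$train[[1]]))
    bmodel <- train_bayesian(bmodel, reps$rgb$train, labels$train,
                             reps$rgb$val, labels$val,
                             class_weights = class_weights,
                             augmentation = aug, verbose = verbose)
    models$bayes <- bmodel
    n_mc <- min(length(reps$rgb$test), config$mc_max_images)
    mc_idx <- seq_len(n_mc)
    sets <- mc_predict(bmodel, reps$rgb$test[mc_idx], T = config$mc_passes,
                       seed = seeds$mc)
    pred_bayes <- vapply(sets, function(P) {
      which.max(tabulate(max.col(P), nbins = config$cnn$n_classes)) - 1L
    }, integer(1))
    comparison$bayes <- evaluation_report(pred_bayes, labels$test[mc_idx],
                                          config$cnn$n_classes)
    bundle$uncertainty <- uncertainty_intervals(sets, labels$test[mc_idx],
                                                n_classes = config$cnn$n_classes)
  }

  if ("attribution" %in% stages && !is.null(models$rgb)) {
    say("attribution: permutation Shapley on %d test images",
        config$n_attribution_images)
    baseline <- Reduce(`+`, reps$rgb$train) / length(reps$rgb$train)
    n_show <- min(config$n_attribution_images, length(reps$rgb$test))
    bundle$attributions <- lapply(seq_len(n_show), function(i) {
      img <- reps$rgb$test[[i]]
      cls <- labels$test[i]
      shapley_attribution(cnn_value_fn(models$rgb, cls), img, baseline,
                          grid = config$attribution_grid,
                          n_permutations = config$n_permutations,
                          seed = derive_seed(seeds$attribution, i),
                          target_class = cls)
    })
  }

  bundle$models <- models
  if (length(comparison)) {
    bundle$comparison <- data.frame(
      model = names(comparison),
      accuracy = vapply(comparison, `[[`, numeric(1), "accuracy"),
      macro_precision = vapply(comparison, `[[`, numeric(1), "macro_precision"),
      macro_recall = vapply(comparison, `[[`, numeric(1), "macro_recall"),
      row.names = NULL)
    bundle$reports <- comparison
  }
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

# write the CSV/JSON artifacts of a result bundle
write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$stats)) {
    write.csv(bundle$stats, file.path(output_dir, "stats.csv"),
              row.names = FALSE)
    write.csv(attr(bundle$stats, "per_image"),
              file.path(output_dir, "stats_per_image.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$comparison)) {
    write.csv(bundle$comparison, file.path(output_dir, "model_comparison.csv"),
              row.names = FALSE)
  }
  if (!is.null(bundle$uncertainty)) {
    write.csv(bundle$uncertainty, file.path(output_dir, "uncertainty.csv"),
              row.names = FALSE)
  }
  for (i in seq_along(bundle$attributions)) {
    m <- bundle$attributions[[i]]
    write.csv(m$values, file.path(output_dir, sprintf("attribution_%02d.csv", i)),
              row.names = FALSE)
  }
  sidecar <- list(config_hash = bundle$config_hash, seeds = bundle$seeds,
                  generator = unclass(bundle$config$generator),
                  cnn = unclass(bundle$config$cnn))
  jsonlite::write_json(sidecar, file.path(output_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
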