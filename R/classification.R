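#' CNN configuration
#'
#' The reference architecture: four convolution stages (kernel 3, 'same'
#' padding, L2 kernel penalty, ReLU, 2x2 max-pool, dropout) whose widths are
#' `base_units * unit_multipliers`, then a ReLU dense layer, dropout, and an
#' 18-unit softmax. The hyperparameter grid explored in the study was
#' `base_units` 16/32/64/128, L2 1e-3/1e-4/1e-5, dropout 0.1/0.2/0.3, batch
#' 32/64/128, learning rate 1e-3/1e-4, 100 epochs; the defaults here are the
#' desk-scale working point (base 16, 15 epochs, batch 32) used throughout
#' the package examples, and any grid value can be set explicitly.
#'
#' @param base_units width of the first convolution stage.
#' @param unit_multipliers per-stage width multipliers (length = number of
#'   convolution stages).
#' @param kernel_size convolution kernel side.
#' @param l2_strength L2 kernel-penalty coefficient (deterministic layers).
#' @param dropout dropout rate after every pool and the dense layer.
#' @param dense_units width of the fully connected layer before the softmax.
#' @param n_classes number of output classes.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param kl_weight weight of the KL term per training example in the
#'   Bayesian variant (`NULL` = `1 / n_train`, the standard minibatch ELBO
#'   scaling; `0` trains on the pure negative log-likelihood).
#' @param seed integer seed controlling weight initialization and training.
#' @return An `ir_cnn_config` list.
#' @export
cnn_config <- function(base_units = 16L, unit_multipliers = c(1L, 2L, 3L, 4L),
                       kernel_size = 3L, l2_strength = 1e-4, dropout = 0.2,
                       dense_units = 128L, n_classes = 18L, batch_size = 32L,
                       learning_rate = 1e-3, epochs = 15L, kl_weight = NULL,
                       seed = 1L) {
  cfg <- list(base_units = as.integer(base_units),
              unit_multipliers = as.integer(unit_multipliers),
              kernel_size = as.integer(kernel_size),
              l2_strength = l2_strength, dropout = dropout,
              dense_units = as.integer(dense_units),
              n_classes = as.integer(n_classes),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              kl_weight = kl_weight, seed = as.integer(seed))
  stopifnot(cfg$base_units >= 1L, length(cfg$unit_multipliers) >= 1L,
            cfg$kernel_size %% 2L == 1L, cfg$dropout >= 0, cfg$dropout < 1,
            cfg$n_classes >= 2L, cfg$batch_size >= 1L, cfg$epochs >= 0L)
  structure(cfg, class = "ir_cnn_config")
}

#' Build an (untrained) convolutional classifier
#'
#' @param config an [cnn_config()].
#' @param input_shape integer `(height, width, channels)`; height and width
#'   must be divisible by `2^n_stages` (one 2x2 pool per convolution stage).
#' @param bayesian replace every kernel weight by an independent Gaussian
#'   posterior (mean + standard deviation, sampled via the reparameterization
#'   trick); doubles the number of kernel parameters. See
#'   [build_bayesian_cnn()].
#' @return An object of class `ir_cnn`.
#' @export
build_cnn <- function(config, input_shape, bayesian = FALSE) {
  stopifnot(inherits(config, "ir_cnn_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L) stopf("input_shape must be (H, W, C)")
  layers <- build_network(input_shape, config$n_classes, config$base_units,
                          config$unit_multipliers, config$kernel_size,
                          if (bayesian) 0 else config$l2_strength,
                          config$dropout, config$dense_units, bayesian,
                          seed = config$seed)
  structure(list(layers = layers, config = config, input_shape = input_shape,
                 bayesian = bayesian, trained = FALSE),
            class = "ir_cnn")
}

#' @export
print.ir_cnn <- function(x, ...) {
  widths <- x$config$base_units * x$config$unit_multipliers
  cat(sprintf("<ir_cnn%s: input %s, conv widths %s, dense %d, %d classes, %s>\n",
              if (x$bayesian) " (Bayesian)" else "",
              paste(x$input_shape, collapse = "x"),
              paste(widths, collapse = ","), x$config$dense_units,
              x$config$n_classes,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Count kernel weight parameters
#'
#' Counts the kernel (weight-matrix) parameters of every convolution and
#' dense layer; biases are excluded. A Bayesian network carries a mean and a
#' standard deviation per kernel weight and therefore reports exactly twice
#' the count of its deterministic twin.
#'
#' @param model an `ir_cnn`.
#' @return Integer parameter count.
#' @export
n_weight_parameters <- function(model) {
  n <- 0L
  for (lay in model$layers) {
    if (lay$type %in% c("conv", "dense")) {
      n <- n + if (lay$bayesian) {
        length(lay$params$W_mu) + length(lay$params$W_rho)
      } else {
        length(lay$params$W)
      }
    }
  }
  n
}

# coerce training inputs: list of arrays (+labels) -> matrix
as_batch_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  images_to_matrix(images)
}

#' Train a convolutional classifier
#'
#' Minimizes class-weighted cross-entropy (natural log) with Adam. For a
#' Bayesian model the loss is the negative log-likelihood of sampled-weight
#' predictions plus the KL divergence of the weight posteriors from the
#' standard-normal prior, scaled by `kl_weight` (default `1/n_train`).
#' Augmentation, when given, is applied to training batches only. Everything
#' is driven by `config$seed`, so identical calls give identical histories.
#'
#' @param model an `ir_cnn` from [build_cnn()] or [build_bayesian_cnn()].
#' @param train_images,train_labels training images (list of arrays) and
#'   0-based integer labels.
#' @param val_images,val_labels optional validation set.
#' @param class_weights per-class loss weights ([compute_class_weights()];
#'   default all 1).
#' @param augmentation optional [augmentation_params()].
#' @param epochs,batch_size,learning_rate overrides of the config values.
#' @param verbose print one line per epoch.
#' @return The model, with element `history`: data.frame with per-epoch
#'   `epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`.
#' @export
train_classifier <- function(model, train_images, train_labels,
                             val_images = NULL, val_labels = NULL,
                             class_weights = NULL, augmentation = NULL,
                             epochs = model$config$epochs,
                             batch_size = model$config$batch_size,
                             learning_rate = model$config$learning_rate,
                             verbose = FALSE) {
  stopifnot(inherits(model, "ir_cnn"))
  n_classes <- model$config$n_classes
  y <- as.integer(train_labels)
  if (any(y < 0L | y >= n_classes)) stopf("labels must lie in [0, %d]", n_classes - 1L)
  present <- sort(unique(y))
  if (length(present) < 2L) stopf("training labels contain a single class")
  if (is.null(class_weights)) class_weights <- rep(1, n_classes)
  if (length(class_weights) != n_classes) stopf("need one weight per class")
  n_train <- length(y)
  kl_weight <- if (!model$bayesian) 0
    else if (is.null(model$config$kl_weight)) 1 / n_train
    else model$config$kl_weight
  bayes <- model$bayesian
  is_list_input <- !is.matrix(train_images)
  Xfull <- if (is_list_input && is.null(augmentation)) as_batch_matrix(train_images) else NULL
  Xval <- if (!is.null(val_images)) as_batch_matrix(val_images) else NULL
  yval <- if (!is.null(val_labels)) as.integer(val_labels) else NULL
  layers <- model$layers
  state <- adam_init(layers)
  history <- vector("list", epochs)
  tstep <- 0L
  model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                              accuracy = numeric(0), val_loss = numeric(0),
                              val_accuracy = numeric(0))
  if (epochs == 0L) return(model)
  with_seed(model$config$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_train)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n_train, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, n_train)]
        if (!is.null(augmentation)) {
          imgs <- lapply(bidx, function(i) {
            img <- if (is_list_input) train_images[[i]] else
              array(train_images[i, ], dim = model$input_shape)
            augment(img, augmentation)
          })
          Xb <- images_to_matrix(imgs)
        } else if (!is.null(Xfull)) {
          Xb <- Xfull[bidx, , drop = FALSE]
        } else {
          Xb <- train_images[bidx, , drop = FALSE]
        }
        yb <- y[bidx]
        fw <- nn_forward(layers, Xb, training = TRUE, sample = bayes,
                         keep_cache = TRUE)
        P <- fw$out
        N <- nrow(P)
        sw <- class_weights[yb + 1L]
        p_true <- pmax(P[cbind(seq_len(N), yb + 1L)], 1e-12)
        loss <- -sum(sw * log(p_true)) / N
        one_hot <- matrix(0, N, n_classes)
        one_hot[cbind(seq_len(N), yb + 1L)] <- 1
        dZ <- (P - one_hot) * (sw / N)
        grads <- nn_backward(layers, fw$caches, dZ, kl_weight = kl_weight)
        tstep <- tstep + 1L
        upd <- adam_step(layers, grads, state, tstep, learning_rate)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + loss * N
        ep_correct <- ep_correct + sum(max.col(P) - 1L == yb)
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(Xval)) {
        Pv <- predict_matrix(layers, Xval, sample = bayes)
        pv <- pmax(Pv[cbind(seq_len(nrow(Pv)), yval + 1L)], 1e-12)
        val_loss <- -mean(class_weights[yval + 1L] * log(pv))
        val_acc <- mean(max.col(Pv) - 1L == yval)
      }
      history[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n_train,
                                  accuracy = ep_correct / n_train,
                                  val_loss = val_loss, val_accuracy = val_acc)
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %.3f\n",
                    ep, ep_loss / n_train, ep_correct / n_train, val_acc))
      }
    }
  })
  model$layers <- layers
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model
}

# batched eval-mode forward returning an N x n_classes matrix
predict_matrix <- function(layers, X, sample = FALSE, batch = 128L) {
  n <- nrow(X)
  out <- NULL
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    P <- nn_forward(layers, X[idx, , drop = FALSE], training = FALSE,
                    sample = sample)$out
    if (is.null(out)) out <- matrix(0, n, ncol(P))
    out[idx, ] <- P
  }
  out
}

#' Class-probability predictions
#'
#' Eval-mode forward pass (dropout off; Bayesian models use the posterior
#' means — see [mc_predict()] for sampled predictions).
#'
#' @param model a trained `ir_cnn`.
#' @param images list of image arrays or an `N x D` matrix matching the
#'   model's input shape.
#' @return `N x n_classes` matrix of probabilities; each row sums to one.
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "ir_cnn"))
  X <- as_batch_matrix(images)
  if (nrow(X) == 0L) return(matrix(0, 0L, model$config$n_classes))
  if (ncol(X) != prod(model$input_shape)) {
    stopf("images have %d values per image; model expects %d",
          ncol(X), prod(model$input_shape))
  }
  predict_matrix(model$layers, X)
}

#' Concatenate branch probability vectors into fusion features
#'
#' Decision-level fusion: the class-probability outputs of the RGB, HOG and
#' LBP branches are concatenated per image (in that fixed order) into one
#' `3 * n_classes` feature vector.
#'
#' @param p_rgb,p_hog,p_lbp aligned `N x n_classes` probability matrices.
#' @return `N x (3 * n_classes)` matrix.
#' @export
fuse_probabilities <- function(p_rgb, p_hog, p_lbp) {
  if (nrow(p_rgb) != nrow(p_hog) || nrow(p_rgb) != nrow(p_lbp)) {
    stopf("branch outputs are misaligned: %d / %d / %d rows",
          nrow(p_rgb), nrow(p_hog), nrow(p_lbp))
  }
  cbind(p_rgb, p_hog, p_lbp)
}

#' Random-forest meta-classifier over fusion features
#'
#' Trains a random forest on concatenated branch probabilities. To avoid
#' meta-overfitting, the training features should be branch predictions on
#' held-out (validation) images, not on the branches' own training images.
#'
#' @param features `N x (3 * n_classes)` fusion features ([fuse_probabilities()]).
#' @param labels 0-based integer labels.
#' @param n_trees number of trees (the study grid tested 100 and 300).
#' @param seed seed for the forest.
#' @return Object of class `ir_fusion`: list with the fitted forest (`rf`),
#'   `oob_error` and `n_classes`.
#' @export
fusion_meta_classifier <- function(features, labels, n_trees = 300L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stopf("meta-classifier needs at least two classes in the training labels")
  }
  df <- as.data.frame(features)
  rf <- with_seed(seed,
    randomForest::randomForest(x = df, y = factor(labels), ntree = n_trees))
  structure(list(rf = rf, oob_error = mean(rf$err.rate[n_trees, "OOB"]),
                 n_classes = length(levels(rf$y)), levels = levels(rf$y)),
            class = "ir_fusion")
}

#' @rdname fusion_meta_classifier
#' @param object an `ir_fusion`.
#' @param ... unused.
#' @return `predict()` returns 0-based integer class predictions.
#' @export
predict.ir_fusion <- function(object, features, ...) {
  df <- as.data.frame(features)
  as.integer(as.character(predict(object$rf, newdata = df)))
}
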