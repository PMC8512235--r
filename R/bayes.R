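#' Build a Bayesian convolutional classifier
#'
#' Same architecture as [build_cnn()], but every kernel weight is an
#' independent Gaussian with a learnable mean and standard deviation (the
#' standard deviation is parameterized through a softplus and initialized at
#' 0.05). Forward passes draw kernels by the reparameterization trick, so the
#' network output is stochastic and repeated predictions quantify the model's
#' epistemic uncertainty. The kernel parameter count is exactly twice that of
#' the deterministic twin.
#'
#' @inheritParams build_cnn
#' @return An `ir_cnn` with `bayesian = TRUE`.
#' @export
build_bayesian_cnn <- function(config, input_shape) {
  build_cnn(config, input_shape, bayesian = TRUE)
}

#' Train a Bayesian classifier
#'
#' Convenience wrapper around [train_classifier()]: minimizes the negative
#' log-likelihood of the labels under sampled-weight predictions plus the KL
#' divergence of the weight posteriors from the standard-normal prior, scaled
#' by `kl_weight` (default `1/n_train`; set `kl_weight = 0` in the config to
#' train on the pure likelihood).
#'
#' @inheritParams train_classifier
#' @return The trained model with its history.
#' @export
train_bayesian <- function(model, train_images, train_labels,
                           val_images = NULL, val_labels = NULL,
                           class_weights = NULL, augmentation = NULL,
                           epochs = model$config$epochs,
                           batch_size = model$config$batch_size,
                           learning_rate = model$config$learning_rate,
                           verbose = FALSE) {
  if (!isTRUE(model$bayesian)) stopf("model is not Bayesian; use build_bayesian_cnn()")
  train_classifier(model, train_images, train_labels, val_images, val_labels,
                   class_weights, augmentation, epochs, batch_size,
                   learning_rate, verbose)
}

#' Rescale all posterior standard deviations
#'
#' Multiplies the posterior standard deviation of every Gaussian weight by
#' `factor` (0 collapses the posterior to its mean, making every forward pass
#' identical). Useful for studying how posterior width drives prediction
#' intervals.
#'
#' @param model a Bayesian `ir_cnn`.
#' @param factor non-negative multiplier.
#' @return The modified model.
#' @export
set_posterior_scale <- function(model, factor) {
  stopifnot(isTRUE(model$bayesian), factor >= 0)
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    if (lay$type %in% c("conv", "dense")) {
      sigma <- softplus(lay$params$W_rho) * factor
      model$layers[[li]]$params$W_rho <- softplus_inv(sigma)
    }
  }
  model
}

#' Monte-Carlo prediction distributions
#'
#' Runs `T` independent stochastic forward passes (a fresh kernel draw per
#' pass) over the given images.
#'
#' @param model a trained Bayesian `ir_cnn`.
#' @param images a single `H x W x C` array, a list of arrays, or an `N x D`
#'   matrix.
#' @param T number of stochastic passes.
#' @param seed seed for the kernel draws.
#' @return For a single image, a `T x n_classes` matrix (each row a
#'   probability vector); for several images, a list of such matrices.
#' @export
mc_predict <- function(model, images, T = 300L, seed = 1L) {
  stopifnot(inherits(model, "ir_cnn"))
  if (!isTRUE(model$bayesian)) stopf("mc_predict() needs a Bayesian model")
  if (T < 1L) stopf("T must be >= 1")
  single <- is.array(images) && !is.list(images)
  if (single) images <- list(images)
  X <- as_batch_matrix(images)
  n <- nrow(X)
  k <- model$config$n_classes
  sets <- lapply(seq_len(n), function(i) matrix(0, T, k))
  with_seed(seed, {
    for (t in seq_len(T)) {
      P <- nn_forward(model$layers, X, training = FALSE, sample = TRUE)$out
      for (i in seq_len(n)) sets[[i]][t, ] <- P[i, ]
    }
  })
  if (single) sets[[1]] else sets
}

#' Per-class uncertainty intervals from Monte-Carlo predictions
#'
#' Restricts to correctly predicted images (majority vote of the per-pass
#' argmax equals the true label). For each such image, the `T` probabilities
#' assigned to the true class give a per-image mean, 2.5th and 97.5th
#' percentile (linear interpolation); these are averaged over the images of
#' each class.
#'
#' @param prediction_sets list of `T x n_classes` matrices ([mc_predict()]).
#' @param true_labels 0-based integer labels, one per prediction set.
#' @param n_classes number of classes.
#' @param level interval coverage (default 95%).
#' @return data.frame with one row per class: `class_index`, `n_images`,
#'   `n_correct`, `mean_certainty`, `lower`, `upper`. Classes without any
#'   correctly predicted image report `NA` intervals.
#' @export
uncertainty_intervals <- function(prediction_sets, true_labels,
                                  n_classes = 18L, level = 0.95) {
  if (is.matrix(prediction_sets)) prediction_sets <- list(prediction_sets)
  true_labels <- as.integer(true_labels)
  stopifnot(length(prediction_sets) == length(true_labels))
  alpha <- (1 - level) / 2
  per_image <- lapply(seq_along(prediction_sets), function(i) {
    P <- prediction_sets[[i]]
    votes <- tabulate(max.col(P), nbins = n_classes)
    predicted <- which.max(votes) - 1L
    p_true <- P[, true_labels[i] + 1L]
    q <- quantile(p_true, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(class_index = true_labels[i],
               correct = predicted == true_labels[i],
               mean = mean(p_true), lower = q[1], upper = q[2])
  })
  tab <- do.call(rbind, per_image)
  out <- lapply(0:(n_classes - 1L), function(cls) {
    sub <- tab[tab$class_index == cls, , drop = FALSE]
    ok <- sub[sub$correct, , drop = FALSE]
    data.frame(class_index = cls, n_images = nrow(sub), n_correct = nrow(ok),
               mean_certainty = if (nrow(ok)) mean(ok$mean) else NA_real_,
               lower = if (nrow(ok)) mean(ok$lower) else NA_real_,
               upper = if (nrow(ok)) mean(ok$upper) else NA_real_)
  })
  do.call(rbind, out)
}

#' Plot per-class uncertainty intervals
#'
#' @param summary output of [uncertainty_intervals()].
#' @return A ggplot object: mean certainty with interval bars per class.
#' @export
plot_uncertainty <- function(summary) {
  sub <- summary[!is.na(summary$mean_certainty), , drop = FALSE]
  ggplot2::ggplot(sub, ggplot2::aes(x = factor(class_index),
                                    y = mean_certainty)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = lower, ymax = upper)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "class index", y = "prediction certainty (true class)")
}
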