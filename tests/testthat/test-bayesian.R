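small_bayes_cfg <- function(n_classes = 4L, epochs = 3L, seed = 21L) {
  cnn_config(base_units = 4L, unit_multipliers = c(1L, 2L), dense_units = 16L,
             n_classes = n_classes, epochs = epochs, batch_size = 16L,
             seed = seed)
}

test_that("Gaussian posteriors double the kernel parameter count", {
  cfg <- cnn_config(base_units = 16L)
  det <- build_cnn(cfg, c(64L, 64L, 3L))
  bay <- build_bayesian_cnn(cfg, c(64L, 64L, 3L))
  expect_equal(n_weight_parameters(bay), 2L * n_weight_parameters(det))
  # holds across architectures
  cfg2 <- small_bayes_cfg()
  expect_equal(n_weight_parameters(build_bayesian_cnn(cfg2, c(16L, 16L, 1L))),
               2L * n_weight_parameters(build_cnn(cfg2, c(16L, 16L, 1L))))
})

test_that("an untrained network starts near the uniform-prediction loss", {
  cfg <- cnn_config(seed = 5L)
  m <- build_bayesian_cnn(cfg, c(64L, 64L, 3L))
  set.seed(6)
  X <- matrix(rnorm(16 * 64 * 64 * 3), 16)
  y <- sample(0:17, 16, TRUE)
  P <- irimage:::with_seed(7L,
    irimage:::nn_forward(m$layers, X, sample = TRUE)$out)
  nll <- -mean(log(P[cbind(1:16, y + 1L)]))
  expect_equal(nll, log(18), tolerance = 0.1)
})

test_that("zero posterior variance collapses Monte-Carlo spread", {
  cfg <- small_bayes_cfg()
  m <- build_bayesian_cnn(cfg, c(16L, 16L, 3L))
  m0 <- set_posterior_scale(m, 0)
  img <- array(rnorm(16 * 16 * 3), c(16L, 16L, 3L))
  mc <- mc_predict(m0, img, T = 300L, seed = 9L)
  expect_equal(dim(mc), c(300L, 4L))
  expect_equal(rowSums(mc), rep(1, 300), tolerance = 1e-6)
  expect_true(all(apply(mc, 2, function(col) diff(range(col))) == 0))
  # with nonzero variance the passes differ but stay seeded
  mc1 <- mc_predict(m, img, T = 20L, seed = 9L)
  mc2 <- mc_predict(m, img, T = 20L, seed = 9L)
  expect_identical(mc1, mc2)
  expect_gt(max(apply(mc1, 2, sd)), 0)
  expect_error(mc_predict(m, img, T = 0L), ">= 1")
})

test_that("training reduces the negative log-likelihood on separable data", {
  d <- make_small_dataset(classes = c(0L, 3L, 5L, 8L), images_per_class = 12L,
                          image_size = c(32L, 32L), seed = 29L)
  s <- standardize(d$images)
  cfg <- small_bayes_cfg(epochs = 6L)
  m <- build_bayesian_cnn(cfg, c(32L, 32L, 3L))
  m <- train_bayesian(m, s$train, d$labels)
  h <- m$history
  expect_equal(nrow(h), 6L)
  expect_lt(mean(h$loss[5:6]), mean(h$loss[1:2]))
  expect_lte(h$loss[1], log(4) + 0.3)  # starts near ln(n_classes)
  # zero epochs leave parameters untouched
  m0 <- build_bayesian_cnn(cfg, c(32L, 32L, 3L))
  expect_identical(train_bayesian(m0, s$train, d$labels, epochs = 0L)$layers,
                   m0$layers)
})

test_that("uncertainty summaries respect ordering and handle edge cases", {
  # all passes fully confident in the true class
  sure <- matrix(0, 50, 4); sure[, 3] <- 1
  u <- uncertainty_intervals(list(sure, sure), c(2L, 2L), n_classes = 4L)
  row <- u[u$class_index == 2L, ]
  expect_equal(c(row$mean_certainty, row$lower, row$upper), c(1, 1, 1))
  # classes with no correctly predicted image are reported missing
  expect_true(is.na(u$mean_certainty[u$class_index == 0L]))
  expect_equal(u$n_correct[u$class_index == 0L], 0L)
  # alternating 0.8/0.9 true-class probabilities: mean 0.85, bounds inside
  p <- rep(c(0.8, 0.9), 150L)
  mcs <- cbind(p, 1 - p, 0, 0)
  u2 <- uncertainty_intervals(list(mcs), 0L, n_classes = 4L)
  r2 <- u2[u2$class_index == 0L, ]
  expect_equal(r2$mean_certainty, 0.85)
  expect_gte(r2$lower, 0.8); expect_lte(r2$upper, 0.9)
  expect_lte(r2$lower, r2$mean_certainty)
  expect_lte(r2$mean_certainty, r2$upper)
  # invariant to image ordering
  set.seed(31)
  sets <- lapply(1:6, function(i) {
    m <- matrix(rexp(40 * 4), 40); m / rowSums(m)
  })
  labs <- c(0L, 1L, 2L, 3L, 1L, 0L)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  expect_equal(uncertainty_intervals(sets, labs, n_classes = 4L),
               uncertainty_intervals(sets[perm], labs[perm], n_classes = 4L))
})

test_that("shrinking the posterior shrinks the prediction intervals", {
  d <- make_small_dataset(classes = c(0L, 8L), images_per_class = 10L,
                          image_size = c(32L, 32L), seed = 37L)
  s <- standardize(d$images)
  cfg <- small_bayes_cfg(n_classes = 2L, epochs = 4L)
  m <- build_bayesian_cnn(cfg, c(32L, 32L, 3L))
  m <- train_bayesian(m, s$train, d$labels)
  imgs <- s$train[1:8]
  width_at <- function(model) {
    sets <- mc_predict(model, imgs, T = 80L, seed = 13L)
    u <- uncertainty_intervals(sets, d$labels[1:8], n_classes = 2L)
    mean(u$upper - u$lower, na.rm = TRUE)
  }
  w_full <- width_at(m)
  w_small <- width_at(set_posterior_scale(m, 0.1))
  expect_gt(w_full, 0)
  expect_lt(w_small, w_full)
  expect_equal(width_at(set_posterior_scale(m, 0)), 0)
})
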