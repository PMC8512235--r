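# Correctness of the network engine itself: analytic gradients vs finite
# differences, shape bookkeeping, and determinism.

nn_loss <- function(layers, X, y, cw, kl_weight = 0, seed_fwd = NULL) {
  fw <- if (is.null(seed_fwd)) {
    irimage:::nn_forward(layers, X, training = FALSE, keep_cache = TRUE)
  } else {
    irimage:::with_seed(seed_fwd,
      irimage:::nn_forward(layers, X, training = FALSE, sample = TRUE,
                           keep_cache = TRUE))
  }
  P <- fw$out
  N <- nrow(P)
  -sum(cw[y + 1L] * log(P[cbind(seq_len(N), y + 1L)])) / N +
    irimage:::network_l2(layers) + kl_weight * irimage:::network_kl(layers)
}

test_that("backpropagation matches finite differences", {
  for (bayesian in c(FALSE, TRUE)) {
    cfg <- cnn_config(base_units = 3L, unit_multipliers = c(1L, 2L),
                      dense_units = 6L, n_classes = 4L, l2_strength = 1e-3,
                      dropout = 0, seed = 42L)
    model <- build_cnn(cfg, c(8L, 8L, 2L), bayesian = bayesian)
    layers <- model$layers
    set.seed(7)
    X <- matrix(rnorm(4 * 8 * 8 * 2), 4)
    y <- c(0L, 1L, 2L, 3L)
    cw <- c(1.2, 0.8, 1.0, 1.5)
    klw <- if (bayesian) 0.01 else 0
    seed_fwd <- if (bayesian) 99L else NULL
    fw <- if (is.null(seed_fwd)) {
      irimage:::nn_forward(layers, X, keep_cache = TRUE)
    } else {
      irimage:::with_seed(seed_fwd,
        irimage:::nn_forward(layers, X, sample = TRUE, keep_cache = TRUE))
    }
    P <- fw$out
    one_hot <- matrix(0, 4, 4); one_hot[cbind(1:4, y + 1L)] <- 1
    dZ <- (P - one_hot) * (cw[y + 1L] / 4)
    grads <- irimage:::nn_backward(layers, fw$caches, dZ, kl_weight = klw)
    eps <- 1e-5
    set.seed(13)
    for (li in seq_along(layers)) {
      g <- grads[[li]]
      if (is.null(g)) next
      for (nm in names(g)) {
        p <- layers[[li]]$params[[nm]]
        for (ix in sample(length(p), min(4L, length(p)))) {
          lp <- layers; lp[[li]]$params[[nm]][ix] <- p[ix] + eps
          lm <- layers; lm[[li]]$params[[nm]][ix] <- p[ix] - eps
          num <- (nn_loss(lp, X, y, cw, klw, seed_fwd) -
                  nn_loss(lm, X, y, cw, klw, seed_fwd)) / (2 * eps)
          expect_equal(g[[nm]][ix], num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("architecture bookkeeping matches the configuration", {
  cfg <- cnn_config(base_units = 16L)
  m <- build_cnn(cfg, c(64L, 64L, 3L))
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_equal(vapply(convs, `[[`, integer(1), "filters"),
               c(16L, 32L, 48L, 64L))
  # spatial map before flatten: 64 / 2^4 = 4
  last_pool <- Filter(function(l) l$type == "pool", m$layers)
  expect_equal(last_pool[[4]]$geom$Ho, 4L)
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_equal(dense[[1]]$d_in, 4L * 4L * 64L)
  expect_equal(dense[[2]]$d_out, 18L)
  expect_error(build_cnn(cfg, c(8L, 8L, 3L)), "incompatible")
})

test_that("softmax outputs are probability vectors for any input", {
  cfg <- cnn_config(base_units = 2L, unit_multipliers = c(1L, 2L),
                    dense_units = 5L, n_classes = 6L, seed = 1L)
  m <- build_cnn(cfg, c(16L, 16L, 1L))
  set.seed(2)
  X <- matrix(rnorm(7 * 256) * 10, 7)
  P <- irimage:::predict_matrix(m$layers, X)
  expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-6)
  expect_true(all(P >= 0))
  # duplicated inputs give duplicated outputs; empty input gives empty output
  X2 <- rbind(X[1, ], X[1, ])
  P2 <- predict_proba(m, X2)
  expect_equal(P2[1, ], P2[2, ])
  expect_equal(dim(predict_proba(m, X[0, , drop = FALSE])), c(0L, 6L))
})

test_that("training is deterministic given a seed and skips zero epochs", {
  d <- make_small_dataset(classes = c(0L, 8L), images_per_class = 6L,
                          image_size = c(32L, 32L))
  s <- standardize(d$images)
  cfg <- cnn_config(base_units = 2L, unit_multipliers = c(1L, 2L),
                    dense_units = 8L, n_classes = 2L, epochs = 2L, seed = 77L)
  m0 <- build_cnn(cfg, c(32L, 32L, 3L))
  # zero epochs: parameters untouched, empty history
  mz <- train_classifier(m0, s$train, d$labels, epochs = 0L)
  expect_identical(mz$layers, m0$layers)
  expect_equal(nrow(mz$history), 0L)
  m1 <- train_classifier(m0, s$train, d$labels)
  m2 <- train_classifier(m0, s$train, d$labels)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
  expect_error(train_classifier(m0, s$train, rep(0L, 12L)), "single class")
})
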