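test_that("patch partitions tile the image exactly", {
  p <- partition_patches(c(64L, 64L), c(8L, 8L))
  expect_length(p, 64L)
  expect_true(all(lengths(p) == 64L))
  expect_equal(sort(unlist(p)), 1:(64 * 64))
  one <- partition_patches(c(16L, 16L), c(1L, 1L))
  expect_length(one, 1L)
  expect_equal(sort(one[[1]]), 1:256)
  expect_error(partition_patches(c(10L, 10L), c(3L, 3L)), "does not divide")
})

test_that("the exact oracle satisfies the Shapley axioms", {
  set.seed(3)
  H <- 8L; W <- 8L
  img <- array(runif(H * W), c(H, W, 1L))
  base <- array(0, c(H, W, 1L))
  grid <- c(2L, 4L)
  patches <- partition_patches(c(H, W), grid)
  wts <- c(2, -1, 0.5, 0, 1.5, -0.5, 1, 0.25)
  f <- patch_mean_model(patches, wts, H, W)
  m <- exact_shapley_oracle(f, img, base, grid)
  # efficiency
  expect_equal(sum(m$values), m$full_value - m$base_value, tolerance = 1e-9)
  # null player: weight-zero patch has zero value
  expect_equal(as.numeric(t(m$values))[4], 0, tolerance = 1e-9)
  # symmetry: two interchangeable patches get equal values
  img_sym <- img
  img_sym[patches[[5]]] <- img[patches[[1]]]  # same content as patch 1
  wts_sym <- wts; wts_sym[5] <- wts[1]        # same effect
  ms <- exact_shapley_oracle(patch_mean_model(patches, wts_sym, H, W),
                             img_sym, base, grid)
  vals <- as.numeric(t(ms$values))
  expect_equal(vals[1], vals[5], tolerance = 1e-9)
  # single patch: value is exactly f(image) - f(baseline)
  m1 <- exact_shapley_oracle(f, img, base, c(1L, 1L))
  expect_equal(as.numeric(m1$values), m1$full_value - m1$base_value,
               tolerance = 1e-12)
  expect_error(exact_shapley_oracle(f, img, base, c(4L, 4L)), "12 patches")
})

test_that("the exact oracle matches the subset-sum definition", {
  set.seed(5)
  H <- 6L; W <- 6L
  img <- array(runif(H * W), c(H, W, 1L))
  base <- array(0.2, c(H, W, 1L))
  grid <- c(2L, 3L)
  patches <- partition_patches(c(H, W), grid)
  f <- patch_mean_model(patches, c(1, -2, 0.5, 3, -1, 0.75), H, W)
  m <- exact_shapley_oracle(f, img, base, grid)
  v_of <- function(S) {
    x <- base
    for (p in S) x[patches[[p]]] <- img[patches[[p]]]
    f(matrix(as.numeric(x), 1))
  }
  phi <- naive_shapley(v_of, 6L)
  expect_equal(as.numeric(t(m$values)), phi, tolerance = 1e-9)
})

test_that("an additive model is attributed its per-patch effects exactly", {
  H <- 8L; W <- 8L
  grid <- c(2L, 2L)
  patches <- partition_patches(c(H, W), grid)
  g <- c(1.5, -2, 0.5, 3)
  f_add <- function(X) {
    vapply(seq_len(nrow(X)), function(i) {
      img <- matrix(X[i, ], H, W)
      sum(g * vapply(seq_along(patches),
                     function(p) mean(img[patches[[p]]]), numeric(1)))
    }, numeric(1))
  }
  set.seed(7)
  img <- array(runif(H * W), c(H, W, 1L))
  base <- array(0, c(H, W, 1L))
  expected <- g * vapply(patches, function(p) mean(img[p]), numeric(1))
  m <- exact_shapley_oracle(f_add, img, base, grid)
  expect_equal(as.numeric(t(m$values)), expected, tolerance = 1e-9)
  # sampling estimator recovers additive effects too (any single permutation
  # already does, by additivity)
  ms <- shapley_attribution(f_add, img, base, grid, n_permutations = 20L,
                            seed = 11L)
  expect_equal(as.numeric(t(ms$values)), expected, tolerance = 1e-9)
})

test_that("a constant model gets all-zero attributions", {
  f0 <- function(X) rep(0.42, nrow(X))
  img <- array(runif(64), c(8L, 8L, 1L))
  base <- array(0, c(8L, 8L, 1L))
  m <- shapley_attribution(f0, img, base, c(2L, 2L), n_permutations = 10L,
                           seed = 1L)
  expect_true(all(m$values == 0))
  expect_equal(m$base_value, 0.42)
})

test_that("the sampling estimator converges to the oracle", {
  set.seed(13)
  H <- 8L; W <- 8L
  grid <- c(2L, 4L)  # 8 patches
  patches <- partition_patches(c(H, W), grid)
  f <- patch_mean_model(patches, c(2, -1, 0.5, 0.8, 1.5, -0.5, 1, -2), H, W)
  img <- array(runif(H * W), c(H, W, 1L))
  base <- array(0.1, c(H, W, 1L))
  oracle <- exact_shapley_oracle(f, img, base, grid)
  errs <- vapply(c(100L, 500L, 2000L), function(np) {
    est <- shapley_attribution(f, img, base, grid, n_permutations = np,
                               seed = 17L)
    max(abs(est$values - oracle$values))
  }, numeric(1))
  expect_lte(errs[3], 0.02)
  expect_lt(errs[3], errs[1])
  # efficiency holds exactly for the estimator (telescoping sums)
  est <- shapley_attribution(f, img, base, grid, n_permutations = 50L,
                             seed = 19L)
  expect_equal(sum(est$values), est$full_value - est$base_value,
               tolerance = 1e-12)
  # determinism
  est2 <- shapley_attribution(f, img, base, grid, n_permutations = 50L,
                              seed = 19L)
  expect_identical(est$values, est2$values)
  expect_error(shapley_attribution(f, img, base, grid, n_permutations = 0L),
               ">= 1")
})

test_that("attribution maps can be rendered as overlays", {
  img <- array(runif(16 * 16 * 3, 0, 255), c(16L, 16L, 3L))
  base <- array(0, c(16L, 16L, 3L))
  f0 <- function(X) rowMeans(X) / 255
  m <- shapley_attribution(f0, img, base, c(4L, 4L), n_permutations = 5L,
                           seed = 1L, target_class = 3L)
  p <- render_attribution(m, img)
  expect_s3_class(p, "ggplot")
})
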