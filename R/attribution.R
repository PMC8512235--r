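#' Partition an image into a rectangular patch grid
#'
#' Shapley values over individual pixels are intractable, so attributions are
#' computed over disjoint rectangular patches covering the image.
#'
#' @param image_dim integer `(height, width)` (extra dimensions ignored).
#' @param grid integer `(rows, cols)`; must divide the image dimensions.
#' @return List of integer vectors, one per patch in row-major order
#'   (left-to-right within a patch row), each indexing the pixels of a single
#'   `H x W` plane.
#' @export
partition_patches <- function(image_dim, grid) {
  H <- image_dim[1]; W <- image_dim[2]
  gr <- as.integer(grid[1]); gc <- as.integer(grid[2])
  if (H %% gr != 0L || W %% gc != 0L) {
    stopf("grid %dx%d does not divide image %dx%d", gr, gc, H, W)
  }
  ph <- H %/% gr; pw <- W %/% gc
  patches <- vector("list", gr * gc)
  k <- 0L
  for (r in seq_len(gr)) for (cc in seq_len(gc)) {
    k <- k + 1L
    rows <- (r - 1L) * ph + seq_len(ph)
    cols <- (cc - 1L) * pw + seq_len(pw)
    patches[[k]] <- as.integer(outer(rows, (cols - 1L) * H, "+"))
  }
  patches
}

# Compose masked images: for each row of `member` (logical n_images x
# n_patches), reveal the listed patches of `image` on top of `baseline`.
# Returns an n_images x (H*W*C) matrix.
masked_batch <- function(image, baseline, patches, member) {
  d <- dim(image)
  HW <- d[1] * d[2]
  C <- if (length(d) == 3L) d[3] else 1L
  base_vec <- as.numeric(baseline)
  img_vec <- as.numeric(image)
  X <- matrix(base_vec, nrow(member), length(base_vec), byrow = TRUE)
  for (p in seq_along(patches)) {
    rows <- which(member[, p])
    if (!length(rows)) next
    pix <- patches[[p]]
    cols <- as.integer(outer(pix, (seq_len(C) - 1L) * HW, "+"))
    X[rows, cols] <- matrix(img_vec[cols], length(rows), length(cols),
                            byrow = TRUE)
  }
  X
}

as_attribution <- function(values, grid, target_class, base_value, full_value) {
  structure(list(values = matrix(values, grid[1], grid[2], byrow = TRUE),
                 grid = as.integer(grid), target_class = target_class,
                 base_value = base_value, full_value = full_value),
            class = "ir_attribution")
}

#' Sampling-based Shapley attribution over image patches
#'
#' Permutation-sampling estimate of the Shapley value of each patch for a
#' model output (e.g. the probability of a target class): for random
#' permutations of the patches, each patch's marginal contribution is the
#' model output with the patch revealed minus the output with it hidden
#' (hidden patches are replaced by the baseline image), averaged over
#' permutations. The per-permutation contributions telescope, so the
#' estimated values sum exactly to `f(image) - f(baseline)` (efficiency).
#'
#' @param f value function: takes an `N x (H*W*C)` matrix of flattened images
#'   and returns `N` numbers. Use [cnn_value_fn()] to wrap a trained model.
#' @param image `H x W x C` array to explain.
#' @param baseline array of the same shape representing "no information"
#'   (commonly the training-set mean image).
#' @param grid patch grid `(rows, cols)`.
#' @param n_permutations number of sampled permutations.
#' @param seed RNG seed.
#' @param target_class stored in the result for bookkeeping.
#' @return An `ir_attribution`: `values` (grid matrix, probability units),
#'   `grid`, `target_class`, `base_value = f(baseline)` and
#'   `full_value = f(image)`.
#' @export
shapley_attribution <- function(f, image, baseline, grid = c(8L, 8L),
                                n_permutations = 2000L, seed = 1L,
                                target_class = NA_integer_) {
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  d <- dim(image)
  if (!identical(dim(baseline), d)) stopf("baseline shape must match the image")
  patches <- partition_patches(d, grid)
  n <- length(patches)
  values <- numeric(n)
  base_value <- NULL; full_value <- NULL
  with_seed(seed, {
    for (s in seq_len(n_permutations)) {
      perm <- sample.int(n)
      member <- matrix(FALSE, n + 1L, n)
      for (t in seq_len(n)) member[t + 1L, perm[seq_len(t)]] <- TRUE
      X <- masked_batch(image, baseline, patches, member)
      v <- f(X)
      if (is.null(base_value)) { base_value <- v[1]; full_value <- v[n + 1L] }
      values[perm] <- values[perm] + diff(v)
    }
  })
  as_attribution(values / n_permutations, grid, target_class, base_value,
                 full_value)
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all `2^n` patch coalitions and applies the combinatorial
#' Shapley weights; tractable for `n <= 12` patches and used as the oracle
#' against which the sampling estimator is validated.
#'
#' @inheritParams shapley_attribution
#' @return An `ir_attribution` with exact values (efficiency holds to
#'   numerical precision).
#' @export
exact_shapley_oracle <- function(f, image, baseline, grid = c(2L, 2L),
                                 target_class = NA_integer_) {
  d <- dim(image)
  if (!identical(dim(baseline), d)) stopf("baseline shape must match the image")
  patches <- partition_patches(d, grid)
  n <- length(patches)
  if (n > 12L) stopf("exact enumeration limited to 12 patches (got %d)", n)
  n_sets <- 2L^n
  member <- matrix(FALSE, n_sets, n)
  for (p in seq_len(n)) {
    member[, p] <- bitwAnd(0:(n_sets - 1L), bitwShiftL(1L, p - 1L)) > 0L
  }
  X <- masked_batch(image, baseline, patches, member)
  v <- f(X)                      # value of every coalition
  sizes <- rowSums(member)
  # weight of a coalition S (not containing i): |S|! (n-|S|-1)! / n!
  wt <- exp(lfactorial(0:n) + lfactorial(n - 1L - (0:n)) - lfactorial(n))
  values <- numeric(n)
  for (p in seq_len(n)) {
    without <- !member[, p]
    with_i <- bitwOr(0:(n_sets - 1L), bitwShiftL(1L, p - 1L)) + 1L
    values[p] <- sum(wt[sizes[without] + 1L] *
                       (v[with_i[without]] - v[without]))
  }
  as_attribution(values, grid, target_class, v[1], v[n_sets])
}

#' Value function of a trained classifier
#'
#' Wraps a trained `ir_cnn` as the scalar value function used by the Shapley
#' estimators: the predicted probability of `target_class`.
#'
#' @param model a trained `ir_cnn`.
#' @param target_class 0-based class index.
#' @return Function mapping an `N x D` matrix of flattened images to `N`
#'   probabilities.
#' @export
cnn_value_fn <- function(model, target_class) {
  force(model); force(target_class)
  function(X) predict_matrix(model$layers, X)[, target_class + 1L]
}

#' Overlay attribution values on an image
#'
#' Renders the patch Shapley values as a diverging red (positive) / blue
#' (negative) overlay on the grayscale image, one panel per attribution map.
#'
#' @param maps an `ir_attribution` or list of them (e.g. one per class).
#' @param image the `H x W x C` image that was explained.
#' @param alpha overlay opacity.
#' @return A ggplot object.
#' @export
render_attribution <- function(maps, image, alpha = 0.55) {
  if (inherits(maps, "ir_attribution")) maps <- list(maps)
  d <- dim(image)
  gray <- if (length(d) == 3L && d[3] == 3L) rgb_to_gray(image) else
    array(image, d[1:2])
  panels <- lapply(seq_along(maps), function(k) {
    m <- maps[[k]]
    if (any(d[1:2] %% m$grid != 0L)) stopf("map grid does not match the image")
    ph <- d[1] %/% m$grid[1]; pw <- d[2] %/% m$grid[2]
    expand <- m$values[rep(seq_len(m$grid[1]), each = ph),
                       rep(seq_len(m$grid[2]), each = pw)]
    data.frame(
      y = rep(seq_len(d[1]), times = d[2]),
      x = rep(seq_len(d[2]), each = d[1]),
      gray = as.numeric(gray) / max(as.numeric(gray), 1),
      value = as.numeric(expand),
      panel = sprintf("class %s", m$target_class)
    )
  })
  df <- do.call(rbind, panels)
  lim <- max(abs(df$value), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = gray), fill = "black") +
    ggplot2::geom_raster(ggplot2::aes(fill = value), alpha = alpha) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha_identity() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Shapley value")
}
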