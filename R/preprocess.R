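#' Centered crop and bilinear resize
#'
#' Mirrors the acquisition pipeline: images are cropped centrally (the imaging
#' enclosure centres the field of view) to remove border artefacts and then
#' downsized with bilinear interpolation.
#'
#' @param image `H x W x C` array or matrix.
#' @param crop_size integer `(height, width)` of the central crop; must not
#'   exceed the image size.
#' @param out_size integer `(height, width)` after resizing.
#' @return Array of dimension `out_size x C` (numeric).
#' @export
crop_and_resize <- function(image, crop_size, out_size) {
  d <- dim(image)
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  crop_size <- as.integer(crop_size); out_size <- as.integer(out_size)
  if (any(crop_size > d[1:2])) {
    stopf("crop %dx%d exceeds image size %dx%d",
          crop_size[1], crop_size[2], d[1], d[2])
  }
  if (any(crop_size < 1L) || any(out_size < 1L)) stopf("sizes must be positive")
  y0 <- (d[1] - crop_size[1]) %/% 2L
  x0 <- (d[2] - crop_size[2]) %/% 2L
  img <- image[y0 + seq_len(crop_size[1]), x0 + seq_len(crop_size[2]), ,
               drop = FALSE]
  if (all(crop_size == out_size)) return(img * 1.0)
  out <- array(0, dim = c(out_size, d[3]))
  eb <- EBImage::resize(EBImage::Image(img / 255, colormode = "Grayscale"),
                        w = out_size[1], h = out_size[2], filter = "bilinear")
  out[] <- EBImage::imageData(eb) * 255
  out
}

#' Z-score standardization fitted on the training set
#'
#' Fits per-channel mean and standard deviation over all training pixels and
#' applies `z = (x - mu) / sigma` to the training set and any number of other
#' image sets. Channels with zero variance get `sigma = 1` (with a warning) so
#' constant features map to zero.
#'
#' @param train_images list of `H x W x C` arrays (training set).
#' @param ... further image sets (lists) transformed with the training
#'   parameters.
#' @return List with `train`, one entry per extra set (named as passed, or
#'   `set1`, `set2`, ...), and `params` (list with `mu`, `sigma` per channel).
#' @export
standardize <- function(train_images, ...) {
  if (!length(train_images)) stopf("training set must be non-empty")
  d <- dim(train_images[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  C <- d[3]
  sums <- numeric(C); sqs <- numeric(C); n <- 0
  for (img in train_images) {
    dim(img) <- c(prod(d[1:2]), C)
    sums <- sums + colSums(img)
    sqs <- sqs + colSums(img^2)
    n <- n + nrow(img)
  }
  mu <- sums / n
  sigma <- sqrt(pmax(sqs / n - mu^2, 0))
  if (any(sigma == 0)) {
    warning("zero-variance channel(s): sigma replaced by 1")
    sigma[sigma == 0] <- 1
  }
  apply_one <- function(img) {
    di <- dim(img); if (length(di) == 2L) di <- c(di, 1L)
    z <- array(0, di)
    for (ch in seq_len(C)) z[, , ch] <- (img[, , ch] - mu[ch]) / sigma[ch]
    z
  }
  extra <- list(...)
  out <- list(train = lapply(train_images, apply_one))
  if (length(extra)) {
    nm <- names(extra)
    if (is.null(nm)) nm <- rep("", length(extra))
    nm[nm == ""] <- paste0("set", seq_along(extra))[nm == ""]
    for (i in seq_along(extra)) out[[nm[i]]] <- lapply(extra[[i]], apply_one)
  }
  out$params <- list(mu = mu, sigma = sigma)
  out
}

#' Invert a standardization
#'
#' @param images list of standardized arrays.
#' @param params `params` element returned by [standardize()].
#' @return List of arrays on the original intensity scale.
#' @export
unstandardize <- function(images, params) {
  lapply(images, function(z) {
    di <- dim(z); if (length(di) == 2L) di <- c(di, 1L); dim(z) <- di
    x <- array(0, di)
    for (ch in seq_len(di[3])) x[, , ch] <- z[, , ch] * params$sigma[ch] + params$mu[ch]
    x
  })
}

#' Shuffled train/validation/test split
#'
#' Shuffles the dataset with the given seed and partitions it by the stated
#' fractions. Sizes of the validation and test sets are floor-rounded; the
#' remainder goes to the training set.
#'
#' @param dataset an `ir_dataset`.
#' @param fractions numeric `(train, validation, test)` summing to one.
#' @param seed integer shuffle seed.
#' @return List of `ir_dataset`s: `train`, `validation`, `test` (disjoint and
#'   exhaustive), plus `indices` giving the original positions of each part.
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(dataset, "ir_dataset"))
  n <- length(dataset$images)
  if (n < 1L) stopf("cannot split an empty dataset")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be three positive numbers summing to 1")
  }
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  list(train = subset_dataset(dataset, idx$train),
       validation = subset_dataset(dataset, idx$validation),
       test = subset_dataset(dataset, idx$test),
       indices = idx)
}

#' Balanced class weights
#'
#' `weight_c = n_total / (n_classes * n_c)`, the balanced-weight formula:
#' minority classes are up-weighted, majority classes down-weighted, and a
#' balanced dataset yields all weights equal to one.
#'
#' @param labels integer class indices.
#' @param n_classes number of classes declared (defaults to
#'   `max(labels) + 1` for 0-based labels).
#' @return Numeric vector of length `n_classes`, names = class indices.
#' @export
compute_class_weights <- function(labels, n_classes = max(labels) + 1L) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    stopf("class(es) absent from labels: %s",
          paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  w <- length(labels) / (n_classes * counts)
  names(w) <- as.character(seq_len(n_classes) - 1L)
  w
}

#' Training-time augmentation parameters
#'
#' @param rotation_max maximum absolute rotation in degrees (drawn uniformly
#'   in `[-rotation_max, rotation_max]`).
#' @param zoom_range `(low, high)` multiplicative zoom factors, drawn
#'   uniformly.
#' @param horizontal_flip,vertical_flip apply the flip with probability 0.5?
#' @return An `ir_augmentation` list.
#' @export
augmentation_params <- function(rotation_max = 20, zoom_range = c(0.9, 1.1),
                                horizontal_flip = TRUE, vertical_flip = TRUE) {
  if (rotation_max < 0) stopf("rotation_max must be >= 0")
  if (length(zoom_range) != 2L || zoom_range[1] > zoom_range[2]) {
    stopf("zoom_range must be (low, high) with low <= high")
  }
  structure(list(rotation_max = rotation_max, zoom_range = zoom_range,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip),
            class = "ir_augmentation")
}

#' Random rotation / zoom / flip augmentation
#'
#' Applies a random rotation (uniform in `[-rotation_max, rotation_max]`
#' degrees), a random zoom (uniform in `zoom_range`) and, with probability 0.5
#' each, horizontal and vertical flips. Rotation and zoom are a single
#' bilinear affine warp about the image centre; uncovered pixels are filled
#' with `fill`. Uses the current RNG stream, so seeding the caller makes the
#' output deterministic.
#'
#' @param image `H x W x C` numeric array.
#' @param params an [augmentation_params()] object.
#' @param fill fill value for pixels mapped from outside the image.
#' @return Augmented array of the same dimensions.
#' @export
augment <- function(image, params = augmentation_params(), fill = 0) {
  stopifnot(inherits(params, "ir_augmentation"))
  d <- dim(image)
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  angle <- if (params$rotation_max > 0) {
    runif(1, -params$rotation_max, params$rotation_max)
  } else 0
  zoom <- if (diff(params$zoom_range) > 0 || params$zoom_range[1] != 1) {
    runif(1, params$zoom_range[1], params$zoom_range[2])
  } else 1
  flip_h <- isTRUE(params$horizontal_flip) && runif(1) < 0.5
  flip_v <- isTRUE(params$vertical_flip) && runif(1) < 0.5
  out <- image
  if (angle != 0 || zoom != 1) {
    th <- angle * pi / 180
    # inverse map: for each output pixel, sample input at the back-rotated,
    # back-zoomed position about the centre
    cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
    oy <- rep(seq_len(d[1]), times = d[2]) - cy
    ox <- rep(seq_len(d[2]), each = d[1]) - cx
    sy <- (cos(th) * oy - sin(th) * ox) / zoom + cy
    sx <- (sin(th) * oy + cos(th) * ox) / zoom + cx
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    inside <- y0 >= 1 & y0 + 1 <= d[1] & x0 >= 1 & x0 + 1 <= d[2]
    out <- array(fill, d)
    y0i <- pmin(pmax(y0, 1L), d[1] - 1L); x0i <- pmin(pmax(x0, 1L), d[2] - 1L)
    for (ch in seq_len(d[3])) {
      m <- image[, , ch]
      i00 <- cbind(y0i, x0i); i10 <- cbind(y0i + 1L, x0i)
      i01 <- cbind(y0i, x0i + 1L); i11 <- cbind(y0i + 1L, x0i + 1L)
      v <- m[i00] * (1 - wy) * (1 - wx) + m[i10] * wy * (1 - wx) +
           m[i01] * (1 - wy) * wx + m[i11] * wy * wx
      v[!inside] <- fill
      out[, , ch] <- v
    }
  }
  if (flip_h) out <- out[, d[2]:1, , drop = FALSE]
  if (flip_v) out <- out[d[1]:1, , , drop = FALSE]
  out
}
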