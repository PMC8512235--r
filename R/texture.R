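#' Shannon entropy of an image intensity histogram
#'
#' Computes `H = -sum(p_i log2 p_i)` over the discrete intensity histogram,
#' skipping empty bins. RGB images are first reduced to gray luminance
#' (ITU-R BT.601 weights, see [rgb_to_gray()]) so that the statistic measures
#' whole-image texture; a single channel can be passed directly.
#'
#' @param image matrix (single channel) or `H x W x 3` RGB array with values
#'   in `[0, levels - 1]`.
#' @param levels number of histogram bins (intensity levels).
#' @return Entropy in bits, in `[0, log2(levels)]`.
#' @export
shannon_entropy <- function(image, levels = 256L) {
  if (length(image) == 0L) stopf("cannot compute entropy of an empty image")
  if (is.array(image) && length(dim(image)) == 3L) {
    image <- if (dim(image)[3] == 3L) rgb_to_gray(image) else image[, , 1]
  }
  v <- as.numeric(image)
  if (any(v < 0 | v > levels - 1L)) {
    stopf("pixel values must lie in [0, %d]", levels - 1L)
  }
  counts <- tabulate(as.integer(round(v)) + 1L, nbins = levels)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Counts ordered pairs of intensity values `(pixel, pixel at offset)` across
#' a single channel. The default offset is one pixel at zero radians
#' (horizontal neighbour to the right), the configuration used for the
#' red-channel contrast analysis.
#'
#' @param channel integer-valued matrix with values in `[0, levels - 1]`.
#' @param distance offset length in pixels.
#' @param angle offset angle in radians; `0` pairs each pixel with the pixel
#'   `distance` columns to its right, `pi/2` with the pixel `distance` rows up.
#' @param levels number of gray levels.
#' @param normalize divide counts by the total number of pairs so entries sum
#'   to one.
#' @return An object of class `ir_glcm`: list with the `levels x levels`
#'   matrix `G`, `offset` (row/column pixel offset), `levels` and `normalized`.
#' @export
cooccurrence_matrix <- function(channel, distance = 1L, angle = 0,
                                levels = 256L, normalize = TRUE) {
  if (is.array(channel) && length(dim(channel)) == 3L) {
    stopf("cooccurrence_matrix() expects a single channel; extract one first")
  }
  channel <- as.matrix(channel)
  if (any(channel < 0 | channel > levels - 1L)) {
    stopf("channel values must lie in [0, %d]", levels - 1L)
  }
  # skimage-compatible offset convention: (row, col) = (d sin a, d cos a)
  dr <- as.integer(round(distance * sin(angle)))
  dc <- as.integer(round(distance * cos(angle)))
  H <- nrow(channel); W <- ncol(channel)
  rows <- seq_len(H); cols <- seq_len(W)
  r1 <- rows[rows + dr >= 1L & rows + dr <= H]
  c1 <- cols[cols + dc >= 1L & cols + dc <= W]
  if (!length(r1) || !length(c1)) {
    stopf("image is smaller than the requested offset (%d, %d)", dr, dc)
  }
  a <- as.integer(round(channel[r1, c1, drop = FALSE]))
  b <- as.integer(round(channel[r1 + dr, c1 + dc, drop = FALSE]))
  idx <- a + levels * b + 1L  # (i, j) pair -> linear bin
  counts <- tabulate(idx, nbins = as.integer(levels)^2)
  G <- matrix(as.numeric(counts), levels, levels)
  if (normalize) G <- G / sum(G)
  structure(list(G = G, offset = c(dr, dc), levels = as.integer(levels),
                 normalized = normalize),
            class = "ir_glcm")
}

normalize_glcm <- function(glcm) {
  if (!glcm$normalized) {
    glcm$G <- glcm$G / sum(glcm$G)
    glcm$normalized <- TRUE
    message("co-occurrence matrix was unnormalized; normalizing before use")
  }
  glcm
}

glcm_index_grids <- function(levels) {
  i <- matrix(0:(levels - 1L), levels, levels)          # row index
  list(i = i, j = t(i))
}

#' GLCM texture properties
#'
#' Standard Haralick-style properties of a normalized co-occurrence matrix
#' `G`: `glcm_contrast()` is `sum_ij G_ij (i - j)^2`; `glcm_props()` also
#' returns dissimilarity `sum G|i-j|`, homogeneity `sum G/(1+(i-j)^2)`,
#' energy `sqrt(sum G^2)` and the intensity correlation.
#'
#' @param glcm an `ir_glcm` from [cooccurrence_matrix()] (unnormalized input
#'   is normalized internally with a message).
#' @return `glcm_contrast()` a single number; `glcm_props()` a named list.
#' @export
glcm_contrast <- function(glcm) {
  stopifnot(inherits(glcm, "ir_glcm"))
  glcm <- normalize_glcm(glcm)
  ij <- glcm_index_grids(glcm$levels)
  sum(glcm$G * (ij$i - ij$j)^2)
}

#' @rdname glcm_contrast
#' @export
glcm_props <- function(glcm) {
  stopifnot(inherits(glcm, "ir_glcm"))
  glcm <- normalize_glcm(glcm)
  ij <- glcm_index_grids(glcm$levels)
  d <- ij$i - ij$j
  G <- glcm$G
  mu_i <- sum(ij$i * G); mu_j <- sum(ij$j * G)
  sd_i <- sqrt(sum((ij$i - mu_i)^2 * G)); sd_j <- sqrt(sum((ij$j - mu_j)^2 * G))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((ij$i - mu_i) * (ij$j - mu_j) * G) / (sd_i * sd_j)
  } else 1
  list(contrast = sum(G * d^2),
       dissimilarity = sum(G * abs(d)),
       homogeneity = sum(G / (1 + d^2)),
       energy = sqrt(sum(G^2)),
       correlation = corr)
}

#' Per-image texture summary
#'
#' Entropy is computed on the gray-luminance histogram of the whole image;
#' the co-occurrence properties are computed on the red channel (red dominates
#' intestinal tissue) with a one-pixel horizontal offset.
#'
#' @param image `H x W x 3` RGB array, 8-bit values.
#' @param distance,angle,levels passed to [cooccurrence_matrix()].
#' @return Named list: `entropy_bits`, `contrast`, `dissimilarity`,
#'   `homogeneity`, `energy`, `correlation`.
#' @export
red_channel_stats <- function(image, distance = 1L, angle = 0, levels = 256L) {
  check_rgb(image)
  red <- image[, , 1]
  glcm <- cooccurrence_matrix(red, distance = distance, angle = angle,
                              levels = levels)
  c(list(entropy_bits = shannon_entropy(image, levels = levels)),
    glcm_props(glcm))
}

#' Per-class distribution summary of entropy and contrast
#'
#' Computes the per-image texture statistics for a labelled dataset and
#' summarizes each class with boxplot statistics (median, quartiles, Tukey
#' 1.5 IQR whiskers).
#'
#' @param dataset an `ir_dataset`.
#' @return A data.frame with one row per class and statistic (`entropy_bits`,
#'   `contrast`): columns `class_index`, `statistic`, `n`, `mean`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`. The per-image values are
#'   attached as attribute `"per_image"`.
#' @export
class_summary <- function(dataset) {
  stopifnot(inherits(dataset, "ir_dataset"))
  per <- lapply(dataset$images, red_channel_stats)
  tab <- data.frame(
    class_index = dataset$labels,
    entropy_bits = vapply(per, `[[`, numeric(1), "entropy_bits"),
    contrast = vapply(per, `[[`, numeric(1), "contrast")
  )
  rows <- list()
  for (cls in sort(unique(tab$class_index))) {
    sub <- tab[tab$class_index == cls, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("class %d has no images; skipped", cls))
      next
    }
    for (stat in c("entropy_bits", "contrast")) {
      v <- sub[[stat]]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      lo <- min(v[v >= q[1] - 1.5 * iqr])
      hi <- max(v[v <= q[3] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <- data.frame(
        class_index = cls, statistic = stat, n = length(v),
        mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = lo, whisker_high = hi, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_image") <- tab
  out
}

#' Boxplot of per-class entropy and contrast
#'
#' @param summary output of [class_summary()] (uses its `"per_image"`
#'   attribute).
#' @return A ggplot object with one facet per statistic.
#' @export
plot_class_summary <- function(summary) {
  tab <- attr(summary, "per_image")
  if (is.null(tab)) stopf("summary lacks the per-image attribute")
  long <- rbind(
    data.frame(class_index = tab$class_index, statistic = "entropy_bits",
               value = tab$entropy_bits),
    data.frame(class_index = tab$class_index, statistic = "contrast",
               value = tab$contrast))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(class_index), y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~statistic, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "class index", y = NULL)
}
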