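#' RGB to gray luminance
#'
#' ITU-R BT.601 weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image `H x W x 3` array.
#' @param round_8bit round the result to 8-bit integers (default keeps the
#'   exact weighted sum).
#' @return `H x W` matrix.
#' @export
rgb_to_gray <- function(image, round_8bit = FALSE) {
  check_rgb(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (round_8bit) g <- round(g)
  g
}

# Centered-difference gradients with edge replication. Returns list(gx, gy):
# gx[i, j] = I[i, j+1] - I[i, j-1] (columns), gy rows, halved nowhere (the
# constant factor cancels in orientation and block normalization).
image_gradients <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  left <- gray[, c(1L, seq_len(W - 1L)), drop = FALSE]
  right <- gray[, c(seq_len(W - 1L) + 1L, W), drop = FALSE]
  up <- gray[c(1L, seq_len(H - 1L)), , drop = FALSE]
  down <- gray[c(seq_len(H - 1L) + 1L, H), , drop = FALSE]
  list(gx = right - left, gy = down - up)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' From-scratch HOG: centered-difference gradients, 9 unsigned orientation
#' bins over `[0, 180)` degrees with magnitude-weighted linear interpolation
#' between neighbouring bin centres, `cell x cell` pixel cells, `2 x 2`-cell
#' blocks at one-cell stride, L2 block normalization, flattened row-major
#' (blocks scanned down rows then across columns, cells within a block
#' likewise, bins fastest).
#'
#' @param gray `H x W` matrix; both dimensions must be divisible by `cell`.
#' @param orientations number of unsigned orientation bins.
#' @param cell cell side in pixels.
#' @param block block side in cells.
#' @param render also compute an image-shaped rendering (per-cell oriented
#'   lines weighted by the cell histogram), used as the "HOG image" input of
#'   the fusion CNN branch.
#' @return Object of class `ir_hog`: list with `vector` (length
#'   `blocks_y * blocks_x * block^2 * orientations`), `cell_hist`
#'   (`cells_y x cells_x x orientations`), `params`, and `rendering`
#'   (`H x W` matrix) when requested.
#' @export
hog_descriptor <- function(gray, orientations = 9L, cell = 8L, block = 2L,
                           render = FALSE) {
  if (is.array(gray) && length(dim(gray)) == 3L) {
    stopf("hog_descriptor() expects a grayscale matrix; use rgb_to_gray()")
  }
  gray <- as.matrix(gray) * 1.0
  H <- nrow(gray); W <- ncol(gray)
  if (H %% cell != 0L || W %% cell != 0L) {
    stopf("image %dx%d not divisible by cell size %d; resize first", H, W, cell)
  }
  g <- image_gradients(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  theta <- atan2(g$gy, g$gx) * 180 / pi       # (-180, 180]
  theta <- theta %% 180                        # unsigned, [0, 180)
  bin_width <- 180 / orientations
  # linear interpolation between the two nearest bin centres (k - 0.5) * bw
  t <- theta / bin_width - 0.5
  b0 <- floor(t)
  w1 <- t - b0                                 # weight of upper bin
  b1 <- (b0 + 1L) %% orientations
  b0 <- b0 %% orientations
  cells_y <- H %/% cell; cells_x <- W %/% cell
  cell_id <- (ceiling(row(gray) / cell) - 1L) +
    cells_y * (ceiling(col(gray) / cell) - 1L)      # 0-based, y fastest
  key0 <- cell_id * orientations + b0
  key1 <- cell_id * orientations + b1
  nbin <- cells_y * cells_x * orientations
  hist <- numeric(nbin)
  acc0 <- rowsum(as.numeric(mag * (1 - w1)), as.integer(key0))
  acc1 <- rowsum(as.numeric(mag * w1), as.integer(key1))
  hist[as.integer(rownames(acc0)) + 1L] <- hist[as.integer(rownames(acc0)) + 1L] + acc0[, 1]
  hist[as.integer(rownames(acc1)) + 1L] <- hist[as.integer(rownames(acc1)) + 1L] + acc1[, 1]
  cell_hist <- array(hist, dim = c(orientations, cells_y, cells_x))
  cell_hist <- aperm(cell_hist, c(2, 3, 1))    # cells_y x cells_x x bins
  blocks_y <- cells_y - block + 1L
  blocks_x <- cells_x - block + 1L
  if (blocks_y < 1L || blocks_x < 1L) stopf("image too small for one block")
  blk_len <- block * block * orientations
  vec <- numeric(blocks_y * blocks_x * blk_len)
  eps <- 1e-6
  k <- 0L
  for (bx in seq_len(blocks_x)) for (by in seq_len(blocks_y)) {
    v <- as.numeric(aperm(cell_hist[by:(by + block - 1L),
                                    bx:(bx + block - 1L), , drop = FALSE],
                          c(3, 1, 2)))         # bins fastest, cells y-then-x
    nrm <- sqrt(sum(v^2))
    if (nrm > eps) v <- v / nrm else v[] <- 0  # zero-energy guard
    vec[k + seq_len(blk_len)] <- v
    k <- k + blk_len
  }
  out <- list(vector = vec, cell_hist = cell_hist,
              params = list(orientations = orientations, cell = cell,
                            block = block, blocks = c(blocks_y, blocks_x)))
  if (render) out$rendering <- hog_render(cell_hist, cell)
  structure(out, class = "ir_hog")
}

# Per-cell oriented-line rendering of cell histograms: each orientation bin
# adds a line through the cell centre along the edge direction (gradient
# orientation + 90 degrees), weighted by the bin mass.
hog_render <- function(cell_hist, cell) {
  orientations <- dim(cell_hist)[3]
  masks <- lapply(seq_len(orientations), function(k) {
    ang <- ((k - 0.5) * 180 / orientations + 90) * pi / 180
    m <- matrix(0, cell, cell)
    cc <- (cell + 1) / 2
    for (t in seq(-cell / 2, cell / 2, by = 0.25)) {
      y <- round(cc + t * sin(ang)); x <- round(cc + t * cos(ang))
      if (y >= 1 && y <= cell && x >= 1 && x <= cell) m[y, x] <- 1
    }
    m
  })
  cy <- dim(cell_hist)[1]; cx <- dim(cell_hist)[2]
  img <- matrix(0, cy * cell, cx * cell)
  for (i in seq_len(cy)) for (j in seq_len(cx)) {
    acc <- matrix(0, cell, cell)
    for (k in seq_len(orientations)) {
      if (cell_hist[i, j, k] > 0) acc <- acc + cell_hist[i, j, k] * masks[[k]]
    }
    img[(i - 1L) * cell + seq_len(cell), (j - 1L) * cell + seq_len(cell)] <- acc
  }
  # raw magnitude-weighted rendering: the overall gradient energy is part of
  # the texture signal, so no per-image rescaling
  img
}

#' Local binary pattern code map
#'
#' Classic 8-neighbour LBP at radius 1: each pixel is compared with its 8
#' surrounding neighbours (the radius-1 circle snapped to the pixel grid,
#' which keeps the codes exactly invariant under any monotone intensity
#' transform); bit `k` is set when neighbour `k` is greater than or equal to
#' the centre, and the code is `sum(bit_k * 2^k)`. Neighbours are ordered
#' counter-clockwise starting from the right. Borders are handled by edge
#' replication. Off-grid circular sampling with bilinear interpolation is
#' available with `interpolate = TRUE` (codes are then only approximately
#' monotone-invariant).
#'
#' @param gray `H x W` matrix, at least `3 x 3`.
#' @param neighbors number of sampling points `P` (8 for the 256-code map).
#' @param radius circle radius `R` in pixels.
#' @param interpolate sample the exact circle with bilinear interpolation
#'   instead of snapping to the grid.
#' @return Object of class `ir_lbp`: list with integer `codes`
#'   (`H x W`, values in `[0, 2^P - 1]`) and `params`.
#' @export
lbp_map <- function(gray, neighbors = 8L, radius = 1L, interpolate = FALSE) {
  if (is.array(gray) && length(dim(gray)) == 3L) {
    stopf("lbp_map() expects a grayscale matrix; use rgb_to_gray()")
  }
  gray <- as.matrix(gray) * 1.0
  H <- nrow(gray); W <- ncol(gray)
  if (H < 3L || W < 3L) stopf("image must be at least 3x3")
  P <- as.integer(neighbors); R <- radius
  pad <- as.integer(ceiling(R))
  # edge-replicated padding
  ri <- c(rep(1L, pad), seq_len(H), rep(H, pad))
  ci <- c(rep(1L, pad), seq_len(W), rep(W, pad))
  gp <- gray[ri, ci, drop = FALSE]
  rows <- pad + seq_len(H); cols <- pad + seq_len(W)
  codes <- matrix(0L, H, W)
  for (k in 0:(P - 1L)) {
    ang <- 2 * pi * k / P
    dy <- R * sin(ang); dx <- R * cos(ang)
    if (!interpolate) {
      nb <- gp[rows + as.integer(round(dy)), cols + as.integer(round(dx)),
               drop = FALSE]
    } else {
      y0 <- floor(dy); x0 <- floor(dx)
      wy <- dy - y0; wx <- dx - x0
      nb <- gp[rows + y0, cols + x0, drop = FALSE] * (1 - wy) * (1 - wx) +
        gp[rows + y0 + 1L, cols + x0, drop = FALSE] * wy * (1 - wx) +
        gp[rows + y0, cols + x0 + 1L, drop = FALSE] * (1 - wy) * wx +
        gp[rows + y0 + 1L, cols + x0 + 1L, drop = FALSE] * wy * wx
    }
    codes <- codes + as.integer(nb >= gray) * 2L^k
  }
  structure(list(codes = codes,
                 params = list(neighbors = P, radius = R,
                               interpolate = interpolate)),
            class = "ir_lbp")
}

#' Aligned RGB / HOG / LBP image stacks
#'
#' Builds the three image representations consumed by the decision-level
#' fusion branches: the original RGB images, the HOG renderings and the LBP
#' code maps (both single-channel, on the 0-255 scale), all in identical
#' order with identical labels.
#'
#' @param dataset an `ir_dataset` of uniformly sized RGB images.
#' @return List with elements `rgb`, `hog`, `lbp` (each a list of arrays:
#'   `H x W x 3` for rgb, `H x W x 1` otherwise) and `labels`.
#' @export
feature_image_stack <- function(dataset) {
  stopifnot(inherits(dataset, "ir_dataset"))
  hogs <- vector("list", length(dataset$images))
  lbps <- vector("list", length(dataset$images))
  rgbs <- vector("list", length(dataset$images))
  for (i in seq_along(dataset$images)) {
    img <- dataset$images[[i]] * 1.0
    gray <- rgb_to_gray(img)
    h <- hog_descriptor(gray, render = TRUE)$rendering
    l <- lbp_map(gray)$codes * 1.0
    rgbs[[i]] <- img
    hogs[[i]] <- array(h, dim = c(dim(h), 1L))
    lbps[[i]] <- array(l, dim = c(dim(l), 1L))
  }
  list(rgb = rgbs, hog = hogs, lbp = lbps, labels = dataset$labels)
}
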