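# Independent naive implementations used as oracles: plain per-pixel loops,
# no code shared with the package internals.

naive_entropy <- function(values, levels = 256L) {
  counts <- rep(0, levels)
  for (v in as.integer(round(as.numeric(values)))) {
    counts[v + 1L] <- counts[v + 1L] + 1
  }
  p <- counts[counts > 0] / length(values)
  -sum(p * log2(p))
}

# ordered-pair co-occurrence counting by explicit loops; offset (dr, dc)
naive_glcm <- function(channel, dr = 0L, dc = 1L, levels = 256L,
                       normalize = TRUE) {
  H <- nrow(channel); W <- ncol(channel)
  G <- matrix(0, levels, levels)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      i <- channel[r, cc] + 1L
      j <- channel[r2, c2] + 1L
      G[i, j] <- G[i, j] + 1
    }
  }
  if (normalize) G <- G / sum(G)
  G
}

naive_contrast <- function(channel, dr = 0L, dc = 1L, levels = 256L) {
  G <- naive_glcm(channel, dr, dc, levels)
  total <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    total <- total + G[i, j] * (i - j)^2
  }
  total
}

# per-pixel HOG: centered differences with edge replication, unsigned bins
# with linear interpolation between bin centres at (k - 0.5) * 180 / n
naive_hog_vector <- function(gray, orientations = 9L, cell = 8L, block = 2L) {
  H <- nrow(gray); W <- ncol(gray)
  at <- function(r, cc) gray[min(max(r, 1L), H), min(max(cc, 1L), W)]
  cells_y <- H %/% cell; cells_x <- W %/% cell
  hist <- array(0, dim = c(cells_y, cells_x, orientations))
  bw <- 180 / orientations
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    gx <- at(r, cc + 1L) - at(r, cc - 1L)
    gy <- at(r + 1L, cc) - at(r - 1L, cc)
    mag <- sqrt(gx^2 + gy^2)
    th <- (atan2(gy, gx) * 180 / pi) %% 180
    t <- th / bw - 0.5
    b0 <- floor(t); w1 <- t - b0
    lo <- (b0 %% orientations) + 1L
    hi <- ((b0 + 1) %% orientations) + 1L
    cy <- ceiling(r / cell); cx <- ceiling(cc / cell)
    hist[cy, cx, lo] <- hist[cy, cx, lo] + mag * (1 - w1)
    hist[cy, cx, hi] <- hist[cy, cx, hi] + mag * w1
  }
  vec <- c()
  for (bx in seq_len(cells_x - block + 1L)) {
    for (by in seq_len(cells_y - block + 1L)) {
      v <- c()
      for (dx in 0:(block - 1L)) for (dy in 0:(block - 1L)) {
        v <- c(v, hist[by + dy, bx + dx, ])
      }
      # note: package order is (bins fastest, cells y then x); rebuild that
      v <- as.numeric(aperm(array(v, dim = c(orientations, block, block)),
                            c(1, 2, 3)))
      nrm <- sqrt(sum(v^2))
      v <- if (nrm > 1e-6) v / nrm else v * 0
      vec <- c(vec, v)
    }
  }
  vec
}

# per-pixel classic LBP: 8 grid neighbours (snapped radius-1 circle),
# edge replication, bit k set when neighbour k >= centre
naive_lbp <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  at <- function(r, cc) gray[min(max(r, 1L), H), min(max(cc, 1L), W)]
  offs <- lapply(0:7, function(k) {
    a <- 2 * pi * k / 8
    c(round(sin(a)), round(cos(a)))
  })
  codes <- matrix(0L, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    code <- 0L
    for (k in 0:7) {
      nb <- at(r + offs[[k + 1L]][1], cc + offs[[k + 1L]][2])
      if (nb >= gray[r, cc]) code <- code + 2L^k
    }
    codes[r, cc] <- code
  }
  codes
}

# direct Shapley value by definition (sum over subsets, factorial weights)
naive_shapley <- function(v_of, n) {
  # v_of(subset integer vector, possibly empty) -> value
  all_subsets <- function(items) {
    if (!length(items)) return(list(integer(0)))
    rest <- all_subsets(items[-1])
    c(rest, lapply(rest, function(s) c(items[1], s)))
  }
  phi <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (S in all_subsets(others)) {
      w <- factorial(length(S)) * factorial(n - length(S) - 1) / factorial(n)
      phi[i] <- phi[i] + w * (v_of(sort(c(S, i))) - v_of(S))
    }
  }
  phi
}

# fixture model for attribution tests: a smooth nonlinear function of patch
# means, so Shapley values are nontrivial but enumerable
patch_mean_model <- function(patches, weights, H, W, C = 1L) {
  force(patches); force(weights)
  function(X) {
    vapply(seq_len(nrow(X)), function(i) {
      img <- matrix(X[i, seq_len(H * W)], H, W)
      s <- sum(weights * vapply(patches, function(p) mean(img[p]), numeric(1)))
      1 / (1 + exp(-s))
    }, numeric(1))
  }
}

# small helper: tiny dataset restricted to a few well-separated classes with
# 0-based relabelling
make_small_dataset <- function(classes = c(0L, 3L, 6L), images_per_class = 12L,
                               image_size = c(32L, 32L), seed = 11L, ...) {
  cfg <- generator_config(image_size = image_size,
                          images_per_class = images_per_class,
                          seed = seed, ...)
  d <- generate_dataset(cfg)
  keep <- which(d$labels %in% classes)
  d <- subset_dataset(d, keep)
  d$labels <- match(d$labels, classes) - 1L
  d
}

constant_rgb <- function(H = 16L, W = 16L, value = c(100L, 50L, 25L)) {
  img <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- value[ch]
  img
}
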