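# Minimal convolutional-network engine.
#
# No deep-learning framework is used: convolution is im2col + BLAS matrix
# multiplication, gradients are exact backpropagation (checked against finite
# differences in the test suite), and optimization is Adam. Layers can be
# deterministic (point weights, optional L2 penalty) or Bayesian (independent
# Gaussian posterior per kernel weight, sampled by the reparameterization
# trick, with an analytic KL term against a standard-normal prior).
#
# Data layout: a batch is an N x (H*W*C) matrix, pixels flattened
# column-major (row fastest, then column, then channel). A convolution with
# 'same' padding keeps H and W; its output reshapes back to N x (H*W*F).

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}
softplus_inv <- function(y) {
  out <- y + log(-expm1(-y))
  out[y == 0] <- -Inf
  out
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- geometry caches -------------------------------------------------------

# im2col gather indices into a zero-padded (H+2p) x (W+2p) x C array for a
# k x k kernel with 'same' padding (stride 1).
conv_geometry <- function(H, W, C, k = 3L) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  HW <- H * W
  pos_h <- rep(seq_len(H), times = W)
  pos_w <- rep(seq_len(W), each = H)
  idx <- integer(HW * k * k * C)
  j <- 0L
  for (c in seq_len(C)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    ph <- pos_h + (ky - 1L)
    pw <- pos_w + (kx - 1L)
    idx[(j * HW + 1L):((j + 1L) * HW)] <- ph + Hp * (pw - 1L) + Hp * Wp * (c - 1L)
    j <- j + 1L
  }
  # scatter indices of the unpadded image inside the padded buffer
  ph <- rep(seq_len(H) + p, times = W)
  pw <- rep(seq_len(W) + p, each = H)
  inner <- as.integer(outer(ph + Hp * (pw - 1L), (seq_len(C) - 1L) * Hp * Wp, "+"))
  list(H = H, W = W, C = C, k = k, HW = HW, KC = k * k * C,
       padlen = Hp * Wp * C, idx = idx, inner = inner)
}

# gather im2col columns for a batch: X is N x (H*W*C); returns (N*HW) x KC
im2col <- function(X, geom) {
  N <- nrow(X)
  Xp <- matrix(0, N, geom$padlen)
  Xp[, geom$inner] <- X
  cols <- Xp[, geom$idx]
  dim(cols) <- c(N * geom$HW, geom$KC)
  cols
}

# 2x2 max-pool child indices for an (H, W, C) layout
pool_geometry <- function(H, W, C) {
  if (H %% 2L != 0L || W %% 2L != 0L) stopf("pooling needs even spatial dims")
  Ho <- H %/% 2L; Wo <- W %/% 2L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  base <- function(dy, dx) {
    pos <- (2L * oh - 1L + dy) + H * (2L * ow - 2L + dx)
    as.integer(outer(pos, (seq_len(C) - 1L) * H * W, "+"))
  }
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo,
       children = list(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L)))
}

# ---- layer constructors ----------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

new_conv_layer <- function(H, W, C, filters, k, l2, bayesian,
                           init_sigma_rel = 0.05) {
  geom <- conv_geometry(H, W, C, k)
  lay <- list(type = "conv", geom = geom, filters = filters, l2 = l2,
              bayesian = bayesian)
  W0 <- he_init(geom$KC, filters, geom$KC)
  if (bayesian) {
    # posterior sd starts at 5% of the He weight scale so an untrained
    # Bayesian network behaves like its deterministic twin
    sigma0 <- init_sigma_rel * sqrt(2 / geom$KC)
    lay$params <- list(W_mu = W0,
                       W_rho = matrix(softplus_inv(sigma0), geom$KC, filters),
                       b = rep(0, filters))
    # geometry of the gradient convolution (channels = filters)
    lay$geom_back <- conv_geometry(H, W, filters, k)
  } else {
    lay$params <- list(W = W0, b = rep(0, filters))
    lay$geom_back <- conv_geometry(H, W, filters, k)
  }
  lay
}

new_dense_layer <- function(d_in, d_out, activation, l2, bayesian,
                            init_sigma_rel = 0.05) {
  # logit-zero init: the classification layer starts at exactly uniform
  # predictions, so the initial loss is log(n_classes)
  W0 <- if (activation == "softmax") matrix(0, d_in, d_out) else
    he_init(d_in, d_out, d_in)
  lay <- list(type = "dense", d_in = d_in, d_out = d_out,
              activation = activation, l2 = l2, bayesian = bayesian)
  if (bayesian) {
    sigma0 <- init_sigma_rel * sqrt(2 / d_in)
    lay$params <- list(W_mu = W0,
                       W_rho = matrix(softplus_inv(sigma0), d_in, d_out),
                       b = rep(0, d_out))
  } else {
    lay$params <- list(W = W0, b = rep(0, d_out))
  }
  lay
}

# rotate a conv kernel matrix (KC x F) into the (K*K*F x C) matrix used by the
# gradient convolution
rotate_kernel <- function(Wm, k, C, F_) {
  Wa <- Wm
  dim(Wa) <- c(k, k, C, F_)
  Wa <- Wa[k:1, k:1, , , drop = FALSE]
  Wa <- aperm(Wa, c(1, 2, 4, 3))
  dim(Wa) <- c(k * k * F_, C)
  Wa
}

# effective kernel (sampled for Bayesian layers); returns list(W, eps)
layer_kernel <- function(lay, sample) {
  if (!lay$bayesian) return(list(W = lay$params$W, eps = NULL))
  sigma <- softplus(lay$params$W_rho)
  if (sample) {
    eps <- matrix(rnorm(length(sigma)), nrow(sigma), ncol(sigma))
    list(W = lay$params$W_mu + sigma * eps, eps = eps)
  } else {
    list(W = lay$params$W_mu, eps = NULL)
  }
}

# ---- model construction ----------------------------------------------------

build_network <- function(input_shape, n_classes, base_units, unit_multipliers,
                          kernel_size, l2, dropout, dense_units, bayesian,
                          seed) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  n_stages <- length(unit_multipliers)
  if (H < 2^n_stages || W < 2^n_stages ||
      H %% 2^n_stages != 0L || W %% 2^n_stages != 0L) {
    stopf("input %dx%d incompatible with %d pool-by-2 stages", H, W, n_stages)
  }
  with_seed(seed, {
    layers <- list()
    h <- H; w <- W; c <- C
    for (s in seq_len(n_stages)) {
      f <- base_units * unit_multipliers[s]
      layers[[length(layers) + 1L]] <-
        new_conv_layer(h, w, c, f, kernel_size, l2, bayesian)
      layers[[length(layers) + 1L]] <-
        c(list(type = "pool"), list(geom = pool_geometry(h, w, f)))
      layers[[length(layers) + 1L]] <- list(type = "dropout", rate = dropout)
      h <- h %/% 2L; w <- w %/% 2L; c <- f
    }
    d_flat <- h * w * c
    layers[[length(layers) + 1L]] <-
      new_dense_layer(d_flat, dense_units, "relu", l2, bayesian)
    layers[[length(layers) + 1L]] <- list(type = "dropout", rate = dropout)
    layers[[length(layers) + 1L]] <-
      new_dense_layer(dense_units, n_classes, "softmax", l2, bayesian)
    layers
  })
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(layers, X, training = FALSE, sample = FALSE,
                       keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  N <- nrow(X)
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      cols <- im2col(X, lay$geom)
      kw <- layer_kernel(lay, sample)
      Z <- cols %*% kw$W
      Z <- Z + rep(lay$params$b, each = nrow(Z))
      A <- Z
      A[A < 0] <- 0
      if (keep_cache) caches[[li]] <- list(cols = cols, Z = Z, eps = kw$eps,
                                           W = kw$W)
      dim(A) <- c(N, lay$geom$HW * lay$filters)
      X <- A
    } else if (lay$type == "pool") {
      g <- lay$geom
      ch <- g$children
      Y <- pmax(X[, ch[[1]], drop = FALSE], X[, ch[[2]], drop = FALSE],
                X[, ch[[3]], drop = FALSE], X[, ch[[4]], drop = FALSE])
      if (keep_cache) caches[[li]] <- list(X = X, Y = Y)
      X <- Y
    } else if (lay$type == "dropout") {
      if (training && lay$rate > 0) {
        mask <- matrix(runif(length(X)) >= lay$rate, nrow(X), ncol(X)) /
          (1 - lay$rate)
        if (keep_cache) caches[[li]] <- list(mask = mask)
        X <- X * mask
      }
    } else if (lay$type == "dense") {
      kw <- layer_kernel(lay, sample)
      Z <- X %*% kw$W
      Z <- Z + rep(lay$params$b, each = N)
      if (lay$activation == "relu") {
        A <- Z; A[A < 0] <- 0
      } else if (lay$activation == "softmax") {
        E <- exp(Z - apply(Z, 1, max))
        A <- E / rowSums(E)
      } else {
        A <- Z
      }
      if (keep_cache) caches[[li]] <- list(X = X, Z = Z, eps = kw$eps, W = kw$W)
      X <- A
    } else {
      stopf("unknown layer type '%s'", lay$type)
    }
  }
  list(out = X, caches = caches)
}

# Backward pass from softmax + (weighted) cross-entropy. Returns per-layer
# gradient lists aligned with `layers`. `dZ_top` is the gradient at the final
# pre-softmax logits.
nn_backward <- function(layers, caches, dZ_top, kl_weight = 0) {
  grads <- vector("list", length(layers))
  dA <- NULL
  dZ <- dZ_top
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    cache <- caches[[li]]
    if (lay$type == "dense") {
      if (is.null(dZ)) {
        dZ <- dA
        if (lay$activation == "relu") dZ <- dZ * (cache$Z > 0)
      }
      gW <- crossprod(cache$X, dZ)
      gb <- colSums(dZ)
      g <- kernel_grads(lay, cache, gW, kl_weight)
      g$b <- gb
      grads[[li]] <- g
      dA <- dZ %*% t(cache$W)
      dZ <- NULL
    } else if (lay$type == "dropout") {
      if (!is.null(cache)) dA <- dA * cache$mask
    } else if (lay$type == "pool") {
      g <- lay$geom
      dX <- matrix(0, nrow(dA), g$H * g$W * g$C)
      remaining <- matrix(TRUE, nrow(dA), ncol(dA))
      for (ch_idx in g$children) {
        m <- (cache$X[, ch_idx, drop = FALSE] == cache$Y) & remaining
        remaining <- remaining & !m
        dX[, ch_idx] <- dX[, ch_idx] + dA * m
      }
      dA <- dX
    } else if (lay$type == "conv") {
      N <- nrow(dA)
      dZc <- dA
      dim(dZc) <- c(N * lay$geom$HW, lay$filters)
      dZc <- dZc * (cache$Z > 0)
      gW <- crossprod(cache$cols, dZc)
      gb <- colSums(dZc)
      g <- kernel_grads(lay, cache, gW, kl_weight)
      g$b <- gb
      grads[[li]] <- g
      if (li == 1L) break  # no gradient needed below the input layer
      # gradient w.r.t. the layer input: convolve dZ with the rotated kernel
      dZimg <- dZc
      dim(dZimg) <- c(N, lay$geom$HW * lay$filters)
      cols_b <- im2col(dZimg, lay$geom_back)
      Wrot <- rotate_kernel(cache$W, lay$geom$k, lay$geom$C, lay$filters)
      dX <- cols_b %*% Wrot
      dim(dX) <- c(N, lay$geom$HW * lay$geom$C)
      dA <- dX
    }
  }
  grads
}

# kernel gradients for one layer given the gradient w.r.t. the effective
# kernel, including L2 (deterministic) or scaled KL (Bayesian) terms
kernel_grads <- function(lay, cache, gW, kl_weight) {
  if (!lay$bayesian) {
    if (lay$l2 > 0) gW <- gW + 2 * lay$l2 * lay$params$W
    return(list(W = gW))
  }
  sig_grad <- sigmoid(lay$params$W_rho)
  sigma <- softplus(lay$params$W_rho)
  g_mu <- gW
  g_rho <- if (is.null(cache$eps)) gW * 0 else gW * cache$eps * sig_grad
  if (kl_weight > 0) {
    g_mu <- g_mu + kl_weight * lay$params$W_mu
    g_rho <- g_rho + kl_weight * (sigma - 1 / sigma) * sig_grad
  }
  list(W_mu = g_mu, W_rho = g_rho)
}

# total KL divergence of the Gaussian posteriors from the N(0,1) prior
network_kl <- function(layers) {
  kl <- 0
  for (lay in layers) {
    if (isTRUE(lay$bayesian)) {
      sigma <- softplus(lay$params$W_rho)
      mu <- lay$params$W_mu
      kl <- kl + sum(-log(sigma) + (sigma^2 + mu^2) / 2 - 0.5)
    }
  }
  kl
}

# sum of the deterministic L2 penalties
network_l2 <- function(layers) {
  pen <- 0
  for (lay in layers) {
    if (lay$type %in% c("conv", "dense") && !lay$bayesian && lay$l2 > 0) {
      pen <- pen + lay$l2 * sum(lay$params$W^2)
    }
  }
  pen
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(lay) {
    if (is.null(lay$params)) return(NULL)
    lapply(lay$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[li]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[li]]$params[[nm]] <- layers[[li]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
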