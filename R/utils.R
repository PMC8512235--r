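# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif quantile median sd predict
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Deterministic 31-bit seed derived from a base seed and a stream name,
# so pipeline stages get independent but reproducible RNG streams.
derive_seed <- function(seed, stream) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_rgb <- function(image, what = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stopf("%s must be an H x W x 3 array (got %s)", what,
          paste(dim(image), collapse = " x "))
  }
  invisible(image)
}

# Clip to [0, 255] and round to 8-bit integers.
as_uint8 <- function(x) {
  x <- round(pmin(pmax(x, 0), 255))
  storage.mode(x) <- "integer"
  x
}

# Flatten a list of equally sized H x W x C arrays into an N x (H*W*C) matrix
# (row = image, column-major pixel order: h fastest, then w, then channel).
images_to_matrix <- function(images) {
  d <- dim(images[[1]])
  if (is.null(d)) d <- c(dim(as.matrix(images[[1]])), 1L)
  n <- length(images)
  out <- matrix(0, n, prod(d))
  for (i in seq_len(n)) out[i, ] <- as.numeric(images[[i]])
  attr(out, "image_dim") <- d
  out
}

matrix_to_images <- function(X, image_dim) {
  lapply(seq_len(nrow(X)), function(i) array(X[i, ], dim = image_dim))
}

# FNV-1a style hash of a config for run stamping (hex string).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648 - 2^31 * (h %% 2147483648 >= 2^31)), code)
    h <- (as.double(h %% 2^32 + (h < 0) * 2^32) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
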