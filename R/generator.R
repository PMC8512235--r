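#' Configuration for the synthetic tissue-image generator
#'
#' The real intestinal image dataset is not publicly deposited, so the package
#' ships a seeded generator whose class-dependent statistics reproduce the
#' qualitative findings of the study: Shannon entropy and red-channel GLCM
#' contrast increase with hours of ischemia, are partially reversed by
#' reperfusion, and the reversal is stronger after 3 h of ischemia than after
#' 4 h. Images are a pink-red base field plus a low-frequency mottle texture,
#' curvilinear dark vessels, and pixel noise.
#'
#' @param image_size integer `(height, width)` in pixels, each at least 32.
#' @param images_per_class images generated per class.
#' @param vessel_count_range integer `(min, max)` vessels per image.
#' @param mottle_amplitude_control mottle amplitude (intensity units) for the
#'   control class.
#' @param mottle_gain_per_ischemia_hour relative amplitude gain per hour of
#'   ischemia: amplitude is `control * (1 + gain * ischemia_hours)`.
#' @param reperfusion_recovery_3h,reperfusion_recovery_4h fraction of the
#'   ischemic texture/colour change reversed by full reperfusion after 3 h and
#'   4 h of ischemia; must satisfy `recovery_3h > recovery_4h`.
#' @param red_shift_per_hour drop of the mean red channel (intensity units)
#'   per hour of ischemia, reversed like the mottle amplitude.
#' @param green_shift_per_hour drop of the mean green channel (intensity
#'   units) per hour of total elapsed experiment time (`ischemia +
#'   reperfusion`), emulating the progressive serosal change of exposed
#'   tissue over the 8 h protocol; not reversed by reperfusion.
#' @param noise_sd i.i.d. Gaussian pixel noise standard deviation.
#' @param control_multiplier integer inflation factor for the control class
#'   (`> 1` emulates the acquisition imbalance where the control contributes
#'   more images than any injury class).
#' @param n_subjects number of simulated animals cycled through the images.
#' @param seed integer master seed; every image seed derives from it.
#' @return An object of class `ir_generator_config` (a validated list).
#' @seealso [generate_dataset()], [render_tissue_image()]
#' @export
generator_config <- function(image_size = c(64L, 64L),
                             images_per_class = 40L,
                             vessel_count_range = c(3L, 6L),
                             mottle_amplitude_control = 4,
                             mottle_gain_per_ischemia_hour = 0.35,
                             reperfusion_recovery_3h = 0.5,
                             reperfusion_recovery_4h = 0.25,
                             red_shift_per_hour = 6,
                             green_shift_per_hour = 3,
                             noise_sd = 2,
                             control_multiplier = 1L,
                             n_subjects = 10L,
                             seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size),
    images_per_class = as.integer(images_per_class),
    vessel_count_range = as.integer(vessel_count_range),
    mottle_amplitude_control = mottle_amplitude_control,
    mottle_gain_per_ischemia_hour = mottle_gain_per_ischemia_hour,
    reperfusion_recovery_3h = reperfusion_recovery_3h,
    reperfusion_recovery_4h = reperfusion_recovery_4h,
    red_shift_per_hour = red_shift_per_hour,
    green_shift_per_hour = green_shift_per_hour,
    noise_sd = noise_sd,
    control_multiplier = as.integer(control_multiplier),
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed)
  )
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 32L)) {
    stopf("image_size must be (height, width) with both >= 32")
  }
  if (cfg$images_per_class < 1L) stopf("images_per_class must be >= 1")
  if (length(cfg$vessel_count_range) != 2L || any(cfg$vessel_count_range < 0L) ||
      cfg$vessel_count_range[1] > cfg$vessel_count_range[2]) {
    stopf("vessel_count_range must be a non-negative (min, max) pair")
  }
  amps <- c(cfg$mottle_amplitude_control, cfg$mottle_gain_per_ischemia_hour,
            cfg$red_shift_per_hour, cfg$green_shift_per_hour, cfg$noise_sd)
  if (any(amps < 0)) stopf("amplitudes must be non-negative")
  rec <- c(cfg$reperfusion_recovery_3h, cfg$reperfusion_recovery_4h)
  if (any(rec < 0 | rec > 1)) stopf("recovery fractions must lie in [0, 1]")
  if (!(cfg$reperfusion_recovery_3h > cfg$reperfusion_recovery_4h)) {
    stopf("reperfusion_recovery_3h must exceed reperfusion_recovery_4h")
  }
  if (cfg$control_multiplier < 1L) stopf("control_multiplier must be >= 1")
  structure(cfg, class = "ir_generator_config")
}

# Reversal factor in [0,1]: 1 during ischemia, shrinking with reperfusion.
# For reperfusion classes the injury signal is scaled by
# 1 - recovery * min(r, i) / i.
injury_factor <- function(label, config) {
  i <- label$ischemia_hours
  r <- label$reperfusion_hours
  if (i == 0L) return(0)
  f <- 1
  if (r > 0L) {
    rec <- if (i <= 3L) config$reperfusion_recovery_3h else config$reperfusion_recovery_4h
    f <- 1 - rec * min(r, i) / i
  }
  f
}

# Low-frequency random field: coarse Gaussian grid bilinearly upsampled.
mottle_field <- function(H, W, cells = 8L) {
  g <- matrix(rnorm((cells + 1L)^2), cells + 1L, cells + 1L)
  bilinear_resize(g, c(H, W))
}

# Bilinear resampling of a matrix to a target size (align-corners convention).
bilinear_resize <- function(m, out_size) {
  H <- nrow(m); W <- ncol(m)
  oh <- out_size[1]; ow <- out_size[2]
  ys <- if (oh == 1L) rep(1, oh) else seq(1, H, length.out = oh)
  xs <- if (ow == 1L) rep(1, ow) else seq(1, W, length.out = ow)
  y0 <- pmin(floor(ys), H - 1L); y1 <- y0 + 1L; wy <- ys - y0
  x0 <- pmin(floor(xs), W - 1L); x1 <- x0 + 1L; wx <- xs - x0
  if (H == 1L) { y0 <- y1 <- rep(1L, oh); wy <- rep(0, oh) }
  if (W == 1L) { x0 <- x1 <- rep(1L, ow); wx <- rep(0, ow) }
  a <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
       m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
       m[y0, x1, drop = FALSE] * outer(1 - wy, wx) +
       m[y1, x1, drop = FALSE] * outer(wy, wx)
  a
}

# Stamp dark curvilinear vessels: random-walk polylines with a Gaussian
# cross-section, subtracted from all channels (strongest in red).
draw_vessels <- function(canvas, n_vessels, depth = 35, sigma = 1.2) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  if (n_vessels < 1L) return(canvas)
  r <- 3L
  off <- -r:r
  blob <- exp(-(outer(off^2, off^2, "+")) / (2 * sigma^2))
  chan_scale <- c(1, 0.65, 0.55)
  for (v in seq_len(n_vessels)) {
    y <- runif(1, 1, H); x <- runif(1, 1, W)
    ang <- runif(1, 0, 2 * pi)
    steps <- as.integer(round(1.5 * max(H, W)))
    d <- depth * runif(1, 0.7, 1.3)
    for (s in seq_len(steps)) {
      ang <- ang + rnorm(1, 0, 0.18)
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < 1 || y > H || x < 1 || x > W) break
      yi <- as.integer(round(y)); xi <- as.integer(round(x))
      ys <- pmax(1L, pmin(H, yi + off)); xs <- pmax(1L, pmin(W, xi + off))
      sel_y <- which(yi + off >= 1L & yi + off <= H)
      sel_x <- which(xi + off >= 1L & xi + off <= W)
      if (!length(sel_y) || !length(sel_x)) next
      b <- blob[sel_y, sel_x, drop = FALSE] * d / steps * 14
      for (ch in 1:3) {
        canvas[yi + off[sel_y], xi + off[sel_x], ch] <-
          canvas[yi + off[sel_y], xi + off[sel_x], ch] - b * chan_scale[ch]
      }
    }
  }
  canvas
}

#' Render one synthetic intestinal-surface image
#'
#' Draws a deterministic 8-bit RGB image for a given class. The mottle
#' amplitude is `mottle_amplitude_control * (1 + gain * ischemia_hours)`,
#' scaled for reperfusion classes by `1 - recovery * min(r, i) / i`, and the
#' mean red level decreases with ischemia hours and partially recovers with
#' reperfusion in the same way.
#'
#' @param label an [class_label()] object or an integer index in `[0, 17]`.
#' @param config an [generator_config()] object.
#' @param seed integer seed for this image; the same `(label, config, seed)`
#'   triple always yields a bit-identical image.
#' @return An `H x W x 3` integer array with values in `[0, 255]`.
#' @export
render_tissue_image <- function(label, config = generator_config(), seed = 1L) {
  if (!inherits(label, "ir_label")) label <- class_label(label)
  stopifnot(inherits(config, "ir_generator_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  f <- injury_factor(label, config)
  i <- label$ischemia_hours
  amp <- config$mottle_amplitude_control *
    (1 + config$mottle_gain_per_ischemia_hour * i) * f
  if (i == 0L) amp <- config$mottle_amplitude_control
  red_shift <- config$red_shift_per_hour * i * f
  elapsed <- i + label$reperfusion_hours
  base <- c(190 - red_shift, 120 - config$green_shift_per_hour * elapsed, 110)
  chan_scale <- c(1, 0.6, 0.5)
  with_seed(seed, {
    img <- array(0, dim = c(H, W, 3L))
    field <- mottle_field(H, W)
    for (ch in 1:3) img[, , ch] <- base[ch] + amp * chan_scale[ch] * field
    n_vessels <- if (config$vessel_count_range[2] == 0L) 0L else
      sample(config$vessel_count_range[1]:config$vessel_count_range[2], 1L)
    img <- draw_vessels(img, n_vessels)
    if (config$noise_sd > 0) {
      img <- img + rnorm(H * W * 3L, 0, config$noise_sd)
    }
    as_uint8(img)
  })
}

#' Generate a labelled synthetic image dataset
#'
#' Produces `images_per_class` images for each of the 18 ischemia-reperfusion
#' classes (the control class is inflated by `control_multiplier`, emulating
#' the acquisition protocol in which the control segment is imaged over the
#' whole 8 h course). Every image seed derives deterministically from the
#' config seed, so identical configs yield identical datasets.
#'
#' @param config an [generator_config()] object.
#' @return An object of class `ir_dataset`: list with `images` (list of
#'   `H x W x 3` integer arrays), `labels` (integer vector of class indices)
#'   and `metadata` (one data.frame row per image: `class_index`, `phase`,
#'   `ischemia_hours`, `reperfusion_hours`, `hour`, `subject_id`,
#'   `segment_id`, `seed`).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "ir_generator_config"))
  counts <- rep(config$images_per_class, 18L)
  counts[1] <- counts[1] * config$control_multiplier
  images <- vector("list", sum(counts))
  labels <- integer(sum(counts))
  meta <- vector("list", sum(counts))
  segment_of <- function(lab) {
    if (lab$phase == "control") "A"
    else if (lab$phase == "ischemia") "B"
    else if (lab$ischemia_hours == 3L) "C" else "D"
  }
  k <- 0L
  for (cls in 0:17) {
    lab <- class_label(cls)
    for (j in seq_len(counts[cls + 1L])) {
      k <- k + 1L
      img_seed <- derive_seed(config$seed, sprintf("img_%02d_%05d", cls, j))
      images[[k]] <- render_tissue_image(lab, config, seed = img_seed)
      labels[k] <- cls
      meta[[k]] <- data.frame(
        class_index = cls,
        phase = lab$phase,
        ischemia_hours = lab$ischemia_hours,
        reperfusion_hours = lab$reperfusion_hours,
        hour = lab$ischemia_hours + lab$reperfusion_hours,
        subject_id = ((j - 1L) %% config$n_subjects) + 1L,
        segment_id = segment_of(lab),
        seed = img_seed,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(images = images, labels = labels,
                 metadata = do.call(rbind, meta), config = config),
            class = "ir_dataset")
}

#' @export
print.ir_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<ir_dataset: %d images (%dx%dx%d), %d classes>\n",
              length(x$images), d[1], d[2], d[3],
              length(unique(x$labels))))
  invisible(x)
}

#' Subset an image dataset by position
#'
#' @param dataset an `ir_dataset`.
#' @param idx integer positions to keep.
#' @return An `ir_dataset` with the selected images, labels and metadata.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(images = dataset$images[idx],
                 labels = dataset$labels[idx],
                 metadata = dataset$metadata[idx, , drop = FALSE],
                 config = dataset$config),
            class = "ir_dataset")
}

#' Write / read a dataset as PNG files plus a CSV manifest
#'
#' `write_dataset()` writes one lossless 8-bit PNG per image and a manifest
#' CSV with columns `filename`, `class_index`, `phase`, `ischemia_hours`,
#' `reperfusion_hours`, `subject_id`, `segment_id`, `seed`;
#' `read_dataset()` reconstructs the dataset bit-exactly from the manifest.
#'
#' @param dataset an `ir_dataset`.
#' @param directory output directory (created if missing).
#' @return `write_dataset()` returns the manifest path invisibly;
#'   `read_dataset()` returns an `ir_dataset`.
#' @export
write_dataset <- function(dataset, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L) {
    stopf("cannot write dataset: directory '%s' is not writable", directory)
  }
  n <- length(dataset$images)
  fn <- sprintf("class%02d_%05d.png", dataset$labels, seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(aperm(array(dataset$images[[i]] / 255,
                              dim = dim(dataset$images[[i]])), c(1, 2, 3)),
                  target = file.path(directory, fn[i]))
  }
  manifest <- cbind(data.frame(filename = fn, stringsAsFactors = FALSE),
                    dataset$metadata)
  path <- file.path(directory, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param manifest path to a manifest CSV (or a directory containing
#'   `manifest.csv`).
#' @export
read_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stopf("manifest '%s' not found", manifest)
  dirn <- dirname(manifest)
  m <- read.csv(manifest, stringsAsFactors = FALSE)
  images <- lapply(m$filename, function(f) {
    a <- png::readPNG(file.path(dirn, f))
    as_uint8(a * 255)
  })
  structure(list(images = images, labels = as.integer(m$class_index),
                 metadata = m[, setdiff(names(m), "filename"), drop = FALSE],
                 config = NULL),
            class = "ir_dataset")
}
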