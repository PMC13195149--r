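# ---------------------------------------------------------------------------
# Dataset pipeline: 7:2:1 splitting and the offline augmentation protocol
# (rotation -> noise injection -> brightness), with label-aware geometry.
# ---------------------------------------------------------------------------

#' Offline augmentation configuration
#'
#' Defaults reproduce the study protocol: rotation in \[-15, 15\] degrees,
#' Gaussian noise sigma in \[5, 15\] (8-bit intensity units) alternating 1:1
#' with salt-and-pepper noise of density \[0.002, 0.01\], brightness factor
#' in \[0.7, 1.3\], and two augmented samples per original image.
#'
#' @param rotation_range degrees, length-2.
#' @param gaussian_sigma_range 8-bit intensity units, length-2.
#' @param sp_density_range pixel fractions, length-2.
#' @param brightness_range multiplicative factors, length-2.
#' @param n_aug_per_image augmented copies per original (>= 0).
#' @param seed RNG seed for parameter draws.
#' @return list of class `wb_aug_config`.
#' @export
augmentation_config <- function(rotation_range = c(-15, 15),
                                gaussian_sigma_range = c(5, 15),
                                sp_density_range = c(0.002, 0.01),
                                brightness_range = c(0.7, 1.3),
                                n_aug_per_image = 2, seed = 0) {
  rngs <- list(rotation_range, gaussian_sigma_range, sp_density_range,
               brightness_range)
  if (any(vapply(rngs, function(r) length(r) != 2 || r[1] > r[2], TRUE)))
    stop("invalid config: ranges must be ordered length-2 vectors")
  if (n_aug_per_image < 0)
    stop("invalid config: n_aug_per_image must be >= 0")
  structure(list(rotation_range = rotation_range,
                 gaussian_sigma_range = gaussian_sigma_range,
                 sp_density_range = sp_density_range,
                 brightness_range = brightness_range,
                 n_aug_per_image = n_aug_per_image, seed = seed),
            class = "wb_aug_config")
}

#' Split a dataset 7:2:1
#'
#' Subset sizes are `round(n * ratio)` for validation and test, with the
#' remainder assigned to training; the permutation is deterministic in
#' `seed`.
#'
#' @param samples list (or vector) of samples.
#' @param ratios train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, ratios = c(0.7, 0.2, 0.1), seed = 0) {
  n <- length(samples)
  if (n == 0) stop("invalid input: empty dataset")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("invalid config: ratios must sum to 1")
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  if (n_train < 0) stop("invalid config: ratios leave no training data")
  perm <- with_seed(seed, sample.int(n))
  list(train = samples[perm[seq_len(n_train)]],
       val = samples[perm[n_train + seq_len(n_val)]],
       test = samples[perm[n_train + n_val + seq_len(n_test)]])
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Rotate an image and its boxes about the image centre
#'
#' The canvas size is preserved and uncovered pixels are zero-filled.  Each
#' box is mapped by rotating its four corners and taking the axis-aligned
#' enclosing rectangle, clipped to the image; boxes whose clipped area drops
#' below 20% of the original are removed.
#'
#' @param sample a `wb_sample`.
#' @param angle degrees, `|angle| <= 45`; positive is counter-clockwise in
#'   image coordinates.
#' @return The rotated `wb_sample`.
#' @export
rotate_with_boxes <- function(sample, angle) {
  if (abs(angle) > 45) stop("invalid config: |angle| must be <= 45")
  img <- sample$image
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (angle == 0) return(sample)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse mapping: for each destination pixel sample the source pixel
  dst <- expand.grid(r = seq_len(h), c = seq_len(w))
  dy <- dst$r - cy; dx <- dst$c - cx
  sx <- cos(th) * dx + sin(th) * dy + cx
  sy <- -sin(th) * dx + cos(th) * dy + cy
  sr <- round(sy); sc <- round(sx)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out <- array(0L, d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    dest <- integer(h * w)
    dest[ok] <- plane[cbind(sr[ok], sc[ok])]
    out[, , ch] <- dest
  }
  # forward-map the box corners about the continuous-coordinate centre
  bcx <- w / 2
  bcy <- h / 2
  labels <- sample$labels
  if (nrow(labels) > 0) {
    px <- labels_to_pixel_boxes(labels, h, w)
    keep <- logical(nrow(px))
    newb <- matrix(0, nrow(px), 4)
    for (i in seq_len(nrow(px))) {
      xs <- c(px$x1[i], px$x2[i], px$x1[i], px$x2[i]) - bcx
      ys <- c(px$y1[i], px$y1[i], px$y2[i], px$y2[i]) - bcy
      rx <- cos(th) * xs - sin(th) * ys + bcx
      ry <- sin(th) * xs + cos(th) * ys + bcy
      x1 <- max(0, min(rx)); x2 <- min(w, max(rx))
      y1 <- max(0, min(ry)); y2 <- min(h, max(ry))
      area0 <- (px$x2[i] - px$x1[i]) * (px$y2[i] - px$y1[i])
      area1 <- max(0, x2 - x1) * max(0, y2 - y1)
      if (area1 >= 0.2 * area0 && area1 > 0) {
        keep[i] <- TRUE
        newb[i, ] <- c(x1, y1, x2, y2)
      }
    }
    labels <- if (any(keep))
      pixel_boxes_to_labels(newb[keep, , drop = FALSE], h, w,
                            labels$class_id[keep])
    else empty_labels()
  }
  image_sample(out, labels, sample$id)
}

#' Additive Gaussian pixel noise
#'
#' i.i.d. normal(0, sigma^2) noise per pixel and channel on the 0..255
#' intensity scale, clipped to `[0, 255]`.
#'
#' @param image `H x W x 3` 0..255 array.
#' @param sigma standard deviation in intensity units.
#' @return Noised image.
#' @export
add_gaussian_noise <- function(image, sigma) {
  if (sigma < 0) stop("invalid config: sigma must be >= 0")
  out <- clip255(round(image + stats::rnorm(length(image), 0, sigma)))
  storage.mode(out) <- "integer"
  array(out, dim(image))
}

#' Salt-and-pepper noise
#'
#' A fraction `density` of pixel positions is set to 0 or 255 with equal
#' probability (all channels of a position together).
#'
#' @param image `H x W x 3` 0..255 array.
#' @param density fraction of affected pixels in `[0, 1]`.
#' @return Noised image.
#' @export
add_salt_pepper <- function(image, density) {
  if (density < 0 || density > 1)
    stop("invalid config: density must be in [0,1]")
  d <- dim(image)
  npix <- d[1] * d[2]
  hit <- which(stats::runif(npix) < density)
  out <- image
  if (length(hit) > 0) {
    val <- ifelse(stats::runif(length(hit)) < 0.5, 0L, 255L)
    for (ch in seq_len(d[3])) {
      plane <- out[, , ch]
      plane[hit] <- val
      out[, , ch] <- plane
    }
  }
  out
}

#' Multiplicative brightness adjustment
#'
#' @param image `H x W x 3` 0..255 array.
#' @param factor multiplicative factor (> 0), result clipped to `[0, 255]`.
#' @return Adjusted image.
#' @export
adjust_brightness <- function(image, factor) {
  if (factor <= 0) stop("invalid config: factor must be > 0")
  out <- clip255(round(image * factor))
  storage.mode(out) <- "integer"
  array(out, dim(image))
}

#' Offline augmentation of a training split
#'
#' For every original sample, `n_aug_per_image` augmented copies are produced
#' by the sequential pipeline rotation -> noise injection -> brightness, with
#' parameters drawn uniformly from the configured ranges.  The noise type
#' alternates deterministically between Gaussian and salt-and-pepper so the
#' 1:1 ratio holds exactly.  Labels follow the geometric step.
#'
#' @param train list of `wb_sample`.
#' @param cfg an [augmentation_config()].
#' @return list of originals followed by augmented samples (ids suffixed
#'   `_aug1 ... _augk`).
#' @export
augment_training_set <- function(train, cfg = augmentation_config()) {
  stopifnot(inherits(cfg, "wb_aug_config"))
  if (length(train) == 0) return(list())
  out <- train
  counter <- 0L
  with_seed(cfg$seed, {
    for (s in train) {
      for (k in seq_len(cfg$n_aug_per_image)) {
        ang <- stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
        a <- rotate_with_boxes(s, ang)
        img <- a$image
        if (counter %% 2L == 0L) {
          sg <- stats::runif(1, cfg$gaussian_sigma_range[1],
                             cfg$gaussian_sigma_range[2])
          img <- add_gaussian_noise(img, sg)
          kind <- "gauss"
        } else {
          dn <- stats::runif(1, cfg$sp_density_range[1],
                             cfg$sp_density_range[2])
          img <- add_salt_pepper(img, dn)
          kind <- "sp"
        }
        counter <- counter + 1L
        bf <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
        img <- adjust_brightness(img, bf)
        ns <- image_sample(img, a$labels, paste0(s$id, "_aug", k))
        attr(ns, "noise_kind") <- kind
        out[[length(out) + 1]] <- ns
      }
    }
  })
  out
}

#' Bounding-box size statistics
#'
#' @param labels data frame of YOLO labels pooled over a dataset.
#' @param small_area area threshold defining a "small" target (fraction of
#'   image area).
#' @return list with means, quantiles of normalised width/height/area, the
#'   small-box fraction, and a `scatter` data frame of (w, h) pairs.
#' @export
bbox_stats <- function(labels, small_area = 0.10) {
  if (nrow(labels) == 0) stop("invalid input: no labels")
  area <- labels$w * labels$h
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  list(n = nrow(labels),
       mean_w = mean(labels$w), mean_h = mean(labels$h),
       mean_area = mean(area),
       q_w = stats::quantile(labels$w, qs, names = TRUE),
       q_h = stats::quantile(labels$h, qs, names = TRUE),
       q_area = stats::quantile(area, qs, names = TRUE),
       small_fraction = mean(area < small_area),
       scatter = data.frame(w = labels$w, h = labels$h))
}
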