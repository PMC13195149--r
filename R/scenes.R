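# ---------------------------------------------------------------------------
# Synthetic wetland scenes: textured backgrounds (water ripple, vegetation
# streaks, sunset gradients) with small dark elliptical targets and exact
# axis-aligned ground-truth boxes.  The generator is its own ground truth:
# each label is the bounding box of the rendered target support.
# ---------------------------------------------------------------------------

#' Synthetic scene configuration
#'
#' Defaults emulate the study conditions: square images, 3 to 20 targets per
#' scene, every target below 10% of image area (typically far below),
#' cluttered low-frequency backgrounds, occasional occlusion by vegetation
#' streaks, and dark low-contrast targets.
#'
#' @param image_size square side in pixels.
#' @param n_birds_range inclusive count interval.
#' @param bird_area_fraction_range target area as a fraction of image area;
#'   the upper bound must not exceed 0.10.
#' @param background one of `"water_ripple"`, `"vegetation"`,
#'   `"sunset_gradient"`, `"mixed"`.
#' @param occlusion_prob probability that a streak is drawn over a target.
#' @param contrast_delta_range additive intensity offset of targets
#'   (negative: darker than background; small magnitude: camouflage).
#' @param seed base RNG seed.
#' @return list of class `wb_scene_config`.
#' @export
scene_config <- function(image_size = 640, n_birds_range = c(3, 20),
                         bird_area_fraction_range = c(0.0004, 0.01),
                         background = "mixed", occlusion_prob = 0.3,
                         contrast_delta_range = c(-90, -25), seed = 0) {
  if (bird_area_fraction_range[2] > 0.10)
    stop("invalid config: bird area fraction must stay below 0.10")
  if (n_birds_range[1] > n_birds_range[2] ||
      bird_area_fraction_range[1] > bird_area_fraction_range[2] ||
      contrast_delta_range[1] > contrast_delta_range[2])
    stop("invalid config: intervals must be ordered")
  if (!background %in% c("water_ripple", "vegetation", "sunset_gradient",
                         "mixed"))
    stop("invalid config: unknown background type")
  structure(list(image_size = image_size, n_birds_range = n_birds_range,
                 bird_area_fraction_range = bird_area_fraction_range,
                 background = background, occlusion_prob = occlusion_prob,
                 contrast_delta_range = contrast_delta_range, seed = seed),
            class = "wb_scene_config")
}

# smooth 1-D random curve: a few sinusoids with random phase/frequency
rand_curve <- function(n, n_waves = 3, amp = 1) {
  x <- seq(0, 1, length.out = n)
  y <- numeric(n)
  for (i in seq_len(n_waves))
    y <- y + stats::runif(1, 0.3, 1) *
      sin(2 * pi * stats::runif(1, 1, 6) * x + stats::runif(1, 0, 2 * pi))
  amp * y / n_waves
}

synth_background <- function(kind, s) {
  if (kind == "mixed")
    kind <- sample(c("water_ripple", "vegetation", "sunset_gradient"), 1)
  base <- stats::runif(1, 90, 160)
  rowc <- rand_curve(s, 4)
  colc <- rand_curve(s, 4)
  field <- switch(kind,
    water_ripple = {
      # horizontal ripple bands modulated by a slow vertical drift
      outer(rand_curve(s, 5, 14), rep(1, s)) +
        outer(rep(1, s), rand_curve(s, 6, 10)) +
        10 * outer(rowc, colc)
    },
    vegetation = {
      # vertical streaks: strong column structure, weak row structure
      outer(rep(1, s), rand_curve(s, 8, 22)) +
        outer(rand_curve(s, 3, 6), rep(1, s)) +
        8 * outer(rowc, colc)
    },
    sunset_gradient = {
      grad <- seq(35, -35, length.out = s)
      outer(grad, rep(1, s)) + outer(rep(1, s), rand_curve(s, 4, 8))
    })
  g <- base + field + matrix(stats::rnorm(s * s, 0, 6), s, s)
  tint <- switch(kind,
                 water_ripple = c(-8, 2, 12),
                 vegetation = c(-6, 10, -8),
                 sunset_gradient = c(18, 4, -12))
  img <- array(0, c(s, s, 3))
  for (ch in 1:3)
    img[, , ch] <- g + tint[ch] + matrix(stats::rnorm(s * s, 0, 2), s, s)
  list(img = img, kind = kind)
}

# draw a filled rotated ellipse (body) plus a head blob; returns the pixel
# mask rows/cols actually drawn
draw_bird <- function(img, cx, cy, rx, ry, phi, delta) {
  s <- dim(img)[1]
  ext <- ceiling(max(rx, ry) * 1.6) + 1
  rr <- max(1, floor(cy - ext)):min(s, ceiling(cy + ext))
  cc <- max(1, floor(cx - ext)):min(s, ceiling(cx + ext))
  grid <- expand.grid(r = rr, c = cc)
  dx <- grid$c - cx
  dy <- grid$r - cy
  u <- (cos(phi) * dx + sin(phi) * dy) / rx
  v <- (-sin(phi) * dx + cos(phi) * dy) / ry
  body <- u^2 + v^2 <= 1
  # head: smaller blob at the front end of the major axis
  hx <- cx + 1.15 * rx * cos(phi)
  hy <- cy + 1.15 * rx * sin(phi)
  hr <- max(1, 0.45 * ry)
  head <- ((grid$c - hx)^2 + (grid$r - hy)^2) <= hr^2
  mask <- body | head
  if (!any(mask)) return(NULL)
  pr <- grid$r[mask]
  pc <- grid$c[mask]
  for (ch in 1:3)
    img[cbind(pr, pc, ch)] <- img[cbind(pr, pc, ch)] + delta +
      stats::rnorm(1, 0, 3)
  list(img = img, rows = pr, cols = pc)
}

draw_streak <- function(img, s, through = NULL) {
  # a thick, slightly curved vegetation streak; optionally forced through a
  # given (col, row) point so it occludes a specific target
  slope <- stats::runif(1, -0.4, 0.4)
  x0 <- if (is.null(through)) stats::runif(1, 1, s)
        else through[1] - slope * through[2] -
          3 * sin(through[2] / s * 2 * pi * 2)
  width <- stats::runif(1, 1, max(2, s / 80))
  shade <- stats::runif(1, -35, 25)
  rows <- seq_len(s)
  center <- x0 + slope * rows + 3 * sin(rows / s * 2 * pi * 2)
  for (r in rows) {
    c1 <- max(1, floor(center[r] - width))
    c2 <- min(s, ceiling(center[r] + width))
    if (c1 <= c2)
      img[r, c1:c2, ] <- img[r, c1:c2, ] + shade
  }
  img
}

#' Generate one synthetic scene
#'
#' @param cfg a [scene_config()].
#' @param rng_state integer seed for this scene (defaults to `cfg$seed`).
#' @return A `wb_sample` whose labels are the exact bounding boxes of the
#'   rendered targets (occluders are drawn after the targets; boxes keep the
#'   full target extent).
#' @export
generate_scene <- function(cfg = scene_config(), rng_state = cfg$seed) {
  stopifnot(inherits(cfg, "wb_scene_config"))
  s <- cfg$image_size
  with_seed(rng_state, {
    bg <- synth_background(cfg$background, s)
    img <- bg$img
    n_birds <- if (cfg$n_birds_range[1] == cfg$n_birds_range[2])
      cfg$n_birds_range[1]
    else sample(cfg$n_birds_range[1]:cfg$n_birds_range[2], 1)
    boxes <- matrix(0, 0, 4)
    centers <- matrix(0, 0, 2)
    occluded <- logical(0)
    placed <- 0
    if (n_birds > 0) {
      for (b in seq_len(n_birds)) {
        done <- FALSE
        for (try in 1:60) {
          afrac <- stats::runif(1, cfg$bird_area_fraction_range[1],
                                cfg$bird_area_fraction_range[2])
          area_px <- afrac * s * s
          aspect <- stats::runif(1, 0.6, 1.8)
          ry <- sqrt(area_px / (pi * aspect))
          rx <- aspect * ry
          if (rx < 1) rx <- 1
          if (ry < 1) ry <- 1
          phi <- stats::runif(1, 0, pi)
          ext <- max(rx, ry) * 1.7 + 2
          if (2 * ext >= s) next
          cx <- stats::runif(1, ext, s - ext)
          cy <- stats::runif(1, ext, s - ext)
          cand <- c(cx - ext, cy - ext, cx + ext, cy + ext)
          if (nrow(boxes) > 0 &&
              any(iou_one_many(cand, boxes) > 0.25)) next
          delta <- stats::runif(1, cfg$contrast_delta_range[1],
                                cfg$contrast_delta_range[2])
          dr <- draw_bird(img, cx, cy, rx, ry, phi, delta)
          if (is.null(dr)) next
          img <- dr$img
          # exact bounding box of the rendered support (pixel centres +-0.5)
          bb <- c(min(dr$cols) - 0.5, min(dr$rows) - 0.5,
                  max(dr$cols) + 0.5, max(dr$rows) + 0.5)
          boxes <- rbind(boxes, bb)
          centers <- rbind(centers, c(cx, cy))
          occluded <- c(occluded, stats::runif(1) < cfg$occlusion_prob)
          placed <- placed + 1
          done <- TRUE
          break
        }
        if (!done)
          stop("generation error: could not place target ", b,
               " after bounded retries")
      }
    }
    for (i in which(occluded)) img <- draw_streak(img, s, centers[i, ])
    n_extra <- if (bg$kind == "vegetation") 3 else 1
    for (i in seq_len(sample(0:n_extra, 1))) img <- draw_streak(img, s)
    out <- array(as.integer(clip255(round(img))), dim(img))
    labels <- pixel_boxes_to_labels(boxes, s, s)
    if (nrow(labels) > 0) validate_labels(labels)
    image_sample(out, labels, sprintf("scene_%010d", as.integer(rng_state)))
  })
}

# per-image seed derivation, kept below 2^31
scene_seed <- function(base_seed, i) {
  (as.numeric(base_seed) * 7919 + i * 104729) %% 2147483647
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` image/label pairs and a manifest that records the
#' per-image seeds, so any single scene can be regenerated in isolation with
#' [generate_scene()].
#'
#' @param n_images number of scenes (>= 1).
#' @param cfg a [scene_config()].
#' @param out_dir output directory.
#' @return The manifest path (invisibly: list of samples as attribute).
#' @export
generate_dataset <- function(n_images, cfg = scene_config(), out_dir) {
  if (n_images < 1) stop("invalid input: n_images must be >= 1")
  seeds <- vapply(seq_len(n_images), function(i) scene_seed(cfg$seed, i), 0)
  samples <- lapply(seeds, function(sd) generate_scene(cfg, sd))
  for (i in seq_along(samples))
    samples[[i]]$id <- sprintf("img_%05d", i)
  mp <- write_dataset(samples, out_dir,
                      extra = list(scene_seeds = as.list(seeds),
                                   image_size = cfg$image_size))
  attr(mp, "samples") <- samples
  invisible(mp)
}

#' Generate a synthetic dataset in memory
#'
#' @param n_images number of scenes.
#' @param cfg a [scene_config()].
#' @return list of `wb_sample`.
#' @export
generate_scenes <- function(n_images, cfg = scene_config()) {
  if (n_images < 1) stop("invalid input: n_images must be >= 1")
  lapply(seq_len(n_images), function(i) {
    s <- generate_scene(cfg, scene_seed(cfg$seed, i))
    s$id <- sprintf("img_%05d", i)
    s
  })
}
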