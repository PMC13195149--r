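# ---------------------------------------------------------------------------
# Dataset I/O: YOLO-format label files, PNG images, YAML manifests.
#
# Labels use the standard one-file-per-image text format: one
# "class cx cy w h" line per object, with centre and size normalised to the
# image dimensions.
# ---------------------------------------------------------------------------

#' Create a YOLO label record
#'
#' @param class_id zero-based class index.
#' @param cx,cy,w,h normalised centre and size, all in `[0, 1]`, `w*h > 0`.
#' @return A one-row data frame.
#' @export
yolo_label <- function(class_id, cx, cy, w, h) {
  lab <- data.frame(class_id = as.integer(class_id), cx = cx, cy = cy,
                    w = w, h = h)
  validate_labels(lab)
  lab
}

validate_labels <- function(labels) {
  if (nrow(labels) == 0) return(invisible(labels))
  vals <- as.matrix(labels[, c("cx", "cy", "w", "h")])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("invalid label: coordinates must lie in [0,1]")
  if (any(labels$w * labels$h <= 0))
    stop("invalid label: boxes must have positive area")
  if (any(labels$class_id < 0))
    stop("invalid label: negative class id")
  invisible(labels)
}

empty_labels <- function()
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))

#' Read YOLO labels from a text file
#'
#' @param path label file; whitespace-delimited `class cx cy w h` rows.
#'   An empty (or missing-but-expected) file yields zero labels.
#' @return Data frame with columns `class_id, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_labels())
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (length(tok) != 5)
      stop("parse error at line ", i, " of ", path, ": expected 5 fields")
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("parse error at line ", i, " of ", path, ": non-numeric token")
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop("parse error at line ", i, " of ", path,
           ": coordinate out of [0,1]")
    data.frame(class_id = as.integer(v[1]), cx = v[2], cy = v[3],
               w = v[4], h = v[5])
  })
  labels <- do.call(rbind, rows)
  validate_labels(labels)
  labels
}

#' Write YOLO labels to a text file
#'
#' Values are written with 6 decimals, so a write/read round trip preserves
#' them to 1e-6.
#'
#' @param labels data frame with columns `class_id, cx, cy, w, h`.
#' @param path output file.
#' @export
write_yolo_labels <- function(labels, path) {
  validate_labels(labels)
  if (nrow(labels) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$cx,
                   labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

# convert normalised labels to pixel corner boxes
labels_to_pixel_boxes <- function(labels, h, w) {
  if (nrow(labels) == 0)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), class_id = integer(0)))
  data.frame(x1 = (labels$cx - labels$w / 2) * w,
             y1 = (labels$cy - labels$h / 2) * h,
             x2 = (labels$cx + labels$w / 2) * w,
             y2 = (labels$cy + labels$h / 2) * h,
             class_id = labels$class_id)
}

pixel_boxes_to_labels <- function(boxes, h, w, class_id = 0L) {
  if (nrow(boxes) == 0) return(empty_labels())
  data.frame(class_id = as.integer(class_id),
             cx = (boxes[, 1] + boxes[, 3]) / 2 / w,
             cy = (boxes[, 2] + boxes[, 4]) / 2 / h,
             w = (boxes[, 3] - boxes[, 1]) / w,
             h = (boxes[, 4] - boxes[, 2]) / h)
}

#' Read an image as an 8-bit array
#'
#' @param path a PNG file.
#' @return `H x W x 3` integer array with values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  arr <- round(a * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Write an 8-bit image array to PNG
#'
#' @param image `H x W x 3` array with values in 0..255.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(clip255(image) / 255, path)
  invisible(path)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# model input: [1, 3, H, W] scaled to [0, 1]
image_to_input <- function(image) {
  d <- dim(image)
  x <- aperm(array(as.numeric(image) / 255, d), c(3, 1, 2))
  dim(x) <- c(1, d[3], d[1], d[2])
  x
}

#' Create an image sample
#'
#' @param image `H x W x 3` 0..255 array.
#' @param labels YOLO label data frame.
#' @param id sample name.
#' @return list of class `wb_sample`.
#' @export
image_sample <- function(image, labels, id) {
  if (length(dim(image)) != 3 || any(dim(image) < 1))
    stop("invalid input: image must be H x W x 3")
  validate_labels(labels)
  structure(list(image = image, labels = labels, id = id),
            class = "wb_sample")
}

#' Write a dataset manifest
#'
#' @param samples list of `wb_sample`.
#' @param dir output directory (images/ and labels/ subdirectories).
#' @param extra named list merged into the manifest.
#' @return Path of the manifest YAML.
#' @export
write_dataset <- function(samples, dir, extra = list()) {
  img_dir <- file.path(dir, "images")
  lab_dir <- file.path(dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create dataset directory: ", dir)
  for (s in samples) {
    write_image(s$image, file.path(img_dir, paste0(s$id, ".png")))
    write_yolo_labels(s$labels, file.path(lab_dir, paste0(s$id, ".txt")))
  }
  man <- c(list(images = "images", labels = "labels",
                names = list("bird"),
                ids = lapply(samples, function(s) s$id)), extra)
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, mp)
  mp
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.yaml`.
#' @return list of `wb_sample`.
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.yaml")
  if (!file.exists(mp)) stop("manifest not found in ", dir)
  man <- yaml::read_yaml(mp)
  lapply(man$ids, function(id) {
    image_sample(read_image(file.path(dir, man$images, paste0(id, ".png"))),
                 read_yolo_labels(file.path(dir, man$labels,
                                            paste0(id, ".txt"))),
                 id)
  })
}
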