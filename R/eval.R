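# ---------------------------------------------------------------------------
# Evaluation metrics: greedy matching, precision/recall, interpolated AP and
# the mAP@0.5 / mAP@0.5:0.95 aggregates.
# ---------------------------------------------------------------------------

#' Match detections against ground truth
#'
#' Detections are processed in order of descending confidence; each one is
#' matched to the unmatched ground-truth box of highest IoU provided that IoU
#' reaches `iou_thresh` (a true positive), otherwise it is a false positive.
#' Ground-truth boxes never match twice; those left unmatched are false
#' negatives.
#'
#' @param dets detection data frame (columns `x1, y1, x2, y2, score`).
#' @param gts matrix of ground-truth boxes `[m, 4]` (may have zero rows).
#' @param iou_thresh matching threshold in `(0, 1]`.
#' @return list with `TP`, `FP`, `FN` counts and `flags` (logical TP flag per
#'   detection, ordered by descending confidence).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  if (iou_thresh <= 0 || iou_thresh > 1)
    stop("invalid config: iou_thresh must be in (0,1]")
  gts <- as.matrix(gts)
  if (length(gts) == 0) gts <- matrix(0, 0, 4)
  ngt <- nrow(gts)
  if (is.null(dets) || nrow(dets) == 0)
    return(list(TP = 0L, FP = 0L, FN = ngt, flags = logical(0)))
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  used <- logical(ngt)
  flags <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (ngt == 0) break
    b <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
    ious <- iou_one_many(b, gts)
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) == 1 && ious[j] >= iou_thresh) {
      flags[i] <- TRUE
      used[j] <- TRUE
    }
  }
  tp <- sum(flags)
  list(TP = as.integer(tp), FP = as.integer(nrow(dets) - tp),
       FN = as.integer(ngt - tp), flags = flags)
}

#' Precision of a match result
#'
#' `TP / (TP + FP)`; defined as 0 (with a warning) when no positives were
#' predicted.
#'
#' @param m a [match_detections()] result.
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(m) {
  if (m$TP + m$FP == 0) {
    warning("precision undefined (no predicted positives); returning 0")
    return(0)
  }
  m$TP / (m$TP + m$FP)
}

#' Recall of a match result
#'
#' `TP / (TP + FN)`; defined as 0 (with a warning) when there are no ground
#' truths.
#'
#' @param m a [match_detections()] result.
#' @return fraction in `[0, 1]`.
#' @export
recall <- function(m) {
  if (m$TP + m$FN == 0) {
    warning("recall undefined (no ground truths); returning 0")
    return(0)
  }
  m$TP / (m$TP + m$FN)
}

# build the interpolated PR curve from per-detection TP flags (descending
# confidence) and the number of ground truths
pr_curve_points <- function(flags, ngt) {
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  rec <- tp / ngt
  prec <- tp / (tp + fp)
  # monotone non-increasing interpolated precision
  if (length(prec) > 0)
    prec <- rev(cummax(rev(prec)))
  list(recall = rec, precision = prec)
}

# 101-point interpolation of the PR curve
ap_from_curve <- function(rec, prec) {
  if (length(rec) == 0) return(0)
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(r) {
    i <- which(rec >= r)
    if (length(i) == 0) 0 else max(prec[i])
  }, 0)
  mean(vals)
}

#' Average precision at a single IoU threshold
#'
#' Sweeps the confidence threshold over all detections, interpolates the
#' precision envelope, and integrates it on a 101-point recall grid.
#'
#' @param dets detection data frame for one class across the dataset, with an
#'   `image` column identifying the source image.
#' @param gts list (by image id) of ground-truth box matrices.
#' @param iou_thresh matching IoU threshold.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  ngt <- sum(vapply(gts, function(g) nrow(as.matrix(g)), 0))
  if (ngt == 0) stop("invalid input: no ground-truth boxes")
  if (is.null(dets) || nrow(dets) == 0) return(0)
  # per-image greedy matching, then pool flags by confidence
  flags <- NULL
  scores <- NULL
  for (img in names(gts)) {
    d <- dets[dets$image == img, , drop = FALSE]
    if (nrow(d) == 0) next
    m <- match_detections(d, gts[[img]], iou_thresh)
    flags <- c(flags, m$flags)
    scores <- c(scores, sort(d$score, decreasing = TRUE))
  }
  extra <- dets[!(dets$image %in% names(gts)), , drop = FALSE]
  if (nrow(extra) > 0) {
    flags <- c(flags, logical(nrow(extra)))
    scores <- c(scores, extra$score)
  }
  if (is.null(flags) || length(flags) == 0) return(0)
  ord <- order(-scores)
  pc <- pr_curve_points(flags[ord], ngt)
  ap_from_curve(pc$recall, pc$precision)
}

#' Evaluate detections over a labelled dataset
#'
#' Aggregates average precision per class at IoU thresholds 0.50 to 0.95 in
#' steps of 0.05, and reports the class means `map50` and `map5095` together
#' with the precision/recall of the operating point at IoU 0.5.
#'
#' @param detections data frame with columns
#'   `image, x1, y1, x2, y2, score, class_id` covering the whole dataset.
#' @param truths list by image id; each element a data frame or matrix with
#'   columns `x1, y1, x2, y2` and optionally `class_id`.
#' @param conf operating confidence for the reported precision/recall.
#' @return An `EvalReport` list: `precision`, `recall`, `ap_per_threshold`
#'   (classes x thresholds matrix), `map50`, `map5095`, `num_classes`.
#' @export
evaluate_detections <- function(detections, truths, conf = 0.25) {
  if (length(truths) == 0) stop("invalid input: empty dataset")
  gt_class <- function(g) {
    g <- as.data.frame(g)
    if (!"class_id" %in% names(g)) g$class_id <- 0L
    g
  }
  truths <- lapply(truths, gt_class)
  classes <- sort(unique(c(0L, unlist(lapply(truths, function(g) g$class_id)),
                           detections$class_id)))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(0, length(classes), length(thresholds),
               dimnames = list(paste0("class", classes),
                               sprintf("iou%.2f", thresholds)))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    gts_c <- lapply(truths, function(g) {
      as.matrix(g[g$class_id == cl, c("x1", "y1", "x2", "y2"), drop = FALSE])
    })
    ngt <- sum(vapply(gts_c, nrow, 0L))
    dets_c <- detections[detections$class_id == cl, , drop = FALSE]
    for (ti in seq_along(thresholds)) {
      ap[ci, ti] <- if (ngt == 0) NA_real_
                    else average_precision(dets_c, gts_c, thresholds[ti])
    }
  }
  ap_valid <- ap[!apply(ap, 1, function(r) all(is.na(r))), , drop = FALSE]
  # operating-point P/R at IoU 0.5
  dop <- detections[detections$score >= conf, , drop = FALSE]
  tp <- 0L; fp <- 0L; fn <- 0L
  for (img in names(truths)) {
    g <- truths[[img]]
    m <- match_detections(dop[dop$image == img, , drop = FALSE],
                          as.matrix(g[, c("x1", "y1", "x2", "y2")]), 0.5)
    tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
  }
  fp <- fp + sum(!(dop$image %in% names(truths)))
  mres <- list(TP = tp, FP = fp, FN = fn)
  structure(list(
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    ap_per_threshold = ap,
    map50 = mean(ap_valid[, 1]),
    map5095 = mean(ap_valid),
    num_classes = nrow(ap_valid)), class = "wb_eval_report")
}

#' Evaluate a model on a dataset of image samples
#'
#' Runs the detector on every sample, decodes with the evaluation operating
#' point (low confidence, wide NMS) and aggregates [evaluate_detections()].
#'
#' @param model a built model.
#' @param samples list of image samples (see [generate_scene()]).
#' @param conf decoding confidence threshold.
#' @param nms_iou NMS IoU threshold.
#' @return An `EvalReport`.
#' @export
evaluate_dataset <- function(model, samples, conf = 0.001, nms_iou = 0.7) {
  if (length(samples) == 0) stop("invalid input: empty dataset")
  dets <- list()
  truths <- list()
  for (s in samples) {
    x <- image_to_input(s$image)
    fw <- model_forward(model, x, train = FALSE)
    d <- decode_and_nms(fw$levels, conf, nms_iou,
                        strides = model$strides,
                        reg_max = model$cfg$reg_max %||% 16,
                        nc = model$cfg$num_classes)
    if (nrow(d) > 0) d$image <- s$id
    dets[[s$id]] <- d
    truths[[s$id]] <- labels_to_pixel_boxes(s$labels, dim(s$image)[1],
                                            dim(s$image)[2])
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  if (is.null(dets)) dets <- cbind(empty_detections(), image = character(0))
  evaluate_detections(dets, truths)
}

#' Frames-per-second probe
#'
#' Wall-clock throughput of single-image inference; informational only.
#'
#' @param model a built model, or any function of one input image.
#' @param input_size square input side.
#' @param n_warmup,n_timed warm-up and timed iterations (`n_timed >= 1`).
#' @return frames per second.
#' @export
measure_fps <- function(model, input_size = 160, n_warmup = 1, n_timed = 3) {
  if (n_timed < 1) stop("invalid config: n_timed must be >= 1")
  x <- array(stats::runif(3 * input_size^2), c(1, 3, input_size, input_size))
  run1 <- if (is.function(model)) function() model(x)
          else function() model_forward(model, x, FALSE)
  for (i in seq_len(n_warmup)) run1()
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_timed)) run1()
  dt <- proc.time()[["elapsed"]] - t0
  n_timed / max(dt, 1e-9)
}
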